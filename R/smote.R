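#' SMOTE oversampling of the minority class
#'
#' Synthetic minority oversampling: each synthetic sample is drawn by picking
#' a minority point, one of its \code{k} nearest minority neighbours under
#' Euclidean distance, and a uniform point on the segment between them,
#' \code{x + u * (x' - x)}. Enough synthetic samples are generated to raise
#' the minority count to the majority count; majority rows are untouched.
#' On binary fingerprint matrices the Euclidean distance is the square root
#' of the Hamming distance, and synthetic values are left fractional (convex
#' combinations in [0,1]) unless \code{round_bits} is set.
#'
#' @param x numeric feature matrix.
#' @param y binary labels (factor or character), one per row of \code{x}.
#' @param k number of nearest minority neighbours to interpolate towards; if
#'   the minority class has fewer than \code{k + 1} members, \code{k} is
#'   reduced with a warning.
#' @param seed integer; fixed seed gives byte-identical output.
#' @param round_bits round synthetic values to hard bits.
#' @return object of class \code{smote_result}: list with \code{x} (original
#'   rows followed by synthetic rows), \code{y}, \code{synthetic_index} (row
#'   indices of the synthetic samples), \code{parent_pairs} (two-column
#'   matrix of minority row indices in the input that parent each synthetic
#'   sample) and \code{seed}.
#' @export
smote <- function(x, y, k = 5, seed = 1, round_bits = FALSE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) == 0) stopf("smote(): empty feature matrix")
  y <- as.character(y)
  if (length(y) != nrow(x)) stopf("smote(): length(y) != nrow(x)")
  counts <- table(y)
  if (length(counts) < 2) stopf("smote(): y has a single class")
  if (length(counts) > 2) stopf("smote(): y must be binary")

  minority <- names(counts)[which.min(counts)]
  majority <- names(counts)[which.max(counts)]
  n_min <- counts[[minority]]; n_maj <- counts[[majority]]
  n_syn <- n_maj - n_min
  min_idx <- which(y == minority)

  if (n_syn == 0)
    return(structure(list(x = x, y = y, synthetic_index = integer(),
                          parent_pairs = matrix(integer(), 0, 2,
                                                dimnames = list(NULL, c("base", "neighbor"))),
                          k = k, seed = seed),
                     class = "smote_result"))
  if (n_min < 2) stopf("smote(): minority class needs at least 2 members")
  if (k > n_min - 1) {
    warnf("smote(): k reduced from %d to %d (minority size %d)", k, n_min - 1, n_min)
    k <- n_min - 1
  }

  xm <- x[min_idx, , drop = FALSE]
  d2 <- as.matrix(stats::dist(xm))
  diag(d2) <- Inf
  # k nearest minority neighbours per minority point (deterministic tie-break
  # by row order via order())
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  if (k == 1) nn <- matrix(nn, ncol = 1)

  syn <- matrix(0, n_syn, ncol(x))
  pairs <- matrix(0L, n_syn, 2, dimnames = list(NULL, c("base", "neighbor")))
  with_seed(seed, {
    base <- sample(seq_len(n_min), n_syn, replace = TRUE)
    pick <- sample(seq_len(k), n_syn, replace = TRUE)
    u <- stats::runif(n_syn)
    for (i in seq_len(n_syn)) {
      b <- base[i]; nb <- nn[b, pick[i]]
      syn[i, ] <- xm[b, ] + u[i] * (xm[nb, ] - xm[b, ])
      pairs[i, ] <- c(min_idx[b], min_idx[nb])
    }
  })
  if (round_bits) syn <- round(syn)
  colnames(syn) <- colnames(x)
  out_x <- rbind(x, syn)
  rownames(out_x) <- NULL
  out_y <- c(y, rep(minority, n_syn))
  structure(list(x = out_x, y = out_y,
                 synthetic_index = nrow(x) + seq_len(n_syn),
                 parent_pairs = pairs, k = k, seed = seed),
            class = "smote_result")
}

#' @method print smote_result
#' @export
print.smote_result <- function(x, ...) {
  cat("smote_result:", length(x$synthetic_index), "synthetic samples, classes:",
      paste(sprintf("%s=%d", names(table(x$y)), table(x$y)), collapse = ", "),
      sprintf("(k = %d, seed = %d)\n", x$k, x$seed))
  invisible(x)
}
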