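.onLoad <- function(libname, pkgname) {
  # Quiet OpenBabel's global message log (per-molecule stereo/InChI notes
  # would otherwise flood stderr during batch featurization).
  tryCatch({
    log <- utils::getFromNamespace("obErrorLog_get", "ChemmineOB")()
    utils::getFromNamespace("OBMessageHandler_SetOutputLevel", "ChemmineOB")(log, 0)
  }, error = function(e) invisible(NULL))
  invisible(NULL)
}
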