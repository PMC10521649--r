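.onLoad <- function(libname, pkgname) {
  # Pin reticulate to the python on PATH unless the user already chose one;
  # keeps the HiGHS backend usable without network-based interpreter discovery.
  if (!nzchar(Sys.getenv("RETICULATE_PYTHON"))) {
    py <- Sys.which("python")
    if (!nzchar(py)) py <- Sys.which("python3")
    if (nzchar(py)) Sys.setenv(RETICULATE_PYTHON = py)
  }
}
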