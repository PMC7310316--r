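.onLoad <- function(libname, pkgname) {
  resetEventKinds()
  # fail fast if a vocabulary change ever made tabulation slugs collide
  for (code in c("MIABIS-SAMPLEDONOR-03", "MIABIS-SAMPLE-10",
                 "MIABIS-SAMPLE-11"))
    tabulatedColumnSpec(code)
  invisible(NULL)
}
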