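.onLoad <- function(libname, pkgname) {
  path <- system.file("extdata", "residues.tsv", package = pkgname)
  if (nzchar(path)) .registry$table <- readResidueTable(path)
  invisible()
}
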