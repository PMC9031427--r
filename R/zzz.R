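#' @useDynLib metaboText, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.onLoad <- function(libname, pkgname) {
  registerTokenizer("chem_word", chemWordTokenize)
  registerTokenizer("subword", syntheticSubwordTokenize)
}
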