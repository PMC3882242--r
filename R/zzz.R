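#' @keywords internal
#' @useDynLib csdwave, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang %||% .data
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  register_builtin_forms()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
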