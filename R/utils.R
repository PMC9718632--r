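#' @keywords internal
#' @importFrom stats median sd cor cov var lm coef rnorm rlnorm model.matrix
#' @importFrom utils read.csv write.csv head packageVersion
#' @importFrom signal sgolayfilt
#' @importFrom jsonlite toJSON write_json
"_PACKAGE"

#' Round half away from zero
#'
#' Reporting rounder for tabulated quantities (contents, correction factors,
#' relative errors). `base::round()` rounds half to even, which disagrees
#' with the conventional "round half up" used in analytical reporting.
#' A small epsilon guards against binary representation error pushing an
#' exact decimal half (e.g. 0.8375) just below the boundary.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-8) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("qamsfp_domain_error", "qamsfp_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("qamsfp_format_error", "qamsfp_error")))
}

stop_notfound <- function(...) {
  stop(errorCondition(paste0(...), class = c("qamsfp_notfound_error", "qamsfp_error")))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain(name, " must be a positive finite scalar")
  invisible(x)
}
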