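#' @importFrom methods as is new
#' @importFrom stats var cor sd rnorm rbinom runif rpois pchisq setNames
#'   model.matrix aggregate quantile qnorm coef fitted residuals simulate
#'   predict optimize
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ssblup <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ssblup_error")))
}

#' @keywords internal
assert_that <- function(ok, ..., class = "ssblup_invalid") {
  if (!isTRUE(ok)) stop_ssblup(..., class = class)
  invisible(TRUE)
}

## round half away from zero at the printed precision (plain round() is
## half-even and sits on floating-point artifacts at exact halves)
round_half_up <- function(x, digits = 2L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5 + 1e-9) / 10^digits
}

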