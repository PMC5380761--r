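#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq rchisq rexp rnorm runif chisq.test setNames
#' @importFrom utils read.delim write.table
NULL

# round half away from zero to `digits` decimals (printed-table convention;
# base round() is banker's rounding)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# path to a packaged data file
lrr_extdata <- function(file) {
  p <- system.file("extdata", file, package = "lrrcore")
  if (!nzchar(p)) stop_("packaged file not found: %s", file)
  p
}
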