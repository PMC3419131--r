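# Internal helpers shared across modules.

# Unit constants, centralised: contours are in mm, volumes reported in mL,
# masses in g.  Myocardial density per the standard CMR convention.
MM3_PER_ML <- 1000
MM_PER_CM <- 10
MYOCARDIAL_DENSITY_G_PER_CM3 <- 1.05

rhcmr_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "rhcmr_error"),
                      call = call))
}

#' Round half away from zero
#'
#' Reporting-layer rounding for percentages and table values. Unlike base
#' [round()], which rounds half to even, halves are rounded up in magnitude
#' (0.5 -> 1, 95.5 -> 96), the convention used by clinical statistics
#' software for printed tables.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), 0)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

is_point <- function(p) is.numeric(p) && length(p) == 2 && all(is.finite(p))

`%||%` <- function(a, b) if (is.null(a)) b else a
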