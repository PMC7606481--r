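`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral on an arbitrary sample grid
#' @param t strictly increasing times (seconds)
#' @param v values at `t`
#' @return the trapezoid-rule integral
#' @keywords internal
.trapz <- function(t, v) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (v[-n] + v[-1L]) / 2)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

#' Metric names of a perfusion map set, in canonical order
#' @export
PERFUSION_METRICS <- c("at", "ttp", "ttd", "mtt", "cbv", "cbf")

VIEWS <- c("AP", "LAT", "UNKNOWN")

ROI_LABELS <- c("MCA", "ACA", "PCA", "VERTEBROBASILAR", "CUSTOM")
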