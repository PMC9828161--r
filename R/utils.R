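#' @importFrom stats approx dbinom median optimise plogis qlogis qnorm quantile
#'   rbinom rmultinom rnorm runif sd setNames uniroot var rlnorm acf
#' @importFrom methods new validObject is slot
#' @importFrom utils read.csv write.csv packageVersion
NULL

invlogit <- stats::plogis
logit <- stats::qlogis

## trapezoid quadrature weights for an (unevenly spaced) increasing grid
trapezoidWeights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two grid points")
  d <- diff(x)
  c(d[1L], d[-1L] + d[-(n - 1L)], d[n - 1L]) / 2
}

logMeanExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

## density of the Student-t(df, 0, scale) prior, unnormalised constants kept
dstudent <- function(x, df = 3, scale = 10, log = TRUE) {
  out <- stats::dt(x / scale, df = df, log = TRUE) - log(scale)
  if (log) out else exp(out)
}

#' @importFrom stats dt
NULL

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
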