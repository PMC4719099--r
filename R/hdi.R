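#' Highest density interval of a sample
#'
#' The shortest interval containing the requested posterior mass: among all
#' windows of `ceiling(mass * n)` consecutive order statistics, the one of
#' minimal width (ties broken toward the smallest lower bound). Every value
#' inside an HDI has higher estimated density than any value outside it; for
#' skewed samples it is shorter than the equal-tailed interval.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' hdi(1:100)  # c(1, 95)
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 100) stop("need at least 100 draws for an HDI")
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    stop("`mass` must lie strictly between 0 and 1")
  }
  k <- ceiling(mass * n)
  if (k > n) stop("fewer draws than needed for the requested mass")
  s <- sort(draws)
  lo <- seq_len(n - k + 1)
  widths <- s[lo + k - 1] - s[lo]
  i <- which.min(widths)  # first minimum = smallest lower bound
  c(low = s[i], high = s[i + k - 1])
}
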