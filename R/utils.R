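# numerically stable log-space helpers

logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logMeanExp <- function(x) logSumExp(x) - log(length(x))

#' Effective sample size of a set of log-weights
#'
#' (sum w)^2 / sum w^2 for the finite-weight paths.
#'
#' @param logw log importance weights (-Inf allowed).
#' @return the effective sample size.
#' @export
effectiveSampleSize <- function(logw) {
  if (!any(is.finite(logw))) return(0)
  exp(2 * logSumExp(logw) - logSumExp(2 * logw))
}
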