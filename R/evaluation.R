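#' Prediction accuracy and bias
#'
#' Accuracy is the Pearson correlation between GEBV and the validation
#' phenotype (trait deviation / daughter trait deviation); bias is the slope
#' of the ordinary least-squares regression of phenotype on GEBV (1 =
#' unbiased; < 1 means GEBV are over-dispersed).
#'
#' @param gebv predicted genomic breeding values.
#' @param phenotype paired validation phenotypes.
#' @return list with \code{accuracy} and \code{bias}.
#' @examples
#' accuracy_bias(c(1, 2, 3, 4), c(2, 4, 6, 8))  # accuracy 1, bias 2
#' @export
accuracy_bias <- function(gebv, phenotype) {
  stopifnot(length(gebv) == length(phenotype))
  if (length(gebv) < 3) stop("need at least 3 paired observations")
  if (stats::var(gebv) == 0) stop("zero variance in gebv")
  acc <- stats::cor(gebv, phenotype)
  slope <- stats::cov(gebv, phenotype) / stats::var(gebv)
  list(accuracy = acc, bias = slope)
}

#' Genetic-architecture summary
#'
#' Percentage of variants attributed to each of the four mixture components
#' (zero, 1e-4, 1e-3, 0.01 times sigma_g^2): column means of the posterior
#' class-membership matrix P times 100. Sums to 100.
#'
#' @param summary a \code{"bayesr_posterior"} (or anything with an m x 4
#'   \code{P}).
#' @return named numeric vector of length 4 (percent).
#' @export
architecture_summary <- function(summary) {
  P <- if (is.matrix(summary)) summary else summary$P
  pct <- colMeans(P) * 100
  names(pct) <- c("zero", "small", "medium", "large")
  pct
}
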