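#' Record weights for bull and cow phenotypes
#'
#' Weights deregressed-proof style phenotypes (daughter trait deviations for
#' bulls, trait deviations for cows) by their information content, following
#' Garrick et al.'s derivation:
#' \deqn{w_{bull} = (1 - h^2) / (c h^2 + (4 - h^2)/d)}
#' \deqn{w_{cow} = (1 - h^2) / (c h^2 + [1 + (r-1) t]/r - h^2)}
#' where d is the bull's daughter count, r the cow's record count, t the
#' repeatability, and c the fraction of additive genetic variance not captured
#' by the markers.
#'
#' @param sex \code{"bull"} or \code{"cow"} (vectorized).
#' @param h2 heritability in (0,1).
#' @param c_frac fraction of genetic variance not captured by SNP (default
#'   0.1).
#' @param d daughter count (bulls), >= 1.
#' @param r record count (cows), >= 1.
#' @param t repeatability in [0,1) (cows).
#' @return positive weight(s) w; error on a non-positive denominator.
#' @examples
#' garrick_weight("bull", h2 = 0.25, c_frac = 0.1, d = 10)  # 1.875
#' @export
garrick_weight <- function(sex, h2, c_frac = 0.1, d = NULL, r = NULL,
                           t = 0) {
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must be in (0,1)")
  sex <- match.arg(tolower(as.character(sex)), c("bull", "cow"),
                   several.ok = TRUE)
  nmax <- max(length(sex), length(d %||% 0), length(r %||% 0))
  sex <- rep_len(sex, nmax)
  denom <- numeric(nmax)
  is_bull <- sex == "bull"
  if (any(is_bull)) {
    if (is.null(d)) stop("daughter count d required for bulls")
    db <- rep_len(d, nmax)[is_bull]
    if (any(is.na(db) | db < 1)) stop("d must be >= 1 for bulls")
    denom[is_bull] <- c_frac * h2 + (4 - h2) / db
  }
  if (any(!is_bull)) {
    if (is.null(r)) stop("record count r required for cows")
    rc <- rep_len(r, nmax)[!is_bull]
    if (any(is.na(rc) | rc < 1)) stop("r must be >= 1 for cows")
    denom[!is_bull] <- c_frac * h2 + (1 + (rc - 1) * t) / rc - h2
  }
  if (any(denom <= 0))
    stop("non-positive weight denominator (h2 = ", h2[1],
         ", c = ", c_frac, "); weights undefined for these records")
  (1 - h2) / denom
}

#' Diagonal of the heterogeneous error matrix E
#'
#' Residuals are modelled as e ~ N(0, E sigma_e^2) with E diagonal; each
#' record's entry is the reciprocal of its weight, so high-information records
#' (large w) carry a smaller error variance.
#'
#' @param weights positive record weights.
#' @return numeric vector \code{1/weights}.
#' @export
build_error_matrix <- function(weights) {
  if (any(!is.finite(weights) | weights <= 0))
    stop("weights must be positive and finite")
  1 / weights
}

#' Narrow-sense heritability from variance components
#'
#' h2 = sigma_g^2 / (sigma_g^2 + sigma_a^2 + sigma_e^2): the marker-captured
#' additive variance over the total of marker, polygenic and error variance.
#'
#' @param sigma_g2 additive genetic (marker) variance, or a list/vector with
#'   named components \code{sigma_g2}, \code{sigma_a2}, \code{sigma_e2}.
#' @param sigma_a2 additive polygenic variance.
#' @param sigma_e2 error variance.
#' @return heritability in [0,1].
#' @examples
#' heritability(1, 0, 1)  # 0.5
#' @export
heritability <- function(sigma_g2, sigma_a2 = NULL, sigma_e2 = NULL) {
  if (is.list(sigma_g2) || (is.numeric(sigma_g2) && !is.null(names(sigma_g2)) &&
                            "sigma_g2" %in% names(sigma_g2))) {
    vc <- sigma_g2
    sigma_a2 <- vc[["sigma_a2"]]; sigma_e2 <- vc[["sigma_e2"]]
    sigma_g2 <- vc[["sigma_g2"]]
  }
  v <- c(sigma_g2, sigma_a2, sigma_e2)
  if (any(v < 0)) stop("variance components must be >= 0")
  tot <- sigma_g2 + sigma_a2 + sigma_e2
  if (tot <= 0) stop("total variance must be positive")
  sigma_g2 / tot
}

#' Variance-component bundle
#'
#' Convenience constructor validating the input variances that drive every
#' engine (the variances are treated as known, estimated externally).
#'
#' @param sigma_g2,sigma_a2,sigma_e2 non-negative variances.
#' @param t repeatability (cow records).
#' @param c_frac fraction of genetic variance not captured by SNP.
#' @return list of class \code{"variance_components"} with an added \code{h2}.
#' @export
variance_components <- function(sigma_g2, sigma_a2 = 0, sigma_e2,
                                t = 0, c_frac = 0.1) {
  stopifnot(sigma_g2 >= 0, sigma_a2 >= 0, sigma_e2 >= 0)
  structure(list(sigma_g2 = sigma_g2, sigma_a2 = sigma_a2,
                 sigma_e2 = sigma_e2, t = t, c_frac = c_frac,
                 h2 = heritability(sigma_g2, sigma_a2, sigma_e2)),
            class = "variance_components")
}
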