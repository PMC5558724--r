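#' Four-component mixture prior for SNP effects
#'
#' SNP effects are a priori drawn from
#' Pr1 N(0,0) + Pr2 N(0, 1e-4 sigma_g^2) + Pr3 N(0, 1e-3 sigma_g^2) +
#' Pr4 N(0, 0.01 sigma_g^2), with Pr ~ Dirichlet(alpha). The class variance
#' scalings are fixed for the whole run; only the proportions are updated.
#'
#' @param sigma_g2 additive genetic variance (fixed during inference).
#' @param gamma the four variance scalings (first must be 0, the spike).
#' @param alpha Dirichlet concentration.
#' @param pr_start starting proportions.
#' @return list of class \code{"mixture_prior"}.
#' @export
mixture_prior <- function(sigma_g2, gamma = c(0, 1e-4, 1e-3, 1e-2),
                          alpha = c(1, 1, 1, 1),
                          pr_start = c(0.5, 0.487, 0.01, 0.003)) {
  stopifnot(length(gamma) == 4, gamma[1] == 0, all(diff(gamma) > 0),
            length(alpha) == 4, all(alpha > 0), sigma_g2 > 0,
            length(pr_start) == 4, all(pr_start >= 0))
  pr_start <- pr_start / sum(pr_start)
  structure(list(sigma_g2 = sigma_g2, gamma = gamma, alpha = alpha,
                 pr = pr_start), class = "mixture_prior")
}

#' Gibbs update of a single SNP effect
#'
#' Samples the mixture-class indicator from its full conditional -- each
#' class weighted by Pr_k times the marginal likelihood of the partial
#' residual with the effect integrated out -- then, for a slab class, draws
#' the effect from the conjugate normal
#' N(r_i / (l_i + sigma_e^2/sigma_k^2), sigma_e^2 / (l_i + sigma_e^2/sigma_k^2))
#' with r_i = Z_i' E^-1 (e + Z_i g_old) and l_i = Z_i' E^-1 Z_i. The spike
#' class sets the effect to zero. Likelihoods are evaluated in log space.
#'
#' @param z standardized genotype column Z_i.
#' @param e current residual vector (excludes nothing: it already reflects
#'   \code{g_old}).
#' @param g_old current effect of this SNP.
#' @param prior a \code{\link{mixture_prior}}; its \code{pr} element is the
#'   current proportion vector.
#' @param sigma_e2 current residual variance.
#' @param E_diag diagonal of E (default 1).
#' @return list with \code{g} (new effect), \code{class} (1..4), \code{e}
#'   (updated residuals), and \code{post_prob} (the full-conditional class
#'   probabilities).
#' @export
sample_snp_effect <- function(z, e, g_old, prior, sigma_e2, E_diag = 1) {
  einv <- rep_len(1 / E_diag, length(z))
  if (anyNA(z) || anyNA(e)) stop("NaN/NA input to sample_snp_effect")
  l <- sum(z * einv * z)
  r <- sum(z * einv * e) + l * g_old
  vark <- l^2 * prior$gamma * prior$sigma_g2 + l * sigma_e2
  logw <- log(prior$pr) - 0.5 * log(vark) - 0.5 * r^2 / vark
  logw[prior$pr == 0] <- -Inf
  w <- exp(logw - max(logw))
  post_prob <- w / sum(w)
  k <- sample.int(4, 1, prob = post_prob)
  if (k == 1L) {
    g_new <- 0
  } else {
    denom <- l + sigma_e2 / (prior$gamma[k] * prior$sigma_g2)
    g_new <- stats::rnorm(1, r / denom, sqrt(sigma_e2 / denom))
  }
  list(g = g_new, class = k, e = e - z * (g_new - g_old),
       post_prob = post_prob)
}

#' Sample mixture proportions
#'
#' Pr | counts ~ Dirichlet(alpha + counts), drawn via independent gammas.
#'
#' @param class_counts integer vector of length 4 (SNPs per class).
#' @param alpha Dirichlet concentration (default all 1).
#' @return proportion vector on the 4-simplex.
#' @export
sample_mixture_proportions <- function(class_counts, alpha = c(1, 1, 1, 1)) {
  if (any(class_counts < 0)) stop("negative class counts")
  gk <- stats::rgamma(4, shape = alpha + class_counts, rate = 1)
  gk / sum(gk)
}

#' Sample polygenic values from their full conditional
#'
#' v | . ~ N(Sigma b, Sigma) with Sigma = (E^-1/sigma_e^2 +
#' A^-1/sigma_a^2)^-1 and b = E^-1 r_v / sigma_e^2, where r_v = e + v_old is
#' the partial residual. With sigma_a2 = 0 the polygenic term is dropped and
#' v = 0 deterministically.
#'
#' @param e current residuals. @param v_old current polygenic values.
#' @param A pedigree relationship matrix (NULL for identity).
#' @param E_diag diagonal of E. @param sigma_a2,sigma_e2 variances.
#' @return list with \code{v} and updated \code{e}.
#' @export
sample_polygenic <- function(e, v_old, A = NULL, E_diag = 1, sigma_a2,
                             sigma_e2) {
  n <- length(e)
  if (sigma_a2 == 0) return(list(v = numeric(n), e = e + v_old))
  einv <- rep_len(1 / E_diag, n)
  Ainv <- if (is.null(A)) diag(n) else solve(A)
  prec <- diag(einv / sigma_e2, n) + Ainv / sigma_a2
  ch <- chol(prec)
  rv <- e + v_old
  b <- einv * rv / sigma_e2
  mu <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  v <- mu + backsolve(ch, stats::rnorm(n))
  list(v = drop(v), e = e + v_old - drop(v))
}

#' Sample the residual variance
#'
#' sigma_e^2 | e ~ scaled inverse chi-square with df nu0 + n and scale
#' S0 + e' E^-1 e. The default (nu0 = -2, S0 = 0) is the flat prior on
#' sigma_e^2. The genetic variances sigma_g^2 and sigma_a^2 are never
#' updated: they are fixed inputs.
#'
#' @param e residual vector. @param E_diag diagonal of E.
#' @param nu0,S0 prior degrees of freedom and scale.
#' @return a draw of sigma_e^2.
#' @export
sample_residual_variance <- function(e, E_diag = 1, nu0 = -2, S0 = 0) {
  einv <- rep_len(1 / E_diag, length(e))
  ss <- S0 + sum(e^2 * einv)
  if (ss <= 0) stop("non-positive residual sum of squares")
  df <- nu0 + length(e)
  if (df <= 0) stop("non-positive degrees of freedom")
  ss / stats::rchisq(1, df)
}

# shared precomputations for the compiled engines
.engine_setup <- function(y, Zs, X, E_diag, A, vc) {
  n <- length(y)
  Zs <- as.matrix(Zs)
  stopifnot(nrow(Zs) == n)
  einv <- rep_len(1 / E_diag, n)
  Pbeta <- NULL
  if (!is.null(X)) {
    X <- as.matrix(X)
    XtEi <- t(X * einv)
    Pbeta <- solve(XtEi %*% X, XtEi)  # WLS operator for the beta update
  }
  Tv <- NULL; lamv <- NULL
  if (vc$sigma_a2 > 0) {
    # whitening transform for the polygenic full conditional:
    # precision = diag(einv)/se2 + Ainv/sa2 = S (I/se2 + B/sa2) S with
    # S = diag(sqrt(einv)), B = S^-1 Ainv S^-1; eigen-decompose B once
    Ainv <- if (is.null(A)) diag(n) else solve(A)
    s <- sqrt(einv)
    B <- t(Ainv / s) / s
    B <- (B + t(B)) / 2
    eg <- eigen(B, symmetric = TRUE)
    Tv <- eg$vectors / s
    lamv <- pmax(eg$values, 0)
  }
  list(y = as.numeric(y), Zs = Zs, X = X, Pbeta = Pbeta, einv = einv,
       Tv = Tv, lamv = lamv, n = n, m = ncol(Zs))
}

#' Full BayesR inference by Gibbs sampling
#'
#' Runs one or more Gibbs chains over the model y = X beta + Zs g + v + e
#' with the four-component mixture prior on g. Each iteration performs the
#' fixed-effect update, the full SNP sweep in input order, the Dirichlet
#' proportion draw, the polygenic draw and the residual-variance draw.
#' Chains are seeded \code{seed + chain - 1} and their post-burn-in means
#' averaged. The SNP-exclusion speed-up is off by default here (it belongs
#' to the hybrid scheme; see \code{\link{run_hybrid}}).
#'
#' @param y phenotype vector. @param Zs standardized genotype matrix.
#' @param X fixed-effect design (NULL for none).
#' @param E_diag diagonal of the error matrix E.
#' @param A pedigree relationship matrix (NULL = identity) used when
#'   \code{vc$sigma_a2 > 0}.
#' @param vc variance components (\code{sigma_g2}, \code{sigma_a2},
#'   \code{sigma_e2}).
#' @param prior a \code{\link{mixture_prior}}; defaults to the standard one
#'   built from \code{vc$sigma_g2}.
#' @param chains,iters,burnin MCMC layout (defaults 5 chains x 40000
#'   iterations, 20000 burn-in).
#' @param seed base RNG seed; chain j uses \code{seed + j - 1}.
#' @param start optional list with elements \code{g}, \code{pr}, \code{beta},
#'   \code{v}, \code{sigma_e2} to warm-start every chain.
#' @param exclusion,exclude_at,exclude_threshold SNP-exclusion speed-up:
#'   after \code{exclude_at} iterations, SNPs whose running spike
#'   probability exceeds the threshold are frozen at zero.
#' @param g_sample_thin if positive, store every so-many post-burn-in draws
#'   of g (memory heavy; for diagnostics at small m).
#' @param nu0,S0 residual-variance prior (flat by default).
#' @return object of class \code{"bayesr_posterior"}: per-SNP posterior
#'   means \code{g_mean}, class-membership frequencies \code{P} (m x 4),
#'   proportion means \code{pr_mean}, \code{gebv} (Zs g_mean), fixed-effect
#'   and polygenic means, \code{sigma_e2_mean}, per-chain results and run
#'   metadata.
#' @export
run_gibbs <- function(y, Zs, X = NULL, E_diag = 1, A = NULL, vc,
                      prior = mixture_prior(vc$sigma_g2),
                      chains = 5, iters = 40000, burnin = 20000,
                      seed = NULL, start = NULL,
                      exclusion = FALSE, exclude_at = 500,
                      exclude_threshold = 0.9, g_sample_thin = 0,
                      nu0 = -2, S0 = 0) {
  setup <- .engine_setup(y, Zs, X, E_diag, A, vc)
  m <- setup$m
  b <- if (is.null(setup$X)) 0L else ncol(setup$X)
  start_g <- start$g %||% rep(0, m)
  start_pr <- start$pr %||% prior$pr
  start_beta <- start$beta %||% rep(0, max(b, 1))
  start_v <- start$v %||% rep(0, setup$n)
  start_se2 <- start$sigma_e2 %||% vc$sigma_e2
  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    if (!is.null(seed)) set.seed(seed + ch - 1)
    runs[[ch]] <- .cpp_gibbs_chain(
      setup$Zs, setup$y, setup$X, setup$Pbeta, setup$einv,
      prior$gamma, prior$sigma_g2, vc$sigma_a2, setup$Tv, setup$lamv,
      prior$alpha, as.integer(iters), as.integer(burnin),
      start_g, start_pr, start_beta, start_v, start_se2,
      nu0, S0, exclusion, as.integer(exclude_at), exclude_threshold,
      as.integer(g_sample_thin))
    if (runs[[ch]]$drift_events > 0)
      warning("residual drift detected and resynced in chain ", ch)
  }
  avg <- function(fld) Reduce(`+`, lapply(runs, `[[`, fld)) / chains
  g_mean <- avg("g_mean")
  P <- avg("P")
  out <- structure(list(
    g_mean = g_mean,
    P = P,
    pr_mean = avg("pr_mean"),
    beta_mean = if (b > 0) avg("beta_mean") else NULL,
    v_mean = avg("v_mean"),
    sigma_e2_mean = mean(vapply(runs, `[[`, 0, "sigma_e2_mean")),
    gebv = drop(setup$Zs %*% g_mean),
    excluded = runs[[1]]$excluded,
    run_p1 = runs[[1]]$run_p1,
    n_samples = sum(vapply(runs, `[[`, 0L, "n_samples")),
    chains = runs, method = "mcmc",
    config = list(chains = chains, iters = iters, burnin = burnin,
                  seed = seed, exclusion = exclusion,
                  exclude_at = exclude_at,
                  exclude_threshold = exclude_threshold),
    vc = vc, prior = prior),
    class = "bayesr_posterior")
  out
}

#' @export
print.bayesr_posterior <- function(x, ...) {
  cat("BayesR posterior summary (", x$method, ")\n", sep = "")
  cat("  variants:", length(x$g_mean), " post-burn-in samples:",
      x$n_samples, "\n")
  cat("  mixture proportions:",
      paste(signif(x$pr_mean, 4), collapse = " "), "\n")
  cat("  sigma_e2 (posterior mean):", signif(x$sigma_e2_mean, 5), "\n")
  if (any(x$excluded)) cat("  excluded SNPs:", sum(x$excluded), "\n")
  invisible(x)
}
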