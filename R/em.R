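#' Per-SNP prediction-error-variance correction
#'
#' pev_corr_i = tr(E^-1 Z_i Z_i' E^-1 PEV_u) = (E^-1 Z_i)' PEV_u (E^-1 Z_i),
#' the amount of apparent information about SNP i that is actually
#' uncertainty in the all-other-SNP genetic values u. Computed once before
#' the EM iterations; independent per variant.
#'
#' @param Zs standardized genotype matrix. @param E_diag diagonal of E.
#' @param PEV_u prediction error variance matrix of u (from
#'   \code{\link{compute_pev_u}}).
#' @return non-negative vector of length m.
#' @export
precompute_pev_correction <- function(Zs, E_diag = 1, PEV_u) {
  Zs <- as.matrix(Zs)
  n <- nrow(Zs)
  if (!all(dim(PEV_u) == c(n, n)))
    stop("PEV_u must be ", n, " x ", n)
  W <- Zs * rep_len(1 / E_diag, n)
  unname(pmax(colSums(W * (PEV_u %*% W)), 0))
}

#' EM update of a single SNP
#'
#' E-step: class responsibilities P(i,k) proportional to Pr_k times the
#' marginal likelihood of the partial-residual statistic
#' r_i = Z_i' E^-1 (e + Z_i g_old) under class k. Uncertainty in the
#' genetic-value correction u contributes additive noise to r_i with
#' variance exactly pev_corr_i = Var(Z_i' E^-1 (u - u_hat)), so the class
#' marginal variance is l_i^2 sigma_k^2 + tau with
#' tau = l_i sigma_e^2 + pev_corr_i. M-step: the effect becomes the
#' responsibility-weighted posterior mean over the slab classes,
#' g_i = sum_k P(i,k) r_i l_i / (l_i^2 + tau / sigma_k^2); the spike
#' contributes 0. With pev_corr = 0 these reduce to the usual conjugate
#' forms.
#'
#' @inheritParams sample_snp_effect
#' @param pev_corr the SNP's PEV correction scalar.
#' @return list with \code{g}, \code{P} (length-4 responsibilities), and
#'   updated \code{e}.
#' @export
em_update_snp <- function(z, e, g_old, prior, sigma_e2, E_diag = 1,
                          pev_corr = 0) {
  einv <- rep_len(1 / E_diag, length(z))
  if (anyNA(z) || anyNA(e)) stop("NaN/NA input to em_update_snp")
  l <- sum(z * einv * z)
  r <- sum(z * einv * e) + l * g_old
  tau <- l * sigma_e2 + pev_corr
  vark <- l^2 * prior$gamma * prior$sigma_g2 + tau
  logw <- log(prior$pr) - 0.5 * log(vark) - 0.5 * r^2 / vark
  logw[prior$pr == 0] <- -Inf
  w <- exp(logw - max(logw))
  P <- w / sum(w)
  sk2 <- prior$gamma[-1] * prior$sigma_g2
  ghat <- c(0, r * l / (l^2 + tau / sk2))
  g_new <- sum(P * ghat)
  list(g = g_new, P = P, e = e - z * (g_new - g_old))
}

#' Dirichlet-MAP update of the mixture proportions
#'
#' Pr_k = (sum_i P(i,k) + alpha_k - 1) / (m + sum(alpha) - 4), clipped to
#' the simplex. With the uniform prior this is just the mean responsibility
#' per class.
#'
#' @param P m x 4 responsibility matrix. @param alpha Dirichlet
#'   concentration.
#' @return proportion vector.
#' @export
em_update_proportions <- function(P, alpha = c(1, 1, 1, 1)) {
  P <- as.matrix(P)
  if (nrow(P) == 0) stop("no SNPs: cannot update proportions")
  pr <- pmax(colSums(P) + alpha - 1, 0)
  tot <- nrow(P) + sum(alpha) - 4
  pr <- if (tot > 0) pr / tot else pr / sum(pr)
  pr / sum(pr)
}

#' EM convergence criterion
#'
#' stat = (g_new - g_old)'(g_new - g_old) / (g_new' g_new); converged when
#' strictly below \code{tol} (default 1e-10). An identically zero g_new is
#' converged by convention (stat 0).
#'
#' @param g_new,g_old effect vectors of equal length.
#' @param tol strict threshold.
#' @return list with \code{stat} and logical \code{converged}.
#' @export
check_convergence <- function(g_new, g_old, tol = 1e-10) {
  stopifnot(length(g_new) == length(g_old))
  denom <- sum(g_new^2)
  if (denom == 0) return(list(stat = 0, converged = TRUE))
  stat <- sum((g_new - g_old)^2) / denom
  list(stat = stat, converged = stat < tol)
}

# The monitored EM objective is the variational free energy: the expected
# complete-data log joint posterior under the per-SNP class/effect
# posteriors q, plus their entropy. Each EM sub-step (SNP sweep, Pr MAP,
# polygenic mode, sigma_e2 M-step) is an ascent step for this functional,
# so it is non-decreasing across iterations; the point-estimate log
# posterior alone is not what a posterior-mean M-step climbs.
.em_free_energy <- function(ss_corrected, n, sigma_e2, entropy_terms,
                            class_mass, pr, alpha, v = NULL, Ainv = NULL,
                            sigma_a2 = 0, u_pen = 0) {
  ll <- -0.5 * n * log(sigma_e2) - ss_corrected / (2 * sigma_e2)
  prior_pr <- sum(ifelse(class_mass > 0, class_mass * log(pmax(pr, 1e-300)),
                         0))
  dir <- sum((alpha - 1) * log(pmax(pr, 1e-300)))
  vpen <- if (sigma_a2 > 0 && !is.null(v))
    -0.5 * drop(crossprod(v, Ainv %*% v)) / sigma_a2 else 0
  ll + entropy_terms + prior_pr + dir + vpen + u_pen
}

#' Expectation-maximization stage of the hybrid scheme
#'
#' Initializes every SNP effect at 0.01 and the proportions at
#' {0.5, 0.487, 0.01, 0.003}, then iterates: fixed-effect update, the full
#' SNP E/M sweep, the Dirichlet-MAP proportion update, the polygenic BLUP
#' update, the genetic-value (u) refresh, and the maximum-likelihood
#' residual-variance update, until the relative squared change in g falls
#' strictly below \code{tol}.
#'
#' When \code{pev_correction} is TRUE (the default), a GBLUP fit at startup
#' supplies the prediction error variance of the genetic values u; its
#' per-SNP trace term inflates the apparent residual noise in the E-step,
#' and u itself is refreshed each iteration by a GBLUP solve on the current
#' residual signal, so that signal not yet captured by g is not mistaken
#' for evidence about individual SNPs. With \code{pev_correction = FALSE}
#' the model reduces to y = X beta + Zs g + v + e and the EM fixed point
#' with a degenerate single-slab prior is the ridge/BLUP solution.
#'
#' @inheritParams run_gibbs
#' @param max_iter iteration cap (the EM typically converges in far fewer).
#' @param tol strict convergence threshold on the relative squared change.
#' @param pev_correction enable the u/PEV machinery (see Details).
#' @param update_sigma_e2 update the residual variance each iteration by its
#'   M-step (the expected weighted sum of squares over n); FALSE holds it at
#'   \code{vc$sigma_e2}, which makes the single-slab fixed point exactly the
#'   ridge solution at that variance.
#' @param check_monotone monitor the EM objective (variational free energy)
#'   each iteration and record violations of monotonicity larger than 1e-6.
#' @param verbose print a per-iteration line (iteration, convergence
#'   statistic, proportions, sigma_e2).
#' @return object of class \code{"em_state"}: \code{g}, \code{P} (m x 4
#'   responsibilities), \code{pr}, \code{beta}, \code{u}, \code{v},
#'   \code{sigma_e2}, \code{e}, \code{pev_corr}, \code{iterations},
#'   \code{converged}, \code{stat}, \code{objective_trace},
#'   \code{monotone_violations}.
#' @export
run_em <- function(y, Zs, X = NULL, E_diag = 1, A = NULL, vc,
                   prior = mixture_prior(vc$sigma_g2),
                   max_iter = 5000, tol = 1e-10, pev_correction = TRUE,
                   update_sigma_e2 = TRUE, check_monotone = TRUE,
                   verbose = FALSE) {
  setup <- .engine_setup(y, Zs, X, E_diag, A, vc)
  n <- setup$n; m <- setup$m
  einv <- setup$einv
  Zei <- setup$Zs * einv
  l <- colSums(Zei * setup$Zs)
  Ainv <- if (vc$sigma_a2 > 0) (if (is.null(A)) diag(n) else solve(A)) else NULL

  pev_corr <- rep(0, m)
  u <- rep(0, n)
  Qg <- NULL; shrink_base <- NULL
  if (pev_correction) {
    G <- build_grm(setup$Zs)
    sol0 <- solve_mme(setup$y, setup$X, G, A = A, E_diag = 1 / einv, vc = vc)
    pev_corr <- precompute_pev_correction(setup$Zs, 1 / einv, sol0$PEV_u)
    # u-refresh operator: u = sg2 G (sg2 G + se2 E)^-1 r, diagonalized once
    # via B = S^-1 G S^-1 with S = diag(1/sqrt(einv))
    s <- sqrt(einv)
    B <- t(G * s) * s          # S^-1 G S^-1 with S^-1 = diag(sqrt(einv))
    B <- (B + t(B)) / 2
    eg <- eigen(B, symmetric = TRUE)
    Qg <- eg$vectors
    shrink_base <- pmax(eg$values, 0)
    attr(Qg, "s") <- s
  }
  refresh_u <- function(r_u, sigma_e2) {
    s <- attr(Qg, "s")
    fac <- vc$sigma_g2 * shrink_base /
      (vc$sigma_g2 * shrink_base + sigma_e2)
    drop((Qg %*% (fac * crossprod(Qg, s * r_u))) / s)
  }

  g <- rep(0.01, m)
  pr <- prior$pr
  beta <- if (!is.null(setup$X)) rep(0, ncol(setup$X)) else numeric(0)
  v <- rep(0, n)
  sigma_e2 <- vc$sigma_e2
  e <- setup$y - drop(setup$Zs %*% g)
  if (length(beta)) e <- e - drop(setup$X %*% beta)
  P <- matrix(c(1, 0, 0, 0), m, 4, byrow = TRUE)

  obj_trace <- numeric(0)
  violations <- 0
  stat <- Inf; converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    g_old_iter <- g
    if (length(beta)) {
      xb <- drop(setup$X %*% beta)
      beta_new <- drop(setup$Pbeta %*% (e + xb))
      e <- e + xb - drop(setup$X %*% beta_new)
      beta <- beta_new
    }
    sw <- .cpp_em_sweep(setup$Zs, Zei, e, g, l, pev_corr, pr,
                        prior$gamma, prior$sigma_g2, sigma_e2)
    g <- sw$g; e <- sw$e; P <- sw$P
    pr <- em_update_proportions(P, prior$alpha)
    pr <- pmax(pr, 1e-8); pr <- pr / sum(pr)  # no class dies irreversibly
    if (vc$sigma_a2 > 0) {
      rv <- e + v
      prec <- diag(einv / sigma_e2, n) + Ainv / vc$sigma_a2
      v_new <- drop(solve(prec, einv * rv / sigma_e2))
      e <- e + v - v_new
      v <- v_new
    }
    if (pev_correction) {
      ru <- e + u
      u_new <- refresh_u(ru, sigma_e2)
      e <- e + u - u_new
      u <- u_new
    }
    # M-step for sigma_e2: expected weighted sum of squares, which includes
    # the per-SNP posterior-variance term l_i Var_q(g_i)
    ss_corrected <- sum(e^2 * einv) + sum(l * sw$varg)
    if (update_sigma_e2) sigma_e2 <- ss_corrected / n
    if (check_monotone) {
      u_pen <- 0
      if (pev_correction && any(u != 0)) {
        s <- attr(Qg, "s")
        proj <- crossprod(Qg, s * u)
        lam <- pmax(shrink_base, 1e-12)
        u_pen <- -0.5 * sum(proj^2 / lam) / vc$sigma_g2
      }
      obj <- .em_free_energy(ss_corrected, n, sigma_e2,
                             sw$free_energy_terms, colSums(P), pr,
                             prior$alpha, v, Ainv, vc$sigma_a2, u_pen)
      if (length(obj_trace) && obj < obj_trace[length(obj_trace)] - 1e-6)
        violations <- violations + 1
      obj_trace <- c(obj_trace, obj)
    }
    cc <- check_convergence(g, g_old_iter, tol)
    stat <- cc$stat; converged <- cc$converged
    if (verbose)
      message(sprintf("EM iter %d  stat %.3e  Pr %s  se2 %.4g", it, stat,
                      paste(signif(pr, 3), collapse = "/"), sigma_e2))
    if (converged) break
  }
  if (!converged)
    warning("EM did not converge in ", max_iter,
            " iterations (stat = ", signif(stat, 3), "); returning best state")
  structure(list(g = g, P = P, pr = pr, beta = beta, u = u, v = v,
                 sigma_e2 = sigma_e2, e = e, pev_corr = pev_corr,
                 iterations = it, converged = converged, stat = stat,
                 objective_trace = obj_trace,
                 monotone_violations = violations,
                 gebv = drop(setup$Zs %*% g), vc = vc, prior = prior),
            class = "em_state")
}

#' @export
print.em_state <- function(x, ...) {
  cat("EM state:", length(x$g), "SNPs,", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(stat %.2e)\n", x$stat))
  cat("  Pr:", paste(signif(x$pr, 4), collapse = " "),
      " sigma_e2:", signif(x$sigma_e2, 5), "\n")
  invisible(x)
}
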