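#' Hybrid EM + warm-started MCMC inference
#'
#' The hybrid scheme runs \code{\link{run_em}} to convergence, uses the EM
#' state (g, Pr, beta, v, sigma_e2) as the starting point of a single short
#' Gibbs chain (default 4000 iterations, 1000 burn-in), and applies the
#' SNP-exclusion speed-up: after \code{exclude_at} iterations (default 500),
#' every SNP whose running spike probability P(i,1) exceeds
#' \code{exclude_threshold} (default 0.90) has its effect frozen at zero and
#' is skipped for the rest of the chain. The u/PEV correction is an EM-stage
#' device only; the MCMC stage runs the marker model directly, so residual
#' genetic signal is re-absorbed by the sampled SNP effects.
#'
#' @inheritParams run_gibbs
#' @param iters,burnin MCMC stage layout (defaults 4000 / 1000).
#' @param exclude_at iteration at which the exclusion rule fires; set
#'   \code{exclude_threshold = 1} to disable the rule.
#' @param em_max_iter,em_tol,pev_correction passed to \code{\link{run_em}}.
#' @param g_sample_thin store post-burn-in g draws at this thinning (0 =
#'   off); see \code{\link{run_gibbs}}.
#' @param em_only return the EM state without the MCMC stage (diagnostic).
#' @param verbose print progress.
#' @return a \code{"bayesr_posterior"} (as from \code{\link{run_gibbs}})
#'   with the EM diagnostics attached as \code{$em}; or the
#'   \code{"em_state"} itself when \code{em_only = TRUE}.
#' @export
run_hybrid <- function(y, Zs, X = NULL, E_diag = 1, A = NULL, vc,
                       prior = mixture_prior(vc$sigma_g2),
                       iters = 4000, burnin = 1000, seed = NULL,
                       exclude_at = 500, exclude_threshold = 0.9,
                       em_max_iter = 5000, em_tol = 1e-10,
                       pev_correction = TRUE, em_only = FALSE,
                       g_sample_thin = 0, verbose = FALSE) {
  em <- run_em(y, Zs, X = X, E_diag = E_diag, A = A, vc = vc,
               prior = prior, max_iter = em_max_iter, tol = em_tol,
               pev_correction = pev_correction, verbose = verbose)
  if (em_only) return(em)
  start <- list(g = em$g, pr = em$pr,
                beta = if (length(em$beta)) em$beta else NULL,
                v = em$v, sigma_e2 = em$sigma_e2)
  post <- run_gibbs(y, Zs, X = X, E_diag = E_diag, A = A, vc = vc,
                    prior = prior, chains = 1, iters = iters,
                    burnin = burnin, seed = seed, start = start,
                    exclusion = exclude_threshold < 1,
                    exclude_at = exclude_at,
                    exclude_threshold = exclude_threshold,
                    g_sample_thin = g_sample_thin)
  post$method <- "hybrid"
  post$em <- em
  post$config$em_iterations <- em$iterations
  post
}
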