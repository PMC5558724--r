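#' Fit a genomic prediction model with the BayesR mixture
#'
#' One front end over the package's three inference engines for the model
#' y = X beta + Zg + Wv + e (SNP effects g from the four-component normal
#' mixture; optional pedigree polygenic effects v; heterogeneous error
#' through record weights):
#' \describe{
#'   \item{\code{"hybrid"}}{EM to convergence, then a short warm-started
#'     Gibbs chain (default 4000 iterations) with the SNP-exclusion
#'     speed-up -- the recommended engine.}
#'   \item{\code{"mcmc"}}{full BayesR Gibbs sampling (default 5 chains of
#'     40000 iterations, half discarded as burn-in).}
#'   \item{\code{"gblup"}}{linear mixed-model equations with a genomic
#'     relationship matrix; every SNP effect shrunk equally.}
#'   \item{\code{"em"}}{the EM stage alone (a MAP-style fit; diagnostic).}
#' }
#' Variance components are inputs, not estimated.
#'
#' @param y numeric phenotype vector (trait deviations), one per animal.
#' @param geno a \code{\link{geno_matrix}} or dosage matrix (animals x
#'   variants, rows aligned with \code{y}).
#' @param method inference engine, see above.
#' @param vc \code{\link{variance_components}} (sigma_g2, sigma_a2,
#'   sigma_e2).
#' @param X fixed-effect design matrix (default: intercept only). See
#'   \code{\link{build_fixed_design}}.
#' @param weights positive record weights (E = diag(1/weights)); default
#'   all 1.
#' @param pedigree pedigree data frame for the polygenic relationship
#'   matrix, used when \code{vc$sigma_a2 > 0}; default unrelated animals.
#' @param prior a \code{\link{mixture_prior}}; defaults to the standard
#'   four-component prior at \code{vc$sigma_g2}.
#' @param chains,iters,burnin MCMC layout; defaults depend on
#'   \code{method} (hybrid: 1 x 4000/1000; mcmc: 5 x 40000/20000).
#' @param seed base RNG seed.
#' @param exclude_at,exclude_threshold hybrid SNP-exclusion rule (fires at
#'   iteration 500 at spike probability 0.90 by default; threshold 1
#'   disables).
#' @param pev_correction enable the EM stage's u/PEV correction.
#' @param include_polygenic add the polygenic solution into reported GEBV.
#' @param verbose print progress.
#' @return an object of class \code{"hybbr"} with components \code{gebv},
#'   \code{g_mean} (SNP-effect posterior means; \code{NULL} for gblup),
#'   \code{P} (class-membership probabilities), \code{posterior} or
#'   \code{mme} (the engine result), \code{freq} (reference allele
#'   frequencies used for prediction), \code{map}, \code{vc}, \code{call}.
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{plot}, \code{simulate}.
#' @examples
#' sim <- sim_dataset(n = 300, m = 200, h2 = 0.4, seed = 7)
#' fit <- hybbr(sim$y, sim$Zs, method = "gblup", vc = sim$vc,
#'              X = sim$X, weights = 1 / sim$E_diag)
#' head(fitted(fit))
#' @export
hybbr <- function(y, geno, method = c("hybrid", "mcmc", "gblup", "em"),
                  vc, X = NULL, weights = NULL, pedigree = NULL,
                  prior = NULL, chains = NULL, iters = NULL,
                  burnin = NULL, seed = NULL, exclude_at = 500,
                  exclude_threshold = 0.9, pev_correction = TRUE,
                  include_polygenic = FALSE, verbose = FALSE) {
  method <- match.arg(method)
  cl <- match.call()
  n <- length(y)
  if (inherits(geno, "geno_matrix")) {
    Zs <- standardize_genotypes(geno)
    freq <- attr(Zs, "freq")
    kept <- attr(Zs, "kept")
    map <- data.frame(variant_id = geno$variant_ids[kept],
                      chrom = geno$chrom[kept],
                      pos_bp = geno$pos_bp[kept])
  } else {
    Zs <- as.matrix(geno)   # assumed already standardized
    freq <- attr(Zs, "freq")
    m0 <- ncol(Zs)
    map <- data.frame(variant_id = colnames(Zs) %||% paste0("snp", 1:m0),
                      chrom = "1", pos_bp = seq_len(m0))
  }
  stopifnot(nrow(Zs) == n)
  E_diag <- if (is.null(weights)) rep(1, n) else build_error_matrix(weights)
  A <- NULL
  if (vc$sigma_a2 > 0 && !is.null(pedigree)) {
    A_full <- build_nrm(pedigree)
    ids <- rownames(Zs)
    if (!is.null(ids) && all(ids %in% rownames(A_full)))
      A <- A_full[ids, ids]
    else if (nrow(A_full) == n) A <- A_full
    else stop("pedigree does not cover the genotyped animals")
  }
  if (is.null(prior) && method != "gblup") prior <- mixture_prior(vc$sigma_g2)

  engine <- switch(method,
    gblup = {
      G <- build_grm(Zs)
      solve_mme(y, X, G, A = A, E_diag = E_diag, vc = vc)
    },
    mcmc = run_gibbs(y, Zs, X = X, E_diag = E_diag, A = A, vc = vc,
                     prior = prior, chains = chains %||% 5,
                     iters = iters %||% 40000,
                     burnin = burnin %||% 20000, seed = seed),
    hybrid = run_hybrid(y, Zs, X = X, E_diag = E_diag, A = A, vc = vc,
                        prior = prior, iters = iters %||% 4000,
                        burnin = burnin %||% 1000, seed = seed,
                        exclude_at = exclude_at,
                        exclude_threshold = exclude_threshold,
                        pev_correction = pev_correction,
                        verbose = verbose),
    em = run_em(y, Zs, X = X, E_diag = E_diag, A = A, vc = vc,
                prior = prior, pev_correction = pev_correction,
                verbose = verbose))

  if (method == "gblup") {
    gebv <- engine$u + if (include_polygenic) engine$v else 0
    out <- list(gebv = gebv, g_mean = NULL, P = NULL, mme = engine,
                beta = engine$beta, v = engine$v,
                fitted = engine$fitted, residuals = engine$residuals)
  } else {
    g_mean <- if (method == "em") engine$g else engine$g_mean
    P <- engine$P
    v_hat <- if (method == "em") engine$v else engine$v_mean
    beta <- if (method == "em") engine$beta else engine$beta_mean
    gebv <- unname(drop(Zs %*% g_mean) + if (include_polygenic) v_hat else 0)
    fit_vals <- unname(
      (if (!is.null(X) && length(beta)) drop(X %*% beta) else 0) +
        drop(Zs %*% g_mean) + v_hat)
    out <- list(gebv = gebv, g_mean = g_mean, P = P, posterior = engine,
                beta = beta, v = v_hat, fitted = fit_vals,
                residuals = y - fit_vals)
  }
  out <- c(out, list(method = method, y = y, Zs = Zs, X = X, freq = freq,
                     map = map, vc = vc, prior = prior,
                     E_diag = E_diag, n = n, m = ncol(Zs),
                     include_polygenic = include_polygenic, call = cl))
  class(out) <- "hybbr"
  out
}

#' @export
print.hybbr <- function(x, ...) {
  cat("Genomic prediction fit (", x$method, ")\n", sep = "")
  cat("Call: ", deparse(x$call), "\n")
  cat("  animals:", x$n, " variants:", x$m, "\n")
  cat("  h2 (from variance components):", signif(x$vc$h2, 4), "\n")
  if (!is.null(x$posterior) && !is.null(x$posterior$pr_mean))
    cat("  mixture proportions:",
        paste(signif(x$posterior$pr_mean, 4), collapse = " "), "\n")
  if (!is.null(x$posterior) && !is.null(x$posterior$pr))
    cat("  mixture proportions:",
        paste(signif(x$posterior$pr, 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.hybbr <- function(object, ...) {
  arch <- if (!is.null(object$P)) architecture_summary(object$P) else NULL
  top <- NULL
  if (!is.null(object$P)) {
    q4t <- top_class_probability(list(P = object$P,
                                      g_mean = object$g_mean), object$map)
    pr4 <- if (!is.null(object$posterior$pr_mean))
      object$posterior$pr_mean else object$posterior$pr
    thr <- qtl_threshold(q4t$q4, pr4)
    top <- top_variants_report(q4t, thr)
  }
  out <- list(method = object$method, n = object$n, m = object$m,
              vc = object$vc, architecture = arch, top_variants = top,
              gebv_summary = summary(object$gebv))
  class(out) <- "summary.hybbr"
  out
}

#' @export
print.summary.hybbr <- function(x, ...) {
  cat("Genomic prediction summary (", x$method, "): ", x$n, " animals, ",
      x$m, " variants\n", sep = "")
  if (!is.null(x$architecture)) {
    cat("Variants per effect-size class (%):\n")
    print(round(x$architecture, 3))
  }
  if (!is.null(x$top_variants) && nrow(x$top_variants)) {
    cat("Top variants (largest-variance-class probability):\n")
    print(utils::head(x$top_variants, 10), row.names = FALSE)
  }
  cat("GEBV distribution:\n")
  print(x$gebv_summary)
  invisible(x)
}

#' @export
coef.hybbr <- function(object, type = c("snp", "fixed"), ...) {
  type <- match.arg(type)
  if (type == "fixed") return(object$beta)
  if (is.null(object$g_mean))
    stop("no per-SNP effects for a gblup fit; use predict() for GEBV")
  stats::setNames(object$g_mean, object$map$variant_id)
}

#' @export
fitted.hybbr <- function(object, ...) object$fitted

#' @export
residuals.hybbr <- function(object, ...) object$residuals

#' Predict GEBV for new animals
#'
#' For mixture fits, new genotypes are standardized with the reference
#' allele frequencies and multiplied by the posterior-mean SNP effects.
#' For a gblup fit the conditional-mean (relationship-matrix) predictor
#' \code{\link{predict_gebv}} is used. Variant sets must match.
#'
#' @param object a \code{hybbr} fit.
#' @param newdata \code{geno_matrix} or dosage matrix for the new animals;
#'   omitting it returns the fitted animals' GEBV.
#' @param ... unused.
#' @return numeric GEBV vector.
#' @export
predict.hybbr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$gebv)
  if (inherits(newdata, "geno_matrix")) {
    if (is.null(object$freq))
      stop("fit lacks reference allele frequencies; refit from a geno_matrix")
    if (length(object$freq) != length(newdata$variant_ids))
      stop("variant set mismatch between fit and newdata")
    Zs_new <- standardize_genotypes(newdata, freq = object$freq)
  } else {
    Zs_new <- as.matrix(newdata)
    if (ncol(Zs_new) != object$m)
      stop("variant set mismatch: newdata has ", ncol(Zs_new),
           " variants, fit has ", object$m)
  }
  if (object$method == "gblup") {
    G_vr <- tcrossprod(Zs_new, object$Zs) / object$m
    predict_gebv(object$mme, G_vr)
  } else {
    drop(Zs_new %*% object$g_mean)
  }
}

#' Manhattan-style plot of the QTL-mapping signal
#'
#' Plots each variant's posterior probability of membership in the
#' largest-variance class against genome position, with the report
#' threshold as a horizontal line. For gblup fits (no mixture) the squared
#' backsolved relationship is not available and an error is raised.
#'
#' @param x a \code{hybbr} fit from a mixture engine.
#' @param threshold \code{"auto"} (count-matched rule) or a number.
#' @param ... passed to \code{plot}.
#' @export
plot.hybbr <- function(x, threshold = "auto", ...) {
  if (is.null(x$P)) stop("no mixture posterior to plot for this fit")
  q4t <- top_class_probability(list(P = x$P, g_mean = x$g_mean), x$map)
  chr <- factor(q4t$chrom, levels = unique(q4t$chrom))
  off <- c(0, cumsum(tapply(q4t$pos_bp, chr, max)))
  gpos <- q4t$pos_bp + off[as.integer(chr)]
  graphics::plot(gpos, q4t$q4, pch = 20, cex = 0.6,
                 col = c("grey30", "steelblue")[1 + as.integer(chr) %% 2],
                 xlab = "genome position (bp)",
                 ylab = "P(largest-variance class)", ylim = c(0, 1), ...)
  if (identical(threshold, "auto")) {
    pr4 <- if (!is.null(x$posterior$pr_mean)) x$posterior$pr_mean
           else x$posterior$pr
    threshold <- qtl_threshold(q4t$q4, pr4)
  }
  graphics::abline(h = as.numeric(threshold), col = "grey60", lty = 2)
  invisible(q4t)
}

#' Simulate phenotypes from a fitted model
#'
#' Draws new phenotype vectors from the fitted conditional distribution
#' y* ~ N(X beta + Zs g + v, E sigma_e2), using the posterior-mean (or
#' BLUP) parameter values.
#'
#' @param object a \code{hybbr} fit. @param nsim number of replicates.
#' @param seed optional seed. @param ... unused.
#' @return data frame with \code{nsim} columns, one simulated y per column.
#' @export
simulate.hybbr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  se2 <- if (!is.null(object$posterior$sigma_e2_mean))
    object$posterior$sigma_e2_mean else object$vc$sigma_e2
  mu <- object$fitted
  sds <- sqrt(se2 * object$E_diag)
  out <- as.data.frame(replicate(nsim, stats::rnorm(object$n, mu, sds)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
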