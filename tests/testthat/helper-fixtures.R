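# Shared fixtures. Heavy simulation studies used by several acceptance
# checks are computed once per test run and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# dense generalized-least-squares oracle for the mixed model
# y = X beta + u + v + e,  V = G sg2 + A sa2 + E se2
gls_oracle <- function(y, X, G, A = NULL, E_diag = 1, vc) {
  n <- length(y)
  V <- vc$sigma_g2 * G + diag(rep_len(E_diag, n) * vc$sigma_e2, n)
  if (vc$sigma_a2 > 0) V <- V + vc$sigma_a2 * (if (is.null(A)) diag(n) else A)
  Vi <- solve(V)
  if (is.null(X)) {
    beta <- numeric(0)
    resid <- y
  } else {
    beta <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
    resid <- y - drop(X %*% beta)
  }
  u <- unname(drop(vc$sigma_g2 * G %*% Vi %*% resid))
  v <- if (vc$sigma_a2 > 0)
    unname(drop(vc$sigma_a2 * (if (is.null(A)) diag(n) else A) %*%
                  Vi %*% resid))
  else numeric(n)
  list(beta = unname(beta), u = u, v = v)
}

# small standardized genotype matrix with exact column standardization
small_Zs <- function(n, m, seed = 1) {
  set.seed(seed)
  g <- simulate_genotypes(n, m, maf = 0.2, seed = seed)
  standardize_genotypes(g)
}

# default-architecture scenario used by the hybrid-vs-MCMC and
# architecture-recovery studies (a desk-scale rendition of the reference
# population: 0.99/0.007/0.002/0.001 mixture, h2 = 0.4)
default_scenario <- function(seed, n = 800, m = 2000, n_val = 150) {
  sim_dataset(n = n, m = m, h2 = 0.4,
              pr_true = c(0.99, 0.007, 0.002, 0.001),
              n_val = n_val, seed = seed)
}

hybrid_on_scenario <- function(sim, seed = 1, ...) {
  ref <- sim$ref
  run_hybrid(sim$y[ref], sim$Zs[ref, , drop = FALSE],
             X = sim$X[ref, , drop = FALSE],
             E_diag = sim$E_diag[ref], vc = sim$vc, seed = seed, ...)
}

# ten hybrid replicates on the default scenario (also feeds the
# architecture-recovery check); replicate 1 additionally carries the full
# long-chain BayesR run for the equivalence check
shared_hybrid_reps <- function() {
  memo("hybrid_reps", {
    lapply(1:10, function(r) {
      sim <- default_scenario(seed = 100 + r)
      hy <- suppressWarnings(hybrid_on_scenario(sim, seed = 500 + r))
      list(sim = sim, hybrid = hy)
    })
  })
}

# high-heritability bull-only study where the spike class is identifiable
# enough for the SNP-exclusion rule to fire (shared with the exclusion
# contract checks)
exclusion_run <- function() {
  memo("exclusion_run", {
    sim <- sim_dataset(n = 2000, m = 1500, h2 = 0.9, sex_mix = 1,
                       pr_true = c(0.995, 0.002, 0.002, 0.001), seed = 90)
    hy <- suppressWarnings(
      run_hybrid(sim$y, sim$Zs, X = sim$X, E_diag = sim$E_diag,
                 vc = sim$vc, iters = 1200, burnin = 600, seed = 44,
                 g_sample_thin = 1))
    list(sim = sim, hybrid = hy)
  })
}

shared_full_chain <- function() {
  memo("full_chain", {
    sim <- shared_hybrid_reps()[[1]]$sim
    ref <- sim$ref
    run_gibbs(sim$y[ref], sim$Zs[ref, , drop = FALSE],
              X = sim$X[ref, , drop = FALSE], E_diag = sim$E_diag[ref],
              vc = sim$vc, chains = 1, iters = 15000, burnin = 7500,
              seed = 900)
  })
}
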