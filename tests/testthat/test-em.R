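test_that("PEV correction scalars equal the per-variant trace term", {
  Zs <- small_Zs(12, 8, seed = 44)
  E_diag <- runif(12, 0.5, 2)
  # zero PEV gives zero correction
  expect_equal(precompute_pev_correction(Zs, E_diag, matrix(0, 12, 12)),
               rep(0, 8))
  # identity PEV with E = I gives the squared column norms
  expect_equal(precompute_pev_correction(Zs, 1, diag(12)),
               unname(colSums(Zs^2)))
  # dense PEV against a brute-force trace on each variant
  P <- crossprod(matrix(rnorm(144), 12, 12)) / 12
  pc <- precompute_pev_correction(Zs, E_diag, P)
  for (i in c(1, 5, 8)) {
    Ei <- diag(1 / E_diag)
    brute <- sum(diag(Ei %*% Zs[, i] %*% t(Zs[, i]) %*% Ei %*% P))
    expect_equal(pc[i], brute, tolerance = 1e-10)
  }
  expect_error(precompute_pev_correction(Zs, E_diag, diag(5)), "must be")
})

test_that("single-SNP EM update: spike-only, ridge and quadrature oracles", {
  set.seed(61)
  z <- rnorm(40); e <- rnorm(40) + 0.3 * z
  # spike-only prior pins the effect at zero with full responsibility
  sp <- em_update_snp(z, e, 0.2, mixture_prior(1, pr_start = c(1, 0, 0, 0)),
                      sigma_e2 = 1)
  expect_equal(sp$P, c(1, 0, 0, 0))
  expect_equal(sp$g, 0)
  # degenerate slab with no PEV term is the closed-form ridge estimate
  pr4 <- mixture_prior(2, pr_start = c(0, 0, 0, 1))
  up <- em_update_snp(z, e, 0.1, pr4, sigma_e2 = 0.8)
  l <- sum(z^2); r <- sum(z * e) + l * 0.1
  expect_equal(up$g, r / (l + 0.8 / (0.01 * 2)), tolerance = 1e-12)
  # responsibilities match posterior class probabilities from numerical
  # integration of the single-SNP model over (g, class)
  prior <- mixture_prior(1.5, pr_start = c(0.4, 0.3, 0.2, 0.1))
  up2 <- em_update_snp(z, e, 0, prior, sigma_e2 = 1)
  base <- sum(dnorm(e, 0, 1, log = TRUE))   # stabilizes the integrand
  marg <- function(k) {
    if (k == 1) return(prior$pr[1])
    f <- function(g) vapply(g, function(gi)
      exp(sum(dnorm(e - z * gi, 0, 1, log = TRUE)) - base) *
        dnorm(gi, 0, sqrt(prior$gamma[k] * prior$sigma_g2)), 0)
    prior$pr[k] * integrate(f, -1, 1, rel.tol = 1e-10,
                            abs.tol = 1e-14)$value
  }
  mk <- vapply(1:4, marg, 0)
  expect_equal(up2$P, mk / sum(mk), tolerance = 1e-6)
})

test_that("Dirichlet-MAP proportion update", {
  # uniform prior: column means of the responsibilities
  P <- rbind(c(0.5, 0.5, 0, 0), c(0, 0.5, 0.5, 0))
  expect_equal(em_update_proportions(P), c(0.25, 0.5, 0.25, 0))
  P1 <- matrix(rep(c(1, 0, 0, 0), 5), 5, 4, byrow = TRUE)
  expect_equal(em_update_proportions(P1), c(1, 0, 0, 0))
  # informative prior shifts the MAP
  expect_equal(em_update_proportions(P1, alpha = c(1, 6, 1, 1)),
               c(0.5, 0.5, 0, 0))
  expect_error(em_update_proportions(P[0, ]), "no SNPs")
})

test_that("convergence criterion is the relative squared change, strict", {
  expect_true(check_convergence(c(1, 2), c(1, 2))$converged)
  cc <- check_convergence(c(1, 0), c(0, 0))
  expect_equal(cc$stat, 1)
  expect_false(cc$converged)
  # boundary: a stat exactly equal to the threshold is NOT converged
  # (strict <), checked by using the measured stat as the threshold
  cb <- check_convergence(c(1, 0), c(1 - 2e-5, 0))
  expect_false(check_convergence(c(1, 0), c(1 - 2e-5, 0),
                                 tol = cb$stat)$converged)
  expect_true(check_convergence(c(1, 0), c(1 - 2e-5, 0),
                                tol = cb$stat * (1 + 1e-12))$converged)
  expect_true(check_convergence(c(0, 0), c(1, 1))$converged)  # convention
})

test_that("EM fixed point equals ridge/MME with a single class, no PEV", {
  set.seed(71)
  n <- 100; m <- 200
  Zs <- small_Zs(n, m, seed = 71)
  g_true <- rnorm(m, 0, 0.08)
  y <- drop(Zs %*% g_true) + rnorm(n)
  vc <- variance_components(1, 0, 1)
  prior <- mixture_prior(1, pr_start = c(0, 0, 0, 1),
                         alpha = c(1e-8, 1e-8, 1e-8, 1))
  em <- run_em(y, Zs, vc = vc, prior = prior, pev_correction = FALSE,
               update_sigma_e2 = FALSE, max_iter = 5000)
  expect_true(em$converged)
  lam <- vc$sigma_e2 / (prior$gamma[4] * vc$sigma_g2)
  ridge <- drop(solve(crossprod(Zs) + diag(lam, m), crossprod(Zs, y)))
  expect_lt(max(abs(em$g - ridge)), 1e-6)
})

test_that("EM null limit and planted-QTL detection", {
  set.seed(81)
  # pure noise: effects collapse, spike proportion grows toward 1
  Zs <- small_Zs(200, 150, seed = 81)
  vc <- variance_components(0.4, 0, 1)
  em0 <- suppressWarnings(run_em(rnorm(200), Zs, vc = vc,
                                 pev_correction = FALSE, max_iter = 3000))
  expect_lt(max(abs(em0$g)), 0.05)
  expect_gt(em0$pr[1] + em0$pr[2], 0.9)
  # one large-effect SNP: its top-class responsibility goes to ~1
  g_true <- rep(0, 150); g_true[42] <- 0.8
  vc1 <- variance_components(0.64, 0, 0.5)
  y1 <- drop(Zs %*% g_true) + rnorm(200, sd = sqrt(0.5))
  em1 <- run_em(y1, Zs, vc = vc1, pev_correction = TRUE, max_iter = 3000)
  expect_gt(em1$P[42, 4], 0.95)
  expect_equal(which.max(abs(em1$g)), 42L)
})

test_that("the EM objective is non-decreasing (exact configuration)", {
  for (s in 1:3) {
    sim <- sim_dataset(n = 200, m = 250, h2 = 0.4,
                       pr_true = c(0.9, 0.05, 0.03, 0.02), seed = 300 + s)
    em <- run_em(sim$y, sim$Zs, X = sim$X, E_diag = sim$E_diag,
                 vc = sim$vc, pev_correction = FALSE, max_iter = 2000)
    expect_equal(em$monotone_violations, 0)
    expect_true(all(diff(em$objective_trace) > -1e-6))
  }
})

test_that("EM initialization follows the documented starting values", {
  # one iteration from a fresh start must see g = 0.01 everywhere and
  # Pr = {0.5, 0.487, 0.01, 0.003}: verify through the mixture_prior
  # default and the first convergence statistic
  pr <- mixture_prior(1)
  expect_equal(pr$pr, c(0.5, 0.487, 0.01, 0.003))
  Zs <- small_Zs(50, 20, seed = 2)
  em <- suppressWarnings(run_em(rnorm(50), Zs,
                                vc = variance_components(1, 0, 1),
                                pev_correction = FALSE, max_iter = 1))
  # after a single sweep the change statistic is measured against the
  # g = 0.01 start, so it cannot be the converged state
  expect_false(em$converged)
  expect_equal(em$iterations, 1L)
})
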