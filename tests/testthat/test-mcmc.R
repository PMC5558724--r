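test_that("degenerate spike prior always samples the spike", {
  set.seed(1)
  z <- rnorm(50); e <- rnorm(50)
  pr <- mixture_prior(1, pr_start = c(1, 0, 0, 0))
  for (i in 1:5) {
    up <- sample_snp_effect(z, e, 0.3, pr, sigma_e2 = 1)
    expect_equal(up$class, 1L)
    expect_equal(up$g, 0)
  }
  expect_error(sample_snp_effect(c(z[-1], NA), e, 0, pr, 1), "NaN")
})

test_that("slab draws follow the conjugate normal full conditional", {
  set.seed(42)
  n <- 80
  z <- rnorm(n); e0 <- rnorm(n, sd = 0.8); E_diag <- runif(n, 0.5, 2)
  einv <- 1 / E_diag
  se2 <- 0.9
  prior <- mixture_prior(2, pr_start = c(0, 0, 0, 1))  # forced class 4
  l <- sum(z^2 * einv)
  r <- sum(z * einv * e0)          # g_old = 0
  denom <- l + se2 / (prior$gamma[4] * prior$sigma_g2)
  mu <- r / denom; s2 <- se2 / denom
  nd <- 20000
  draws <- vapply(seq_len(nd), function(i)
    sample_snp_effect(z, e0, 0, prior, se2, E_diag)$g, 0)
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(s2 / nd))
  expect_lt(abs(var(draws) - s2), 3 * s2 * sqrt(2 / (nd - 1)))
})

test_that("class frequencies match the analytic four-term conditional", {
  set.seed(7)
  n <- 60
  z <- rnorm(n); e0 <- rnorm(n) + 0.25 * z
  prior <- mixture_prior(1.5, pr_start = c(0.4, 0.3, 0.2, 0.1))
  up1 <- sample_snp_effect(z, e0, 0, prior, 1)
  # analytic full conditional, spelled out independently of the sampler
  l <- sum(z^2); r <- sum(z * e0)
  vark <- l^2 * prior$gamma * prior$sigma_g2 + l * 1
  lw <- log(prior$pr) - 0.5 * log(vark) - 0.5 * r^2 / vark
  pk <- exp(lw - max(lw)); pk <- pk / sum(pk)
  expect_equal(up1$post_prob, pk, tolerance = 1e-12)
  nd <- 20000
  cls <- vapply(seq_len(nd), function(i)
    sample_snp_effect(z, e0, 0, prior, 1)$class, 0L)
  freq <- tabulate(cls, 4) / nd
  expect_true(all(abs(freq - pk) < 3 * sqrt(pk * (1 - pk) / nd) + 1e-4))
})

test_that("mixture proportions are Dirichlet(alpha + counts)", {
  set.seed(5)
  d0 <- t(replicate(4000, sample_mixture_proportions(c(0, 0, 0, 0))))
  expect_true(all(abs(colMeans(d0) - 0.25) < 0.02))
  expect_equal(rowSums(d0), rep(1, 4000))
  d1 <- t(replicate(4000, sample_mixture_proportions(c(4, 0, 0, 0))))
  expect_true(all(abs(colMeans(d1) - c(5, 1, 1, 1) / 8) < 0.02))
  expect_error(sample_mixture_proportions(c(-1, 0, 0, 0)), "negative")
})

test_that("polygenic full conditional: scalar conjugate and BLUP mean", {
  set.seed(9)
  # sigma_a2 = 0 is deterministic zero
  z0 <- sample_polygenic(rnorm(5), rnorm(5), sigma_a2 = 0, sigma_e2 = 1)
  expect_equal(z0$v, rep(0, 5))
  # A = I, E = I: independent normals, variance (1/se2 + 1/sa2)^-1
  n <- 4; sa2 <- 0.5; se2 <- 2
  e <- rnorm(n); v_old <- rnorm(n)
  rv <- e + v_old
  s2 <- 1 / (1 / se2 + 1 / sa2)
  mu <- s2 * rv / se2
  draws <- t(replicate(8000, sample_polygenic(e, v_old, E_diag = 1,
                                              sigma_a2 = sa2,
                                              sigma_e2 = se2)$v))
  expect_true(all(abs(colMeans(draws) - mu) < 4 * sqrt(s2 / 8000)))
  expect_true(all(abs(apply(draws, 2, var) - s2) < 4 * s2 * sqrt(2 / 8000)))
  # correlated A on a 3-animal toy: mean equals the MME/BLUP solution
  A <- matrix(c(1, 0.5, 0.25, 0.5, 1, 0.5, 0.25, 0.5, 1), 3, 3)
  e3 <- c(0.4, -0.1, 0.3); v3 <- c(0, 0, 0); E3 <- c(1, 2, 0.5)
  blup <- solve(diag(1 / E3) / se2 + solve(A) / sa2,
                (1 / E3) * (e3 + v3) / se2)
  dm <- rowMeans(replicate(8000, sample_polygenic(e3, v3, A, E3, sa2,
                                                  se2)$v))
  expect_true(all(abs(dm - drop(blup)) < 0.05))
})

test_that("residual variance follows the scaled inverse chi-square", {
  set.seed(3)
  e <- rnorm(1000, sd = sqrt(2))
  draws <- replicate(4000, sample_residual_variance(e))
  # flat prior: posterior mean ss/(n - 4); with n = 1000 this is ~ var(e)
  expect_lt(abs(mean(draws) / 2 - 1), 0.05)
  # E = 2I halves the effective sum of squares
  set.seed(11); a <- sample_residual_variance(e, E_diag = 2)
  set.seed(11); b <- sample_residual_variance(e, E_diag = 1)
  expect_equal(a, b / 2, tolerance = 1e-12)
  expect_error(sample_residual_variance(numeric(0)), "degrees|sum")
})

test_that("pure-noise data leaves effects near zero", {
  set.seed(14)
  Zs <- small_Zs(150, 120, seed = 14)
  y <- rnorm(150)
  vc <- variance_components(0.5, 0, 1)
  post <- run_gibbs(y, Zs, vc = vc, chains = 1, iters = 1500, burnin = 500,
                    seed = 5)
  expect_lt(max(abs(post$g_mean)), 0.12)
  expect_lt(sd(post$gebv), 0.5 * sd(y))
  expect_equal(rowSums(post$P), rep(1, 120))
})

test_that("single-class sampler converges to the ridge/BLUP solution", {
  set.seed(16)
  n <- 120; m <- 60
  Zs <- small_Zs(n, m, seed = 16)
  g_true <- rnorm(m, 0, sqrt(0.01))
  y <- drop(Zs %*% g_true) + rnorm(n, sd = 0.7)
  vc <- variance_components(1, 0, 0.49)
  prior <- mixture_prior(1, alpha = c(1e-6, 1e-6, 1e-6, 1),
                         pr_start = c(0, 0, 0, 1))
  post <- run_gibbs(y, Zs, vc = vc, prior = prior, chains = 1,
                    iters = 6000, burnin = 1000, seed = 2)
  lam <- vc$sigma_e2 / (prior$gamma[4] * vc$sigma_g2)
  ridge <- drop(solve(crossprod(Zs) + diag(lam, m), crossprod(Zs, y)))
  expect_gt(cor(post$g_mean, ridge), 0.99)
  expect_lt(max(abs(post$g_mean - ridge)), 0.05)
})

test_that("maintained residuals never drift from recomputed ones", {
  sim <- sim_dataset(n = 200, m = 150, h2 = 0.4,
                     pr_true = c(0.9, 0.05, 0.03, 0.02), seed = 77)
  post <- run_gibbs(sim$y, sim$Zs, X = sim$X, E_diag = sim$E_diag,
                    vc = sim$vc, chains = 1, iters = 2048, burnin = 512,
                    seed = 8)
  expect_equal(post$chains[[1]]$drift_events, 0)
})

test_that("SNP input order does not change the posterior", {
  sim <- sim_dataset(n = 250, m = 120, h2 = 0.5,
                     pr_true = c(0.8, 0.1, 0.05, 0.05), seed = 31)
  perm <- sample(120)
  p1 <- run_gibbs(sim$y, sim$Zs, vc = sim$vc, chains = 1, iters = 4000,
                  burnin = 1000, seed = 9)
  p2 <- run_gibbs(sim$y, sim$Zs[, perm], vc = sim$vc, chains = 1,
                  iters = 4000, burnin = 1000, seed = 10)
  # posterior means agree up to Monte-Carlo error (not bitwise)
  expect_gt(cor(p1$g_mean[perm], p2$g_mean), 0.95)
  expect_lt(max(abs(p1$pr_mean - p2$pr_mean)), 0.06)
  expect_gt(cor(p1$gebv, p2$gebv), 0.99)
})

test_that("posterior intervals for g are calibrated on a small prior draw", {
  # simulation-based check: truth drawn from the model's own prior, then
  # 90% central posterior intervals should cover ~90% of the time
  set.seed(55)
  n <- 100; m <- 50
  Zs <- small_Zs(n, m, seed = 55)
  vc <- variance_components(1, 0, 1)
  hits <- 0; tot <- 0
  for (rep in 1:60) {
    pr_true <- as.vector(rgamma(4, 1)); pr_true <- pr_true / sum(pr_true)
    cls <- sample.int(4, m, TRUE, pr_true)
    gt <- ifelse(cls == 1, 0,
                 rnorm(m, 0, sqrt(c(0, 1e-4, 1e-3, 1e-2)[cls] * 1)))
    y <- drop(Zs %*% gt) + rnorm(n, sd = 1)
    post <- run_gibbs(y, Zs, vc = vc, chains = 1, iters = 1200,
                      burnin = 400, seed = 1000 + rep, g_sample_thin = 2)
    qs <- apply(post$chains[[1]]$g_samples, 2, quantile,
                probs = c(0.05, 0.95))
    hits <- hits + sum(gt >= qs[1, ] & gt <= qs[2, ])
    tot <- tot + m
  }
  expect_gt(hits / tot, 0.85)
  expect_lt(hits / tot, 0.95)
})
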