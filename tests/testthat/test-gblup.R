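test_that("MME solution equals the dense GLS oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    Zs <- small_Zs(n, 60, seed = 21 + rep)
    G <- build_grm(Zs)
    A <- diag(n)
    E_diag <- runif(n, 0.5, 2)
    X <- cbind(1, rnorm(n))
    vc <- variance_components(sigma_g2 = runif(1, 0.5, 2),
                              sigma_a2 = runif(1, 0, 1),
                              sigma_e2 = runif(1, 0.5, 2))
    y <- rnorm(n, sd = 2)
    sol <- solve_mme(y, X, G, A = A, E_diag = E_diag, vc = vc)
    ora <- gls_oracle(y, X, G, A = A, E_diag = E_diag, vc = vc)
    expect_equal(sol$beta, ora$beta, tolerance = 1e-8)
    expect_equal(sol$u, ora$u, tolerance = 1e-8)
    expect_equal(sol$v, ora$v, tolerance = 1e-8)
  }
})

test_that("zero variances shrink the corresponding effects to nothing", {
  n <- 12
  Zs <- small_Zs(n, 30, seed = 3)
  G <- build_grm(Zs)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  E_diag <- runif(n, 0.5, 2)
  vc0 <- variance_components(0, 0, 1.3)
  sol <- solve_mme(y, X, G, E_diag = E_diag, vc = vc0)
  expect_equal(sol$u, rep(0, n))
  expect_equal(sol$v, rep(0, n))
  # beta reduces to weighted least squares
  W <- diag(1 / E_diag)
  beta_wls <- drop(solve(t(X) %*% W %*% X, t(X) %*% W %*% y))
  expect_equal(sol$beta, beta_wls, tolerance = 1e-10)
})

test_that("duplicate animals with identical records get identical u", {
  Zs <- small_Zs(8, 40, seed = 6)
  Zs <- rbind(Zs, Zs[1, ])          # animal 9 clones animal 1
  y <- rnorm(8); y <- c(y, y[1])
  G <- build_grm(Zs)
  vc <- variance_components(1, 0, 1)
  sol <- solve_mme(y, NULL, G, vc = vc)
  expect_equal(sol$u[9], sol$u[1], tolerance = 1e-8)
})

test_that("PEV limits: prior variance with no data, zero with exact data", {
  n <- 6
  Zs <- small_Zs(n, 30, seed = 9)
  G <- build_grm(Zs)
  vc <- variance_components(1.5, 0, 1)
  # E -> infinity (E^-1 -> 0): no information, PEV = sigma_g2 * G
  sol_no <- solve_mme(rep(0, n), NULL, G, E_diag = rep(1e12, n), vc = vc)
  expect_equal(compute_pev_u(sol_no), 1.5 * G, tolerance = 1e-3)
  # essentially exact records: PEV -> 0
  sol_inf <- solve_mme(rnorm(n), NULL, G, E_diag = rep(1e-10, n), vc = vc)
  expect_lt(max(abs(compute_pev_u(sol_inf))), 1e-6)
})

test_that("PEV matches the joint-normal conditional variance on a toy", {
  G <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  vc <- variance_components(2, 0, 1)
  y <- c(0.3, -0.2)
  sol <- solve_mme(y, NULL, G, vc = vc)
  # u, y jointly normal: Var(u | y) = sg2 G - sg2 G (sg2 G + se2 I)^-1 G sg2
  V <- 2 * G + diag(2)
  cond <- 2 * G - (2 * G) %*% solve(V) %*% (2 * G)
  expect_equal(compute_pev_u(sol), cond, tolerance = 1e-8)
  # and the solution is the conditional mean
  expect_equal(sol$u, drop(2 * G %*% solve(V) %*% y), tolerance = 1e-10)
})

test_that("PEV diagonal shrinks as records are added", {
  Zs <- small_Zs(10, 50, seed = 12)
  G <- build_grm(Zs)
  vc <- variance_components(1, 0, 1)
  y <- rnorm(10)
  # removing information = inflating the error variance of 5 records
  E_more <- rep(1, 10)
  E_less <- c(rep(1, 5), rep(1e8, 5))
  pev_more <- diag(compute_pev_u(solve_mme(y, NULL, G, E_diag = E_more,
                                           vc = vc)))
  pev_less <- diag(compute_pev_u(solve_mme(y, NULL, G, E_diag = E_less,
                                           vc = vc)))
  expect_true(all(pev_more <= pev_less + 1e-10))
})

test_that("validation prediction is the conditional mean", {
  Zs <- small_Zs(9, 60, seed = 30)
  ref <- 1:6; val <- 7:9
  Gall <- build_grm(Zs, ridge = 0)
  G <- Gall[ref, ref] + diag(1e-6, 6)
  vc <- variance_components(1, 0, 0.8)
  y <- rnorm(6)
  sol <- solve_mme(y, NULL, G, vc = vc)
  pred <- predict_gebv(sol, Gall[val, ref])
  expect_equal(pred, unname(drop(Gall[val, ref] %*% solve(G, sol$u))),
               tolerance = 1e-12)
  # a validation animal genotypically identical to a reference animal
  # recovers that animal's u
  pred_same <- predict_gebv(sol, Gall[ref[2], ref, drop = FALSE] +
                              c(0, 1e-6, 0, 0, 0, 0))
  expect_equal(pred_same, sol$u[2], tolerance = 1e-4)
  # u = 0 predicts 0
  sol0 <- solve_mme(rep(0, 6), NULL, G, vc = vc)
  expect_equal(predict_gebv(sol0, Gall[val, ref]), rep(0, 3))
  expect_error(predict_gebv(sol, Gall[val, 1:5]), "mismatch")
})
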