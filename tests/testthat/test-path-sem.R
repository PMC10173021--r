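test_that("implied covariance reduces to known closed forms", {
  # no structure at all: block diagonal
  Phi <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  Sig <- implied_covariance(B = matrix(0, 3, 3), Gamma = matrix(0, 3, 2),
                            Psi = c(1, 2, 3), Phi = Phi)
  expect_equal(Sig[1:2, 1:2], Phi, ignore_attr = TRUE)
  expect_equal(Sig[3:5, 3:5], diag(c(1, 2, 3)), ignore_attr = TRUE)
  expect_true(all(Sig[1:2, 3:5] == 0))
  # chain x -> m -> y with unit variances and both coefficients 0.5
  B <- matrix(0, 3, 3, dimnames = rep(list(c("x", "m", "y")), 2))
  B["m", "x"] <- 0.5; B["y", "m"] <- 0.5
  Sig <- implied_covariance(B, Gamma = matrix(0, 3, 0), Psi = c(1, 1, 1),
                            Phi = matrix(0, 0, 0))
  expect_equal(Sig["y", "x"], 0.25)
  expect_equal(Sig["m", "x"], 0.5)
  expect_equal(Sig["m", "m"], 1.25)
  expect_error(implied_covariance(B, matrix(0, 2, 1), c(1, 1, 1),
                                  diag(1)), "dimensions")
})

test_that("implied covariance matches Monte-Carlo simulation", {
  set.seed(7)
  q <- 3L; k <- 2L; n <- 5e5
  B <- matrix(0, q, q); B[2, 1] <- 0.6; B[3, 1] <- -0.4; B[3, 2] <- 0.5
  G <- matrix(runif(q * k, -0.5, 0.5), q, k)
  Psi <- c(1, 0.8, 1.2)
  Phi <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  X <- matrix(rnorm(n * k), n, k) %*% chol(Phi)
  Y <- matrix(0, n, q)
  for (j in seq_len(q))
    Y[, j] <- X %*% G[j, ] + Y %*% B[j, ] + rnorm(n, sd = sqrt(Psi[j]))
  S_mc <- cov(cbind(X, Y))
  Sig <- implied_covariance(B, G, Psi, Phi)
  expect_lt(max(abs(S_mc - Sig)), 4 * max(diag(Sig)) * sqrt(2 / n) * 3)
})

test_that("saturated recursive model recovers F_ML = 0 and OLS estimates", {
  sim <- simulate_dag_data(random_dag(4, p_edge = 1, seed = 3), n = 800,
                           seed = 3)
  dag <- random_dag(4, p_edge = 1, seed = 3)
  fit <- fit_ml(sim$data, dag, se = "naive")
  expect_lt(fit$fml, 1e-10)
  expect_lt(fit$T, 1e-6)
  expect_identical(fit$df, 0)
  expect_true(fit$converged)
  # per-equation OLS oracle
  for (node in dag$endogenous[-1L]) {
    par <- c(dag$edges[dag$edges[, "to"] == node, "from"], dag$covariates)
    ols <- coef(lm(stats::reformulate(par, node), data = sim$data))[par]
    got <- fit$coef[paste0(node, "~", par)]
    expect_lt(max(abs(unname(got) - unname(ols))), 1e-6)
  }
  # saturated model: indices at their limits
  fi <- fit$fit_indices
  expect_equal(fi$rmsea, 0)
  expect_lt(fi$srmr, 1e-8)
  expect_equal(fi$gfi, 1, tolerance = 1e-8)
  expect_equal(fi$cfi, 1)
})

test_that("over-identified fits also equal the factorized OLS solution", {
  # the likelihood of a recursive diagonal-residual model factorizes, so the
  # quasi-Newton optimum must match per-equation least squares
  dag <- random_dag(5, p_edge = 0.5, seed = 11)
  sim <- simulate_dag_data(dag, n = 1500, seed = 11)
  fit <- fit_ml(sim$data, dag, se = "naive")
  expect_true(fit$converged)
  for (node in dag$endogenous[-1L]) {
    par <- c(dag$edges[dag$edges[, "to"] == node, "from"], dag$covariates)
    if (!length(par)) next
    ols <- coef(lm(stats::reformulate(par, node), data = sim$data))[par]
    expect_lt(max(abs(unname(fit$coef[paste0(node, "~", par)]) -
                      unname(ols))), 1e-6)
  }
  expect_gt(fit$df, 0)
  expect_gte(fit$T, 0)
})

test_that("parameters are recovered within robust SEs on generated data", {
  cfg <- small_config(seed = 61L, scale = 0.5)
  gt <- config_ground_truth(cfg)
  dag <- default_dag("all")
  tab <- binarize_sep(generate_registry(cfg))
  fit <- fit_ml(tab, dag, se = "robust", scaling = "none")
  en <- ohcapath:::edge_coef_names(dag)
  truth <- gt$B_true[cbind(dag$edges[, "to"], dag$edges[, "from"])]
  se <- sqrt(diag(fit$vcov_coef))[en]
  expect_true(all(abs(fit$coef[en] - truth) < 3.5 * se))
})

test_that("the test statistic has power against an omitted edge", {
  dag_gen <- dag_spec(c("x", "m", "y"),
                      rbind(c("x", "m"), c("m", "y"), c("x", "y")),
                      covariates = "c1")
  dag_fit <- dag_spec(c("x", "m", "y"), rbind(c("x", "m"), c("m", "y")),
                      covariates = "c1")
  Ts <- vapply(c(2000L, 8000L), function(n) {
    sim <- simulate_dag_data(dag_gen, n = n, seed = 5)
    fit_ml(sim$data, dag_fit, se = "naive")$T
  }, numeric(1))
  expect_gt(Ts[1L], 20)               # misfit detected
  expect_gt(Ts[2L] / Ts[1L], 2)       # grows roughly linearly in N
  expect_lt(Ts[2L] / Ts[1L], 8)
})

test_that("fit is invariant to row shuffling and equivariant to rescaling", {
  dag <- random_dag(4, p_edge = 0.7, seed = 21)
  sim <- simulate_dag_data(dag, n = 600, seed = 21)
  f1 <- fit_ml(sim$data, dag, se = "naive")
  f2 <- fit_ml(sim$data[sample(nrow(sim$data)), ], dag, se = "naive")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  expect_equal(f1$T, f2$T, tolerance = 1e-8)
  # rescale one endogenous variable: coefficients transform as c_y / c_x
  d2 <- sim$data
  d2$m1 <- d2$m1 * 10
  f3 <- fit_ml(d2, dag, se = "naive")
  nm_in <- grep("^m1~", names(f1$coef), value = TRUE)
  expect_equal(unname(f3$coef[nm_in]), unname(10 * f1$coef[nm_in]),
               tolerance = 1e-6)
  nm_out <- grep("~m1$", names(f1$coef), value = TRUE)
  expect_equal(unname(f3$coef[nm_out]), unname(f1$coef[nm_out] / 10),
               tolerance = 1e-6)
})

test_that("fit index formulas match their closed forms", {
  fake <- list(S = diag(2), Sigma = diag(2), N = 1001, T = 100, df = 50,
               scaling_c = NULL)
  fi <- fit_indices(fake, baseline = list(T = 1000, df = 60))
  expect_equal(fi$rmsea, sqrt(0.001))
  expect_equal(fi$cfi, 1 - 50 / 940)
  expect_equal(fi$srmr, 0)
  expect_equal(fi$gfi, 1)
  # df = 0: RMSEA defined as 0, CFI as 1
  fake$df <- 0; fake$T <- 0
  fi0 <- fit_indices(fake, baseline = list(T = 1000, df = 60))
  expect_equal(fi0$rmsea, 0)
  expect_equal(fi0$cfi, 1)
  # scaled variants reduce to the plain ones when c = 1
  fake <- list(S = diag(2), Sigma = diag(2), N = 1001, T = 100, df = 50,
               scaling_c = 1)
  fis <- fit_indices(fake, baseline = list(T = 1000, df = 60,
                                           T_scaled = 1000))
  expect_equal(fis$rmsea_scaled, fis$rmsea)
  expect_equal(fis$cfi_scaled, fis$cfi)
})

test_that("mean-adjusted scaling is near 1 for normal data", {
  dag <- random_dag(4, p_edge = 0.6, seed = 31)
  sim <- simulate_dag_data(dag, n = 4000, seed = 31)
  fit <- fit_ml(sim$data, dag, se = "robust", scaling = "mean_adjusted")
  expect_gt(fit$scaling_c, 0.75)
  expect_lt(fit$scaling_c, 1.3)
  expect_equal(fit$T_scaled, fit$T / fit$scaling_c)
  expect_true(is.finite(fit$fit_indices$rmsea_scaled))
})

test_that("robust coefficient covariance is symmetric positive semidefinite", {
  dag <- random_dag(4, p_edge = 0.8, seed = 41)
  sim <- simulate_dag_data(dag, n = 700, seed = 41)
  fit <- fit_ml(sim$data, dag, se = "robust")
  V <- fit$vcov_coef
  expect_equal(V, t(V), tolerance = 1e-10)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
})

test_that("degenerate inputs are rejected", {
  dag <- random_dag(3, p_edge = 1, seed = 1, k_cov = 1)
  S <- diag(4); S[1, 2] <- S[2, 1] <- 1   # singular
  expect_error(fit_ml(S = S, N = 100, dag = dag), "positive definite")
  sim <- simulate_dag_data(dag, n = 30, seed = 1)
  expect_error(fit_ml(S = cov(sim$data), N = 5, dag = dag), "exceed")
  sim$data$x[1] <- NA
  expect_error(fit_ml(sim$data, dag), "missing")
})
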