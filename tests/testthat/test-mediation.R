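test_that("two-edge chain gives the product of coefficients", {
  fit <- manual_chain_fit(a = 0.5, b = 0.4, d = 0.1)
  pe <- pathway_effect(fit, through = "m")
  expect_equal(pe$effect, 0.20)
  td <- total_and_direct(fit)
  expect_equal(td$total, 0.30)
  expect_equal(td$direct, 0.10)
  expect_equal(td$indirect_sum, 0.20)
})

test_that("delta-method SEs match closed forms on the chain fixture", {
  a <- 0.5; b <- 0.4; va <- 0.01; vb <- 0.02; cab <- 0.003
  fit <- manual_chain_fit(a = a, b = b, d = 0.1, va = va, vb = vb,
                          cab = cab, vd = 0.005)
  pe <- pathway_effect(fit, through = "m")
  want <- sqrt(b^2 * va + a^2 * vb + 2 * a * b * cab)
  expect_equal(pe$se, want, tolerance = 1e-12)
  # single-edge selector: the direct path SE equals that coefficient's SE
  pd <- pathway_effect(fit, through = "direct")
  expect_equal(pd$se, sqrt(0.005), tolerance = 1e-12)
  expect_equal(pd$effect, 0.1)
})

test_that("mediation proportion is the exact percentage ratio", {
  expect_equal(mediation_proportion(-0.005, -0.032), 15.625)
  expect_equal(mediation_proportion(0, -0.032), 0)
  expect_equal(mediation_proportion(-0.032, -0.032), 100)
  expect_error(mediation_proportion(-0.005, 0), "undefined")
})

test_that("decomposition identity holds exactly for random fitted models", {
  for (s in 1:6) {
    dag <- random_dag(m = 5L, p_edge = 0.6, seed = 400 + s)
    sim <- simulate_dag_data(dag, n = 400, seed = 400 + s)
    fit <- fit_ml(sim$data, dag, se = "naive")
    td <- total_and_direct(fit)
    expect_lt(abs(td$total - td$direct - td$indirect_sum), 1e-10)
    q <- length(dag$endogenous)
    A <- solve(diag(q) - fit$B)
    expect_equal(td$total, A[q, 1L], tolerance = 1e-12)
  }
})

test_that("exclusion selectors drop exactly the right paths", {
  dag <- default_dag("all")
  cfg <- synthetic_config(seed = 1L)
  gt <- config_ground_truth(cfg)
  fitB <- gt$B_true
  nm <- ohcapath:::edge_coef_names(dag)
  V <- diag(1e-6, length(nm)); dimnames(V) <- list(nm, nm)
  fit <- structure(list(B = fitB, vcov_coef = V, converged = TRUE,
                        dag = dag), class = "path_model_fit")
  # brute force: filter oracle paths by membership
  adj <- matrix(0, 6, 6, dimnames = list(dag$endogenous, dag$endogenous))
  adj[cbind(dag$edges[, "from"], dag$edges[, "to"])] <- 1
  all_p <- oracle_paths(adj, "sep_binary", "surv_discharge")
  brute <- function(through, exclude = character()) {
    sel <- Filter(function(p) through %in% p && !any(exclude %in% p), all_p)
    sum(vapply(sel, function(p)
      prod(fitB[cbind(p[-1L], p[-length(p)])]), numeric(1)))
  }
  pe <- pathway_effect(fit, through = "bystander_cpr", exclude = "witnessed")
  expect_equal(pe$effect, brute("bystander_cpr", "witnessed"),
               tolerance = 1e-12)
  pe2 <- pathway_effect(fit, through = "bystander_cpr",
                        exclude = "intermediate_confounders")
  expect_equal(pe2$effect, brute("bystander_cpr", "witnessed"),
               tolerance = 1e-12)
  pe3 <- pathway_effect(fit, through = "shockable",
                        exclude = "intermediate_confounders")
  expect_equal(pe3$effect,
               brute("shockable", c("witnessed", "bystander_cpr")),
               tolerance = 1e-12)
  # exclusion monotonicity when all path products share a sign
  pe_all <- pathway_effect(fit, through = "shockable")
  expect_lte(abs(pe3$effect), abs(pe_all$effect))
  expect_error(pathway_effect(fit, through = "nonexistent"), "unknown")
})

test_that("pathway estimates recover generator ground truth", {
  cfg <- small_config(seed = 71L, scale = 1)
  gt <- config_ground_truth(cfg)
  tab <- binarize_sep(generate_registry(cfg))
  fit <- fit_ml(tab, default_dag("all"), se = "robust", scaling = "none")
  for (m in names(gt$pathway)) {
    pe <- pathway_effect(fit, through = m)
    expect_lt(abs(pe$effect - gt$pathway[[m]]), 3.5 * pe$se)
    expect_lt(abs(pe$mediation_proportion - gt$proportion[[m]]),
              3.5 * pe$proportion_se)
  }
  td <- total_and_direct(fit)
  expect_lt(abs(td$total - gt$total), 3.5 * td$total_se)
})

test_that("mediation table mirrors the published decomposition layout", {
  cfg <- small_config(seed = 81L, scale = 0.3)
  tab <- binarize_sep(generate_registry(cfg))
  fit <- fit_ml(tab, default_dag("all"), se = "robust", scaling = "none")
  med <- mediation_table(fit)
  expect_identical(med$pathway[1L], "Total")
  expect_identical(med$pathway[nrow(med)], "Direct")
  expect_true("bystander_cpr (not through witnessed)" %in% med$pathway)
  expect_true(
    "shockable (not through witnessed, bystander_cpr)" %in% med$pathway)
  # ed_level12 has no intermediate confounders, hence no exclusion row
  expect_false(any(grepl("^ed_level12 \\(not", med$pathway)))
  expect_true(all(is.na(med$proportion[med$pathway == "Total"])))
})

test_that("nonsignificant pathway estimates get no proportion", {
  fit <- manual_chain_fit(a = 0.01, b = 0.01, d = 0.3, va = 1, vb = 1,
                          vd = 1e-6, cab = 0)
  med <- mediation_table(fit)
  expect_true(is.na(med$proportion[med$pathway == "m"]))
  expect_false(is.na(med$proportion[med$pathway == "Direct"]))
})

test_that("bootstrap intervals are seeded, cover null effects, and guard B", {
  dag <- dag_spec(c("x", "m", "y"),
                  rbind(c("x", "m"), c("m", "y"), c("x", "y")),
                  covariates = "c1")
  set.seed(5)
  n <- 1500L
  d <- data.frame(c1 = rnorm(n), x = rnorm(n))
  d$m <- rnorm(n)                      # no x -> m edge: theta structurally 0
  d$y <- 0.3 * d$x + 0.2 * d$m + rnorm(n)
  b1 <- bootstrap_ci(d, dag, through = "m", B = 200, seed = 9)
  b2 <- bootstrap_ci(d, dag, through = "m", B = 200, seed = 9)
  expect_identical(b1$effect_ci, b2$effect_ci)
  expect_lte(b1$effect_ci[1L], 0)
  expect_gte(b1$effect_ci[2L], 0)
  expect_error(bootstrap_ci(d, dag, through = "m", B = 100), "200")
})

test_that("delta and bootstrap intervals agree on synthetic registry data", {
  cfg <- small_config(seed = 91L, scale = 0.165)   # about 20k subjects
  tab <- binarize_sep(generate_registry(cfg))
  dag <- default_dag("all")
  fit <- fit_ml(tab, dag, se = "robust", scaling = "none")
  pe <- pathway_effect(fit, through = "witnessed")
  bs <- bootstrap_ci(tab, dag, through = "witnessed", B = 500, seed = 91)
  width_d <- diff(pe$ci)
  width_b <- diff(bs$effect_ci)
  expect_lt(abs(width_b - width_d) / width_d, 0.15)
  expect_lt(abs(mean(bs$effect_ci) - mean(pe$ci)), 0.3 * width_d)
})
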