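test_that("intercept-only generation reproduces published MA prevalences", {
  targets <- c(witnessed = 0.427, bystander_cpr = 0.568,
               shockable = 0.097, ed_level12 = 0.579)
  n <- c(NHI_Q1 = 1L, NHI_Q2 = 1L, NHI_Q3 = 1L, NHI_Q4 = 1L, MA = 10252L)
  cfg <- synthetic_config(
    n_per_group = n, structural_coeffs = list(),
    intercepts = c(targets, public_location = 0.1, bystander_aed = 0.02,
                   rti_lt8 = 0.57, surv_discharge = 0.07,
                   surv_admission = 0.2, cag = 0.1, ttm = 0.1,
                   good_neuro = 0.6),
    seed = 42L)
  tab <- generate_registry(cfg)
  ma <- tab[tab$sep_level == "MA", ]
  for (v in names(targets)) {
    se3 <- 3 * sqrt(targets[[v]] * (1 - targets[[v]]) / nrow(ma))
    expect_lt(abs(mean(ma[[v]]) - targets[[v]]), se3)
  }
})

test_that("zero-logit logistic configuration gives prevalence one half", {
  cfg <- synthetic_config(
    n_per_group = c(NHI_Q1 = 4000L, NHI_Q2 = 4000L, NHI_Q3 = 4000L,
                    NHI_Q4 = 4000L, MA = 4000L),
    structural_coeffs = list(),
    intercepts = stats::setNames(rep(0, 12), ohcapath:::GEN_ORDER),
    link = "logistic", seed = 3L)
  tab <- generate_registry(cfg)
  for (v in c("public_location", "witnessed", "bystander_cpr", "rti_lt8",
              "shockable", "ed_level12", "surv_discharge")) {
    expect_lt(abs(mean(tab[[v]]) - 0.5), 3 * sqrt(0.25 / nrow(tab)))
  }
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 11L, scale = 0.02)
  expect_identical(generate_registry(cfg), generate_registry(cfg))
  cfg2 <- small_config(seed = 12L, scale = 0.02)
  expect_false(identical(generate_registry(cfg), generate_registry(cfg2)))
})

test_that("default configuration hits its calibrated pooled-NHI margins", {
  cfg <- small_config(seed = 5L, scale = 0.5)
  tab <- generate_registry(cfg)
  expect_identical(unname(attr(tab, "clip_events")),
                   rep(0L, length(attr(tab, "clip_events"))))
  nhi <- tab[tab$sep_level != "MA", ]
  m <- default_nhi_margins()
  for (v in names(m)) {
    se3 <- 3 * sqrt(m[[v]] * (1 - m[[v]]) / nrow(nhi))
    expect_lt(abs(mean(nhi[[v]]) - m[[v]]), se3 + 1e-12)
  }
})

test_that("structural consistency: treatment and outcome nesting", {
  tab <- generate_registry(small_config(seed = 8L, scale = 0.1))
  expect_true(all(tab$good_neuro <= tab$surv_discharge))
  expect_true(all(tab$surv_discharge <= tab$surv_admission))
  expect_true(all(tab$cag <= tab$surv_admission))
  expect_true(all(tab$ttm <= tab$surv_admission))
  expect_false(anyNA(tab))
})

test_that("increasing a positive coefficient raises downstream prevalence", {
  # intercepts must be held fixed: the margin calibration would otherwise
  # absorb the coefficient change by construction
  base <- small_config(seed = 1L, scale = 0.1)
  sc2 <- base$structural_coeffs
  sc2$bystander_cpr[["witnessed"]] <-
    sc2$bystander_cpr[["witnessed"]] + 0.15
  hits <- vapply(1:5, function(s) {
    a <- generate_registry(small_config(seed = 100 + s, scale = 0.1,
                                        intercepts = base$intercepts))
    b <- generate_registry(small_config(seed = 100 + s, scale = 0.1,
                                        intercepts = base$intercepts,
                                        structural_coeffs = sc2))
    mean(b$bystander_cpr) > mean(a$bystander_cpr)
  }, logical(1))
  expect_true(all(hits))
})

test_that("linear-probability clipping is counted and warned about", {
  sc <- list(witnessed = c(sep = 0.5))
  cfg <- synthetic_config(
    n_per_group = c(NHI_Q1 = 50L, NHI_Q2 = 50L, NHI_Q3 = 50L,
                    NHI_Q4 = 50L, MA = 500L),
    structural_coeffs = sc,
    intercepts = c(witnessed = 0.8, public_location = 0.1,
                   bystander_cpr = 0.5, bystander_aed = 0.02, rti_lt8 = 0.5,
                   shockable = 0.1, ed_level12 = 0.6, surv_discharge = 0.07,
                   surv_admission = 0.2, cag = 0.1, ttm = 0.1,
                   good_neuro = 0.6),
    seed = 2L)
  expect_warning(tab <- generate_registry(cfg), "clipped")
  expect_gte(attr(tab, "clip_events")[["witnessed"]], 500L)
})

test_that("missingness injection hits its target rates and nothing else", {
  cfg <- small_config(seed = 21L, scale = 0.8)
  tab <- generate_registry(cfg)
  rates <- c(witnessed = 0.09, bystander_cpr = 0.025)
  tm <- inject_missingness(tab, rates, seed = 21L)
  n <- nrow(tm)
  for (v in names(rates)) {
    se3 <- 3 * sqrt(rates[[v]] * (1 - rates[[v]]) / n)
    expect_lt(abs(mean(is.na(tm[[v]])) - rates[[v]]), se3)
  }
  untouched <- setdiff(names(tab), names(rates))
  expect_identical(tab[untouched], tm[untouched])
  obs <- !is.na(tm$witnessed)
  expect_identical(tm$witnessed[obs], tab$witnessed[obs])
  expect_identical(inject_missingness(tab, c(witnessed = 0)), tab)
})

test_that("exposure and outcomes can never be masked", {
  tab <- generate_registry(small_config(seed = 1L, scale = 0.01))
  expect_error(inject_missingness(tab, c(surv_discharge = 0.1)),
               "never masked")
  expect_error(inject_missingness(tab, c(sep_level = 0.1)), "never masked")
})

test_that("MCAR and MAR mechanisms share the same expected rate", {
  tab <- generate_registry(small_config(seed = 31L, scale = 0.15))
  mcar <- vapply(1:25, function(s) mean(is.na(inject_missingness(
    tab, c(witnessed = 0.09), mar_slopes = list(witnessed = c(sex = 0)),
    seed = s)$witnessed)), numeric(1))
  mar <- vapply(1:25, function(s) mean(is.na(inject_missingness(
    tab, c(witnessed = 0.09),
    mar_slopes = list(witnessed = c(metropolitan = 0.6, age = 0.02)),
    seed = 1000 + s)$witnessed)), numeric(1))
  se <- sqrt(0.09 * 0.91 / nrow(tab) / 25)
  expect_lt(abs(mean(mcar) - mean(mar)), 4 * sqrt(2) * se)
  # but the masked rows differ systematically: MAR masks older subjects
  tmar <- inject_missingness(tab, c(witnessed = 0.09),
                             mar_slopes = list(witnessed = c(age = 0.05)),
                             seed = 7L)
  expect_gt(mean(tab$age[is.na(tmar$witnessed)]), mean(tab$age))
})

test_that("config validation catches bad inputs", {
  expect_error(synthetic_config(missingness_rates = c(witnessed = 1.2)),
               "\\[0, 1\\]")
  expect_error(synthetic_config(
    structural_coeffs = list(witnessed = c(shockable = 0.1))),
    "cyclic|anti-temporal")
  expect_error(synthetic_config(missingness_rates = c(cag = 0.1)),
               "never masked")
})

test_that("path-traced ground truth matches the reduced-form total effect", {
  cfg <- synthetic_config(seed = 1L)
  gt <- config_ground_truth(cfg)
  dag <- default_dag("all")
  q <- length(dag$endogenous)
  A <- solve(diag(q) - gt$B_true)
  dimnames(A) <- dimnames(gt$B_true)
  expect_equal(gt$total, A["surv_discharge", "sep_binary"], tolerance = 1e-12)
  paths <- enumerate_paths(dag)
  prods <- vapply(paths, function(p)
    prod(gt$B_true[cbind(p[-1L], p[-length(p)])]), numeric(1))
  expect_equal(gt$total, sum(prods), tolerance = 1e-12)
  expect_equal(gt$direct, gt$B_true["surv_discharge", "sep_binary"])
})
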