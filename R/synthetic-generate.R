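#' Deterministic child seed for a pipeline stage
#'
#' Derives a stage-specific seed from the master seed so that stages draw from
#' independent, reproducible streams. Kept below 2^31 - 1.
#' @param seed master integer seed.
#' @param tag character stage label.
#' @return integer seed.
#' @export
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  val <- ((as.numeric(seed) %% 65011 + 1) * 32749 + h * 104729) %% 2147483647
  as.integer(val)
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Generate a synthetic OHCA registry table
#'
#' Subjects are drawn per SEP group with group-specific confounder
#' distributions; endogenous registry variables are then generated in temporal
#' order from the configured structural equations. Coronary angiography and
#' targeted temperature management are generated only for subjects who survive
#' to admission (0 otherwise); good neurological recovery only for subjects
#' who survive to discharge, so `good_neuro = 1` implies `surv_discharge = 1`.
#' Survival to admission is drawn as a superset event of survival to
#' discharge, so the discharge equation remains exactly the configured
#' full-population structural equation.
#'
#' Under the linear-probability link, any linear predictor falling outside
#' \[0, 1\] is clipped and counted; the count is exposed as
#' `attr(table, "clip_events")`.
#'
#' @param config a [synthetic_config()].
#' @return a `data.frame` with one row per subject, fully observed, with
#'   attributes `clip_events` (named integer vector) and `codebook`.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed.exists()
  set.seed(child_seed(config$seed, "generate"))
  n_g <- config$n_per_group[SEP_LEVELS]
  sep_level <- factor(rep(SEP_LEVELS, times = n_g), levels = SEP_LEVELS)
  n <- length(sep_level)
  cd <- config$confounder_distributions
  tab <- data.frame(sep_level = sep_level)
  tab$sep_binary <- as.integer(sep_level == "MA")
  idx <- as.integer(sep_level)
  tab$age <- rtruncnorm(n, cd$age$mean[idx], cd$age$sd[idx],
                        cd$age$lower, cd$age$upper)
  for (v in c("sex", "diabetes", "hypertension", "metropolitan"))
    tab[[v]] <- stats::rbinom(n, 1L, cd[[v]]$prob[idx])

  clip <- integer(0)
  lin_pred <- function(node) {
    co <- config$structural_coeffs[[node]]
    lp <- rep(config$intercepts[[node]], n)
    for (p in names(co)) {
      x <- if (p == "sep") tab$sep_binary else tab[[p]]
      lp <- lp + co[[p]] * x
    }
    lp
  }
  draw_node <- function(node, subset = NULL) {
    lp <- lin_pred(node)
    if (config$link == "logistic") {
      p <- stats::plogis(lp)
    } else {
      n_clip <- sum(lp < 0 | lp > 1)
      if (n_clip > 0) {
        warning(sprintf("%d linear-probability values clipped for '%s'",
                        n_clip, node))
      }
      clip[node] <<- n_clip
      p <- pmin(pmax(lp, 0), 1)
    }
    y <- stats::rbinom(n, 1L, p)
    if (!is.null(subset)) y[!subset] <- 0L
    y
  }

  for (node in c("public_location", "witnessed", "bystander_cpr",
                 "bystander_aed", "rti_lt8", "shockable", "ed_level12"))
    tab[[node]] <- draw_node(node)
  tab$surv_discharge <- draw_node("surv_discharge")
  # admission: superset of discharge; extra admissions drawn so the marginal
  # admission probability matches its structural equation
  p_adm <- lin_pred("surv_admission")
  p_dis <- lin_pred("surv_discharge")
  if (config$link == "logistic") {
    p_adm <- stats::plogis(p_adm); p_dis <- stats::plogis(p_dis)
  }
  q <- (p_adm - p_dis) / (1 - p_dis)
  n_clip <- sum(q < 0 | q > 1)
  clip["surv_admission"] <- n_clip
  if (n_clip > 0)
    warning(sprintf("%d admission probabilities clipped", n_clip))
  q <- pmin(pmax(q, 0), 1)
  tab$surv_admission <- ifelse(tab$surv_discharge == 1L, 1L,
                               stats::rbinom(n, 1L, q))
  tab$cag <- draw_node("cag", subset = tab$surv_admission == 1L)
  tab$ttm <- draw_node("ttm", subset = tab$surv_admission == 1L)
  tab$good_neuro <- draw_node("good_neuro", subset = tab$surv_discharge == 1L)
  tab <- tab[, c("sep_level", "sep_binary", "age", "sex", "diabetes",
                 "hypertension", "metropolitan", "public_location",
                 "witnessed", "bystander_cpr", "bystander_aed", "rti_lt8",
                 "shockable", "ed_level12", "cag", "ttm", "surv_admission",
                 "surv_discharge", "good_neuro")]
  attr(tab, "clip_events") <- clip
  attr(tab, "codebook") <- registry_codebook()
  restore_seed(old)
  tab
}

.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Inject missing values under a MAR mechanism
#'
#' Masks cells of the maskable Utstein variables (arrest location, witnessed
#' status, bystander CPR, bystander AED use, response-time interval, initial
#' rhythm) with per-column probabilities that are logistic in fully observed
#' covariates. The mechanism intercept is calibrated numerically per column so
#' the expected missingness fraction equals the requested rate exactly;
#' `mar_slopes = NULL` gives MCAR (constant probability).
#'
#' @param table registry `data.frame`.
#' @param rates named vector of missingness proportions; only the maskable
#'   columns are allowed (exposure and outcomes are never masked).
#' @param mar_slopes named list: for each masked column, a named numeric
#'   vector of logit slopes on fully observed covariate columns. Defaults to a
#'   mild dependence on metropolitan residence and age.
#' @param seed integer seed.
#' @return the table with `NA`s injected; all other cells untouched.
#' @export
inject_missingness <- function(table, rates, mar_slopes = NULL, seed = 1L) {
  bad <- setdiff(names(rates), MASKABLE_COLUMNS)
  if (length(bad))
    stop("missingness not allowed for: ", paste(bad, collapse = ", "),
         " (outcomes and exposure are never masked)")
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  old <- .Random.seed.exists()
  set.seed(child_seed(seed, "mask"))
  n <- nrow(table)
  for (col in names(rates)) {
    r <- rates[[col]]
    if (r <= 0) next
    sl <- if (!is.null(mar_slopes) && col %in% names(mar_slopes))
      mar_slopes[[col]] else c(metropolitan = 0.3, age = 0.01)
    lp <- rep(0, n)
    for (v in names(sl)) {
      if (anyNA(table[[v]]))
        stop("MAR covariate '", v, "' must be fully observed")
      lp <- lp + sl[[v]] * table[[v]]
    }
    lp <- lp - mean(lp)
    # calibrate intercept: mean(plogis(c + lp)) == r
    f <- function(c0) mean(stats::plogis(c0 + lp)) - r
    c0 <- stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
    mask <- stats::rbinom(n, 1L, stats::plogis(c0 + lp)) == 1L
    table[mask, col] <- NA
  }
  restore_seed(old)
  table
}
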