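#' SEP binarization schemes
#'
#' The four cutoffs used in the analysis. The low-SEP group (coded 1) always
#' contains the Medical Aid (MA) group:
#' \describe{
#'   \item{MA_vs_rest}{MA vs NHI Q1-Q4 (main analysis)}
#'   \item{MA+Q4}{MA and NHI Q4 vs NHI Q1-Q3}
#'   \item{MA+Q3+Q4}{MA, NHI Q3 and NHI Q4 vs NHI Q1-Q2}
#'   \item{MA+Q2+Q3+Q4}{MA and NHI Q2-Q4 vs NHI Q1}
#' }
#'
#' @param cutoff_id one of the four scheme identifiers above.
#' @return object of class `binarization_scheme` with fields `cutoff_id` and
#'   `low_group_labels`.
#' @export
binarization_scheme <- function(cutoff_id = c("MA_vs_rest", "MA+Q4",
                                              "MA+Q3+Q4", "MA+Q2+Q3+Q4")) {
  cutoff_id <- match.arg(cutoff_id)
  low <- switch(cutoff_id,
                "MA_vs_rest"   = "MA",
                "MA+Q4"        = c("MA", "NHI_Q4"),
                "MA+Q3+Q4"     = c("MA", "NHI_Q3", "NHI_Q4"),
                "MA+Q2+Q3+Q4"  = c("MA", "NHI_Q2", "NHI_Q3", "NHI_Q4"))
  structure(list(cutoff_id = cutoff_id, low_group_labels = low),
            class = "binarization_scheme")
}

#' All four binarization schemes, in sensitivity-grid order
#' @return named list of `binarization_scheme` objects.
#' @export
all_binarization_schemes <- function() {
  ids <- c("MA_vs_rest", "MA+Q4", "MA+Q3+Q4", "MA+Q2+Q3+Q4")
  stats::setNames(lapply(ids, binarization_scheme), ids)
}

#' Binarize the SEP exposure
#'
#' Sets `sep_binary = 1` for subjects whose `sep_level` is in the scheme's
#' low-SEP group. Idempotent; the row count and all other columns are
#' unchanged.
#'
#' @param table registry data.frame with a 5-level `sep_level` column.
#' @param scheme a [binarization_scheme()] (or a cutoff id string).
#' @return the table with `sep_binary` recoded.
#' @export
binarize_sep <- function(table, scheme = binarization_scheme()) {
  if (is.character(scheme)) scheme <- binarization_scheme(scheme)
  lev <- as.character(table$sep_level)
  bad <- setdiff(unique(lev), SEP_LEVELS)
  if (length(bad))
    stop("unknown sep_level label(s): ", paste(bad, collapse = ", "))
  table$sep_binary <- as.integer(lev %in% scheme$low_group_labels)
  attr(table, "binarization") <- scheme$cutoff_id
  table
}

# default imputation predictor set: confounders + SEP + every other observed
# registry variable that carries information about the target, including the
# downstream mediators and the outcomes. Conditioning only on temporally
# upstream variables would make imputed cells independent of their downstream
# correlates and attenuate the corresponding path coefficients.
imputation_predictors <- function(target, columns) {
  base <- c("age", "sex", "diabetes", "hypertension", "metropolitan",
            "sep_level", MASKABLE_COLUMNS,
            "ed_level12", "surv_admission", "surv_discharge")
  setdiff(intersect(base, columns), target)
}

#' Fit logistic imputation models for missing-prone columns
#'
#' One logistic regression per column with missing values, fitted on the
#' rows where the target and all predictors are observed. The default
#' predictor set is the full conditional: confounders, the 5-level SEP
#' factor, the other Utstein variables, ED level and the survival outcomes.
#'
#' @param table registry data.frame (possibly with `NA`s in the maskable
#'   columns).
#' @param min_complete minimum number of complete cases per target.
#' @param predictors optional named list overriding the predictor set per
#'   target (use `character()` for an intercept-only model, whose draws are
#'   then Bernoulli at the observed prevalence).
#' @return named list of `imputation_model` objects (empty when nothing is
#'   missing), each holding `target`, `predictors` and a fitted `fit`
#'   ([fit_logistic()] result) with its model formula.
#' @export
fit_imputation_models <- function(table, min_complete = 50L,
                                  predictors = NULL) {
  targets <- MASKABLE_COLUMNS[vapply(MASKABLE_COLUMNS, function(v)
    v %in% names(table) && anyNA(table[[v]]), logical(1))]
  models <- list()
  for (tg in targets) {
    preds <- if (!is.null(predictors) && tg %in% names(predictors))
      predictors[[tg]] else imputation_predictors(tg, names(table))
    frm <- if (length(preds)) stats::reformulate(preds, response = tg) else
      stats::as.formula(paste(tg, "~ 1"))
    cc <- stats::complete.cases(table[, c(tg, preds), drop = FALSE])
    if (sum(cc) < min_complete)
      stop("fewer than ", min_complete, " complete cases for '", tg, "'")
    mf <- stats::model.frame(frm, table[cc, , drop = FALSE])
    X <- stats::model.matrix(frm, mf)
    y <- stats::model.response(mf)
    fit <- fit_logistic(y, X)
    if (!fit$converged)
      stop("imputation model for '", tg, "' did not converge (separation?)")
    models[[tg]] <- structure(
      list(target = tg, predictors = preds, formula = frm, fit = fit),
      class = "imputation_model")
  }
  models
}

#' Stochastic regression imputation
#'
#' Missing cells are replaced by Bernoulli draws from the fitted predictive
#' probability of their logistic imputation model -- not by thresholded point
#' predictions. Because each model conditions on the full set of other
#' registry variables, imputation proceeds as a short chained-equations
#' scheme: missing cells are first initialized by marginal prevalence draws,
#' then redrawn from their full conditional model in temporal order for
#' `sweeps` passes. At the small missingness rates of this registry two
#' sweeps are ample for the draws to stabilize. Observed cells are untouched
#' and the result is deterministic under `seed`.
#'
#' @param table registry data.frame with `NA`s confined to modeled columns.
#' @param models result of [fit_imputation_models()].
#' @param seed integer seed (draws are deterministic given it).
#' @param sweeps number of full-conditional redraw passes after the initial
#'   fill.
#' @return completed data.frame with no missing cells among modeled columns.
#' @export
impute_stochastic <- function(table, models, seed = 1L, sweeps = 2L) {
  miss_cols <- names(table)[vapply(table, anyNA, logical(1))]
  uncovered <- setdiff(intersect(miss_cols, MASKABLE_COLUMNS), names(models))
  extra <- setdiff(miss_cols, MASKABLE_COLUMNS)
  if (length(c(uncovered, extra)))
    stop("missing cells with no covering model in: ",
         paste(c(uncovered, extra), collapse = ", "))
  ord <- intersect(MASKABLE_COLUMNS, names(models))
  holes <- lapply(table[ord], function(x) which(is.na(x)))
  if (!any(lengths(holes) > 0L)) return(table)
  old <- .Random.seed.exists()
  set.seed(child_seed(seed, "impute"))
  # initial fill: marginal prevalence draws
  for (tg in ord) {
    rows <- holes[[tg]]
    if (!length(rows)) next
    p0 <- mean(table[[tg]], na.rm = TRUE)
    table[rows, tg] <- stats::rbinom(length(rows), 1L, p0)
  }
  # full-conditional redraw sweeps in temporal order
  for (sw in seq_len(max(sweeps, 1L))) {
    for (tg in ord) {
      m <- models[[tg]]
      rows <- holes[[tg]]
      if (!length(rows)) next
      newdata <- table[rows, m$predictors, drop = FALSE]
      if (anyNA(newdata))
        stop("predictors of '", tg, "' not complete at imputation time")
      X <- stats::model.matrix(
        stats::delete.response(stats::terms(m$formula)), newdata)
      p <- stats::plogis(drop(X %*% m$fit$coefficients))
      table[rows, tg] <- stats::rbinom(length(rows), 1L, p)
    }
  }
  restore_seed(old)
  table
}
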