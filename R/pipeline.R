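#' End-to-end analysis pipeline
#'
#' Runs simulate (optional) -> missingness -> stochastic imputation -> SEP
#' binarization -> descriptive table -> crude/adjusted odds ratios ->
#' Baron-Kenny mediator screen -> path-model fit with fit indices ->
#' mediation decomposition table, for one binarization scheme and one
#' population (all patients, or the admitted-only sensitivity population,
#' which is re-screened on the subset before the SEM).
#'
#' @param config a [synthetic_config()] used to generate the input registry;
#'   ignored when `table` is given.
#' @param table an existing registry data.frame (may contain missing maskable
#'   cells, which are imputed).
#' @param scheme binarization scheme id or [binarization_scheme()].
#' @param population `"all"` or `"admitted"`.
#' @param outcome `"surv_discharge"` or `"good_neuro"`.
#' @param seed master seed for generation, masking, imputation.
#' @param outdir optional directory; when given, every table is written as
#'   CSV, the fit as JSON, and a manifest records seed, package version and a
#'   config hash (identical config + seed gives a byte-identical bundle).
#' @param se,scaling passed to [fit_ml()].
#' @param alpha screening significance level.
#' @return list bundle: `descriptive`, `or_crude`, `or_adjusted`, `screen`,
#'   `fit`, `mediation`, `completed` (the completed analysis table) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = NULL, table = NULL,
                         scheme = "MA_vs_rest",
                         population = c("all", "admitted"),
                         outcome = c("surv_discharge", "good_neuro"),
                         seed = NULL, outdir = NULL,
                         se = "robust", scaling = "mean_adjusted",
                         alpha = 0.05) {
  population <- match.arg(population)
  outcome <- match.arg(outcome)
  if (is.character(scheme)) scheme <- binarization_scheme(scheme)
  if (is.null(table)) {
    if (is.null(config)) stop("supply `config` or `table`")
    if (is.null(seed)) seed <- config$seed
    table <- generate_registry(config)
    table <- inject_missingness(table, config$missingness_rates, seed = seed)
  }
  if (is.null(seed)) seed <- 1L
  if (!outcome %in% names(table)) stop("outcome column missing: ", outcome)
  completed <- complete_registry(table, seed = seed)
  completed <- binarize_sep(completed, scheme)
  desc <- descriptive_table(completed)
  orc <- adjusted_or_table(completed, outcome, confounders = character())
  ora <- adjusted_or_table(completed, outcome)
  if (population == "admitted") {
    if (!all(c("cag", "ttm") %in% names(completed)))
      stop("admitted-only analysis requires cag and ttm columns")
    analysis <- completed[completed$surv_admission == 1L, , drop = FALSE]
    candidates <- c("public_location", "witnessed", "bystander_cpr",
                    "bystander_aed", "rti_lt8", "shockable", "ed_level12",
                    "cag", "ttm")
  } else {
    analysis <- completed
    candidates <- c("public_location", "witnessed", "bystander_cpr",
                    "bystander_aed", "rti_lt8", "shockable", "ed_level12")
  }
  screen <- screen_mediators(analysis, candidates, exposure = "sep_binary",
                             outcome = outcome, alpha = alpha)
  dag <- default_dag(population, outcome = outcome)
  fit <- fit_ml(analysis, dag, se = se, scaling = scaling)
  med <- mediation_table(fit)
  manifest <- list(seed = seed, scheme = scheme$cutoff_id,
                   population = population, outcome = outcome,
                   n = nrow(analysis),
                   package_version =
                     as.character(utils::packageVersion("ohcapath")),
                   config_hash = if (!is.null(config)) config_hash(config)
                   else NA_character_)
  bundle <- list(descriptive = desc, or_crude = orc, or_adjusted = ora,
                 screen = screen, fit = fit, mediation = med,
                 completed = completed, manifest = manifest)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

# impute the maskable columns if anything is missing
complete_registry <- function(table, seed = 1L) {
  if (!any(vapply(table, anyNA, logical(1)))) return(table)
  models <- fit_imputation_models(table)
  impute_stochastic(table, models, seed = seed)
}

# small deterministic FNV-1a hash of the serialized configuration
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE, na = "")
  wr(bundle$descriptive, "descriptive_table.csv")
  wr(bundle$or_crude, "or_crude.csv")
  wr(bundle$or_adjusted, "or_adjusted.csv")
  wr(bundle$screen, "mediator_screen.csv")
  wr(bundle$mediation, "mediation_table.csv")
  fit <- bundle$fit
  jsonlite::write_json(
    list(coefficients = as.list(fit$coef),
         T = fit$T, df = fit$df, scaling_c = fit$scaling_c,
         T_scaled = fit$T_scaled,
         fit_indices = fit$fit_indices[c("rmsea", "srmr", "gfi", "cfi")],
         converged = fit$converged, N = fit$N),
    file.path(outdir, "path_model_fit.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Sensitivity grid over the four SEP binarization cutoffs
#'
#' Completes the registry once (imputation does not depend on the cutoff),
#' then re-binarizes, refits the path model and recomputes the mediation
#' table for each scheme, returning a long-format table keyed by scheme and
#' pathway together with the per-pathway range of mediation proportions.
#'
#' @inheritParams run_pipeline
#' @param schemes character vector of scheme ids (default all four).
#' @return list with `grid` (long data.frame) and `ranges` (per-pathway
#'   min/max mediation proportion).
#' @export
sensitivity_grid <- function(config = NULL, table = NULL,
                             schemes = names(all_binarization_schemes()),
                             population = "all", outcome = "surv_discharge",
                             seed = NULL, se = "robust", scaling = "none") {
  if (is.null(table)) {
    if (is.null(config)) stop("supply `config` or `table`")
    if (is.null(seed)) seed <- config$seed
    table <- generate_registry(config)
    table <- inject_missingness(table, config$missingness_rates, seed = seed)
  }
  if (is.null(seed)) seed <- 1L
  completed <- complete_registry(table, seed = seed)
  rows <- list()
  for (sc in schemes) {
    tab <- binarize_sep(completed, sc)
    analysis <- if (population == "admitted")
      tab[tab$surv_admission == 1L, , drop = FALSE] else tab
    dag <- default_dag(population, outcome = outcome)
    fit <- fit_ml(analysis, dag, se = se, scaling = scaling)
    med <- mediation_table(fit)
    med$scheme <- sc
    rows[[sc]] <- med
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  pr <- grid[!is.na(grid$proportion), ]
  ranges <- do.call(rbind, lapply(split(pr, pr$pathway), function(d)
    data.frame(pathway = d$pathway[1L], min_proportion = min(d$proportion),
               max_proportion = max(d$proportion),
               width = diff(range(d$proportion)))))
  rownames(ranges) <- NULL
  list(grid = grid, ranges = ranges)
}
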