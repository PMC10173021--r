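#' Pathway selectors, product-of-coefficients effects and mediation
#' proportions
#'
#' A pathway effect is the sum, over all simple exposure-to-outcome paths
#' selected by a mediator (optionally excluding paths through an exclusion
#' set), of the product of the path's edge coefficients. The mediation
#' proportion expresses a pathway effect as a percentage of the total
#' (reduced-form) exposure effect.
#'
#' @name mediation
NULL

path_product <- function(B, path) {
  prod(vapply(seq_len(length(path) - 1L),
              function(i) B[path[i + 1L], path[i]], numeric(1)))
}

# gradient of sum of path products w.r.t. the named edge coefficients
path_sum_gradient <- function(B, paths, coef_names) {
  g <- stats::setNames(numeric(length(coef_names)), coef_names)
  for (path in paths) {
    for (i in seq_len(length(path) - 1L)) {
      nm <- paste0(path[i + 1L], "~", path[i])
      rest <- prod(vapply(setdiff(seq_len(length(path) - 1L), i),
                          function(j) B[path[j + 1L], path[j]], numeric(1)))
      if (nm %in% coef_names) g[nm] <- g[nm] + rest
    }
  }
  g
}

select_paths <- function(dag, through = NULL, exclude = character()) {
  paths <- enumerate_paths(dag)
  keep <- vapply(paths, function(p) {
    ok <- TRUE
    if (!is.null(through)) ok <- all(through %in% p)
    ok && !any(exclude %in% p)
  }, logical(1))
  paths[keep]
}

#' Pathway effect by the product-of-coefficients approach
#'
#' @param fit a converged `path_model_fit`.
#' @param through mediator name (or vector: paths must contain all of them);
#'   `NULL` selects every path (the total effect) and `"direct"` the
#'   single-edge direct path.
#' @param exclude character vector of nodes whose paths are excluded --
#'   `"intermediate_confounders"` expands to the mediator's intermediate
#'   confounders derived from the DAG.
#' @param level confidence level for the delta-method CI.
#' @return object of class `pathway_effect`: `selector`, `paths`, `effect`,
#'   `se`, `ci`, plus `total`, `mediation_proportion`, `proportion_se`,
#'   `proportion_ci` for mediator selectors.
#' @export
pathway_effect <- function(fit, through = NULL, exclude = character(),
                           level = 0.95) {
  stopifnot(inherits(fit, "path_model_fit"))
  if (!fit$converged) stop("path model fit did not converge")
  dag <- fit$dag
  direct_only <- identical(through, "direct")
  if (direct_only) through <- NULL
  med_nodes <- setdiff(dag$endogenous, c(dag$exposure, dag$outcome))
  if (!is.null(through)) {
    bad <- setdiff(through, med_nodes)
    if (length(bad)) stop("unknown mediator(s): ", paste(bad, collapse = ", "))
  }
  if (identical(exclude, "intermediate_confounders")) {
    if (is.null(through) || length(through) != 1L)
      stop("intermediate-confounder exclusion requires a single mediator")
    exclude <- intermediate_confounders(dag, through)
  }
  paths <- select_paths(dag, through, exclude)
  if (direct_only)
    paths <- Filter(function(p) length(p) == 2L, select_paths(dag))
  theta <- sum(vapply(paths, path_product, numeric(1), B = fit$B))
  enames <- edge_coef_names(dag)
  g <- path_sum_gradient(fit$B, paths, enames)
  V <- fit$vcov_coef[enames, enames, drop = FALSE]
  se <- sqrt(drop(t(g) %*% V %*% g))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list(selector = list(through = through, exclude = exclude,
                              direct = direct_only),
              paths = paths, effect = theta, se = se,
              ci = c(theta - z * se, theta + z * se), level = level)
  if (!is.null(through) || direct_only) {
    all_paths <- select_paths(dag)
    tau <- sum(vapply(all_paths, path_product, numeric(1), B = fit$B))
    gt <- path_sum_gradient(fit$B, all_paths, enames)
    pr <- mediation_proportion(theta, tau)
    # delta method on the ratio 100*theta/tau
    gp <- 100 * (g / tau - theta * gt / tau^2)
    pse <- sqrt(drop(t(gp) %*% V %*% gp))
    out$total <- tau
    out$mediation_proportion <- pr
    out$proportion_se <- pse
    out$proportion_ci <- c(pr - z * pse, pr + z * pse)
  }
  structure(out, class = "pathway_effect")
}

edge_coef_names <- function(dag) {
  paste0(dag$edges[, "to"], "~", dag$edges[, "from"])
}

#' Total and direct exposure effects with the decomposition identity
#'
#' The total effect is the exposure-to-outcome element of the reduced form
#' \eqn{(I-B)^{-1}}; the direct effect is the single-edge coefficient. The
#' identity total = direct + sum of all indirect path products holds exactly
#' for a recursive model.
#'
#' @param fit a converged `path_model_fit`.
#' @param level confidence level.
#' @return list with `total`, `direct`, their `se` and `ci`, and
#'   `indirect_sum`.
#' @export
total_and_direct <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "path_model_fit"))
  if (!fit$converged) stop("path model fit did not converge")
  dag <- fit$dag
  q <- nrow(fit$B)
  A <- solve(diag(q) - fit$B)
  dimnames(A) <- dimnames(fit$B)
  tau <- A[dag$outcome, dag$exposure]
  delta <- fit$B[dag$outcome, dag$exposure]
  enames <- edge_coef_names(dag)
  V <- fit$vcov_coef[enames, enames, drop = FALSE]
  all_paths <- select_paths(dag)
  gt <- path_sum_gradient(fit$B, all_paths, enames)
  se_t <- sqrt(drop(t(gt) %*% V %*% gt))
  dname <- paste0(dag$outcome, "~", dag$exposure)
  se_d <- if (dname %in% enames) sqrt(V[dname, dname]) else 0
  z <- stats::qnorm(1 - (1 - level) / 2)
  ind <- sum(vapply(Filter(function(p) length(p) > 2L, all_paths),
                    path_product, numeric(1), B = fit$B))
  list(total = tau, total_se = se_t, total_ci = c(tau - z * se_t,
                                                  tau + z * se_t),
       direct = delta, direct_se = se_d,
       direct_ci = c(delta - z * se_d, delta + z * se_d),
       indirect_sum = ind)
}

#' Mediation proportion
#'
#' @param theta pathway effect.
#' @param tau total effect; must be nonzero.
#' @return `100 * theta / tau` (percent).
#' @export
mediation_proportion <- function(theta, tau) {
  if (!is.finite(tau) || tau == 0)
    stop("mediation proportion undefined for a zero total effect")
  100 * theta / tau
}

#' Table of pathway effects and mediation proportions
#'
#' Builds the standard decomposition table: the total effect, each mediator's
#' through-pathway effect, the footnoted "but not through its intermediate
#' confounders" variants (for mediators that have any), and the direct
#' effect. Mediation proportions for nonsignificant effect estimates (CI
#' covering 0) are suppressed.
#'
#' @param fit a converged `path_model_fit`.
#' @param mediators mediators to report; default every intermediate node.
#' @param level confidence level.
#' @return data.frame with columns `pathway`, `effect`, `effect_lcl`,
#'   `effect_ucl`, `proportion`, `proportion_lcl`, `proportion_ucl`.
#' @export
mediation_table <- function(fit, mediators = NULL, level = 0.95) {
  dag <- fit$dag
  if (is.null(mediators))
    mediators <- setdiff(dag$endogenous, c(dag$exposure, dag$outcome))
  td <- total_and_direct(fit, level)
  rows <- list(data.frame(
    pathway = "Total", effect = td$total, effect_lcl = td$total_ci[1L],
    effect_ucl = td$total_ci[2L], proportion = NA_real_,
    proportion_lcl = NA_real_, proportion_ucl = NA_real_))
  add <- function(label, pe) {
    signif_ <- !(pe$ci[1L] <= 0 && pe$ci[2L] >= 0)
    rows[[length(rows) + 1L]] <<- data.frame(
      pathway = label, effect = pe$effect, effect_lcl = pe$ci[1L],
      effect_ucl = pe$ci[2L],
      proportion = if (signif_) pe$mediation_proportion else NA_real_,
      proportion_lcl = if (signif_) pe$proportion_ci[1L] else NA_real_,
      proportion_ucl = if (signif_) pe$proportion_ci[2L] else NA_real_)
  }
  for (m in mediators) {
    add(m, pathway_effect(fit, through = m, level = level))
    ic <- intermediate_confounders(dag, m)
    if (length(ic))
      add(paste0(m, " (not through ", paste(ic, collapse = ", "), ")"),
          pathway_effect(fit, through = m,
                         exclude = "intermediate_confounders", level = level))
  }
  add("Direct", pathway_effect(fit, through = "direct", level = level))
  do.call(rbind, rows)
}

#' Percentile bootstrap CI for a pathway effect
#'
#' Refits the path model on nonparametric resamples of the rows and returns
#' percentile intervals for the pathway effect and its mediation proportion.
#'
#' @param data complete data.frame with the model columns.
#' @param dag a [dag_spec()].
#' @param through,exclude selector as in [pathway_effect()].
#' @param B number of bootstrap resamples (at least 200).
#' @param seed integer seed.
#' @param level confidence level.
#' @param selectors optional named list of selectors, each a list with
#'   elements `through` and (optionally) `exclude`; all pathway effects are
#'   then computed from the same resamples (one model fit per resample) and
#'   per-selector intervals are returned, alongside `total` and `direct`.
#' @return single selector: list with `effect_ci`, `proportion_ci`,
#'   `replicates` (data.frame of resampled effect and proportion), `B`.
#'   With `selectors`: list with `effect_ci` (named list of intervals),
#'   `replicates` (one column per selector plus `total` and `direct`), `B`.
#' @export
bootstrap_ci <- function(data, dag, through = NULL, exclude = character(),
                         B = 500L, seed = 1L, level = 0.95,
                         selectors = NULL) {
  if (B < 200L) stop("at least 200 bootstrap resamples are required")
  single <- is.null(selectors)
  if (single)
    selectors <- list(sel = list(through = through, exclude = exclude))
  sel_paths <- lapply(selectors, function(s) {
    ex <- if (is.null(s$exclude)) character() else s$exclude
    if (identical(ex, "intermediate_confounders"))
      ex <- intermediate_confounders(dag, s$through)
    select_paths(dag, s$through, ex)
  })
  paths_all <- select_paths(dag)
  lay <- sem_layout(dag)
  vars <- c(lay$exo, lay$endo)
  Z <- as.matrix(data[, vars, drop = FALSE])
  if (anyNA(Z)) stop("missing values in model variables")
  n <- nrow(Z)
  old <- .Random.seed.exists()
  set.seed(child_seed(seed, "bootstrap"))
  eff <- matrix(NA_real_, B, length(sel_paths),
                dimnames = list(NULL, names(selectors)))
  tot <- dir_ <- rep(NA_real_, B)
  fails <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(
      fit_ml(S = stats::cov(Z[idx, , drop = FALSE]), N = n, dag = dag,
             se = "naive", optimize = FALSE),
      error = function(e) NULL)
    if (is.null(fb)) { fails <- fails + 1L; next }
    eff[b, ] <- vapply(sel_paths, function(ps)
      sum(vapply(ps, path_product, numeric(1), B = fb$B)), numeric(1))
    tot[b] <- sum(vapply(paths_all, path_product, numeric(1), B = fb$B))
    dir_[b] <- fb$B[dag$outcome, dag$exposure]
  }
  restore_seed(old)
  if (fails > 0.05 * B)
    stop("more than 5% of bootstrap resamples failed to fit")
  a <- (1 - level) / 2
  qi <- function(x) unname(stats::quantile(x, c(a, 1 - a), na.rm = TRUE))
  if (single) {
    prop <- ifelse(tot != 0, 100 * eff[, 1L] / tot, NA_real_)
    return(list(effect_ci = qi(eff[, 1L]), proportion_ci = qi(prop),
                replicates = data.frame(effect = eff[, 1L],
                                        proportion = prop), B = B))
  }
  list(effect_ci = c(lapply(as.data.frame(eff), qi),
                     list(total = qi(tot), direct = qi(dir_))),
       replicates = data.frame(eff, total = tot, direct = dir_), B = B)
}
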