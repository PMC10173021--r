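#' Logistic regression fit (IRLS) with Wald inference
#'
#' Thin, validated wrapper around iteratively reweighted least squares for the
#' Bernoulli likelihood: coefficients on the logit scale, covariance equal to
#' the inverse observed information (which coincides with the expected
#' information at the canonical link), log-likelihood and a convergence flag.
#' Rank-deficient designs error; non-convergence and separation are flagged,
#' never silently returned.
#'
#' @param y 0/1 response vector with no missing values.
#' @param X numeric design matrix (including the intercept column).
#' @param tol IRLS convergence tolerance on the score norm.
#' @param maxit maximum IRLS iterations.
#' @return object of class `logistic_fit`: `coefficients`, `vcov`, `n`,
#'   `converged`, `loglik`.
#' @export
fit_logistic <- function(y, X, tol = 1e-8, maxit = 100L) {
  X <- as.matrix(X)
  if (anyNA(y) || anyNA(X)) stop("missing values in response or design")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-12,
                                                     maxit = maxit))
  beta <- fit$coefficients
  p <- fit$fitted.values
  score <- drop(crossprod(X, y - p))
  W <- p * (1 - p)
  info <- crossprod(X * sqrt(W))
  # score tolerance is scaled by the information magnitude so the criterion
  # is attainable in floating point at registry-scale n
  score_ok <- sqrt(sum(score^2)) < tol * max(1, sum(diag(info)))
  converged <- fit$converged && score_ok && !fit$boundary &&
    all(abs(beta) < 20)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc)) converged <- FALSE
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = vc, n = length(y), converged = converged,
                 loglik = ll),
            class = "logistic_fit")
}

or_row <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(est), lcl = exp(est - z * se), ucl = exp(est + z * se),
    p = 2 * stats::pnorm(-abs(est / se)))
}

#' Crude and adjusted odds-ratio table for the 5-level SEP exposure
#'
#' Fits a single logistic model of the outcome on indicator-coded SEP (NHI Q1
#' as reference) plus optional confounders, returning one odds ratio with a
#' Wald 95% CI per non-reference level. Calling without confounders yields the
#' crude table.
#'
#' @param table complete registry data.frame.
#' @param outcome outcome column name.
#' @param confounders character vector of confounder columns (possibly
#'   empty for the crude table).
#' @param exposure exposure column (default the 5-level `sep_level`).
#' @param level confidence level.
#' @return data.frame with columns `level`, `or`, `lcl`, `ucl`, `p`.
#' @export
adjusted_or_table <- function(table, outcome,
                              confounders = c("age", "sex", "hypertension",
                                              "diabetes", "metropolitan"),
                              exposure = "sep_level", level = 0.95) {
  rhs <- c(exposure, confounders)
  frm <- stats::reformulate(rhs, response = outcome)
  mf <- stats::model.frame(frm, table)
  X <- stats::model.matrix(frm, mf)
  y <- stats::model.response(mf)
  fit <- fit_logistic(y, X)
  if (!fit$converged) stop("odds-ratio model did not converge")
  keep <- grep(paste0("^", exposure), colnames(X), value = TRUE)
  out <- t(vapply(keep, function(k)
    or_row(fit$coefficients[[k]], sqrt(fit$vcov[k, k]), level), numeric(4)))
  lev <- sub(paste0("^", exposure), "", keep)
  data.frame(level = lev, out, row.names = NULL)
}

#' Baron-Kenny mediator screen
#'
#' Two adjusted logistic regressions decide mediator status at a two-sided
#' significance level `alpha`: (1) mediator on exposure plus confounders
#' (exposure-mediator association) and (2) outcome on mediator, exposure and
#' confounders (mediator-outcome association given exposure). The attenuation
#' of the exposure coefficient when the mediator is added to the outcome model
#' is reported descriptively.
#'
#' @param table complete data.frame with binary-coded variables.
#' @param exposure,mediator,outcome column names.
#' @param confounders confounder columns.
#' @param alpha two-sided significance level (default 0.05).
#' @return object of class `mediator_screen`: `mediator`, `step1`, `step2`
#'   (each `estimate`, `se`, `p`), `attenuation` (exposure coefficient without
#'   vs with the mediator) and `is_mediator`.
#' @export
baron_kenny_screen <- function(table, exposure, mediator, outcome,
                               confounders = c("age", "sex", "hypertension",
                                               "diabetes", "metropolitan"),
                               alpha = 0.05) {
  coef_of <- function(response, rhs, term) {
    frm <- stats::reformulate(rhs, response = response)
    mf <- stats::model.frame(frm, table)
    X <- stats::model.matrix(frm, mf)
    fit <- fit_logistic(stats::model.response(mf), X)
    if (!fit$converged) stop("screen model for '", response,
                             "' did not converge")
    est <- fit$coefficients[[term]]
    se <- sqrt(fit$vcov[term, term])
    c(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
  }
  s1 <- coef_of(mediator, c(exposure, confounders), exposure)
  s2 <- coef_of(outcome, c(mediator, exposure, confounders), mediator)
  without_m <- coef_of(outcome, c(exposure, confounders), exposure)
  with_m <- coef_of(outcome, c(mediator, exposure, confounders), exposure)
  structure(list(
    mediator = mediator, step1 = s1, step2 = s2,
    attenuation = c(without_mediator = unname(without_m["estimate"]),
                    with_mediator = unname(with_m["estimate"])),
    is_mediator = unname(s1["p"] < alpha && s2["p"] < alpha),
    alpha = alpha), class = "mediator_screen")
}

#' Screen a set of candidate mediators
#'
#' @param table complete data.frame.
#' @param candidates character vector of candidate mediator columns.
#' @inheritParams baron_kenny_screen
#' @return data.frame with one row per candidate: step estimates, p-values,
#'   attenuation and the `is_mediator` flag.
#' @export
screen_mediators <- function(table, candidates, exposure = "sep_binary",
                             outcome = "surv_discharge",
                             confounders = c("age", "sex", "hypertension",
                                             "diabetes", "metropolitan"),
                             alpha = 0.05) {
  rows <- lapply(candidates, function(m) {
    s <- baron_kenny_screen(table, exposure, m, outcome, confounders, alpha)
    data.frame(mediator = m,
               step1_est = s$step1[["estimate"]], step1_p = s$step1[["p"]],
               step2_est = s$step2[["estimate"]], step2_p = s$step2[["p"]],
               exposure_coef_without = s$attenuation[["without_mediator"]],
               exposure_coef_with = s$attenuation[["with_mediator"]],
               is_mediator = s$is_mediator)
  })
  do.call(rbind, rows)
}

smd_binary <- function(p1, p2) {
  (p1 - p2) / sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
}
smd_continuous <- function(m1, s1, m2, s2) {
  (m1 - m2) / sqrt((s1^2 + s2^2) / 2)
}

#' Descriptive characteristics table by SEP group
#'
#' Counts and percentages (1 decimal) for binary columns with chi-square
#' p-values, medians (IQR) for continuous columns with Kruskal-Wallis
#' p-values, and standardized mean differences of each group against the
#' reference (first) group: binary SMD \eqn{(p_1-p_2)/\sqrt{(p_1(1-p_1)+
#' p_2(1-p_2))/2}}, continuous SMD \eqn{(m_1-m_2)/\sqrt{(s_1^2+s_2^2)/2}}.
#'
#' @param table registry data.frame.
#' @param variables columns to summarize; defaults to every codebook variable
#'   other than the grouping column.
#' @param group grouping column (default `sep_level`).
#' @return data.frame with one row per variable x group, columns `variable`,
#'   `group`, `n`, `summary`, `pct`, `smd_vs_ref`, `p_value`.
#' @export
descriptive_table <- function(table, variables = NULL, group = "sep_level") {
  g <- table[[group]]
  if (is.null(g)) stop("grouping column '", group, "' not found")
  g <- droplevels(as.factor(g))
  if (length(g) == 0L || nlevels(g) == 0L)
    stop("empty group in '", group, "'")
  cb <- attr(table, "codebook")
  if (is.null(cb)) cb <- registry_codebook()
  if (is.null(variables))
    variables <- setdiff(intersect(cb$name, names(table)),
                         c(group, "sep_binary"))
  ref <- levels(g)[1L]
  out <- list()
  for (v in variables) {
    x <- table[[v]]
    type <- cb$type[match(v, cb$name)]
    if (is.na(type)) type <- if (is.numeric(x) &&
                                 length(unique(stats::na.omit(x))) > 2L)
      "continuous" else "binary"
    for (lev in levels(g)) {
      xi <- x[g == lev]
      xr <- x[g == ref]
      if (type == "continuous") {
        qs <- stats::quantile(xi, c(0.25, 0.5, 0.75), na.rm = TRUE)
        smd <- if (lev == ref) 0 else
          smd_continuous(mean(xi, na.rm = TRUE), stats::sd(xi, na.rm = TRUE),
                         mean(xr, na.rm = TRUE), stats::sd(xr, na.rm = TRUE))
        pv <- stats::kruskal.test(x, g)$p.value
        out[[length(out) + 1L]] <- data.frame(
          variable = v, group = lev, n = sum(!is.na(xi)),
          summary = sprintf("%.0f (%.0f-%.0f)", qs[2L], qs[1L], qs[3L]),
          pct = NA_real_, smd_vs_ref = smd, p_value = pv)
      } else {
        p1 <- mean(xi, na.rm = TRUE)
        p2 <- mean(xr, na.rm = TRUE)
        smd <- if (lev == ref) 0 else smd_binary(p1, p2)
        pv <- tryCatch(
          stats::chisq.test(table(factor(x), g))$p.value,
          error = function(e) NA_real_, warning = function(w)
            suppressWarnings(stats::chisq.test(table(factor(x), g))$p.value))
        out[[length(out) + 1L]] <- data.frame(
          variable = v, group = lev, n = sum(xi == 1L, na.rm = TRUE),
          summary = sprintf("%d (%.1f)", sum(xi == 1L, na.rm = TRUE),
                            100 * p1),
          pct = round(100 * p1, 1), smd_vs_ref = smd, p_value = pv)
      }
    }
  }
  do.call(rbind, out)
}
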