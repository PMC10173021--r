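#' Goodness-of-fit indices for a fitted path model
#'
#' Computes the four covariance-structure fit indices from the fitted and
#' baseline (independence) models:
#' \itemize{
#'   \item RMSEA \eqn{= \sqrt{\max(T - df, 0) / (df (N-1))}} (0 when df = 0);
#'   \item SRMR: root of the mean squared correlation-metric standardized
#'     residual \eqn{(s_{ij}-\sigma_{ij})/\sqrt{s_{ii}s_{jj}}} over the lower
#'     triangle including the diagonal;
#'   \item GFI \eqn{= 1 - tr((\Sigma^{-1}S - I)^2)/tr((\Sigma^{-1}S)^2)};
#'   \item CFI \eqn{= 1 - \max(T-df,0)/\max(T_b-df_b,\ T-df,\ 0)} (1 when the
#'     denominator is 0).
#' }
#' When the fit carries a mean-adjusted scaling factor, scaled RMSEA/CFI
#' computed from \eqn{T/c} (and the baseline's own scaled statistic) are
#' included; they reduce to the plain values when c = 1.
#'
#' @param fit a `path_model_fit`.
#' @param baseline optional baseline fit statistics as returned by
#'   [baseline_model()]; computed from `fit$S` when absent.
#' @return list with `rmsea`, `srmr`, `gfi`, `cfi`, `T`, `df`, `T_baseline`,
#'   `df_baseline` and, when available, `rmsea_scaled`, `cfi_scaled`.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  S <- fit$S; Sigma <- fit$Sigma; N <- fit$N
  Tstat <- fit$T; df <- fit$df
  if (is.null(baseline)) baseline <- baseline_model(S, N)
  p <- nrow(S)
  rmsea <- if (df <= 0) 0 else sqrt(max(Tstat - df, 0) / (df * (N - 1)))
  sd_ <- sqrt(diag(S))
  R <- (S - Sigma) / tcrossprod(sd_)
  srmr <- sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
  M <- solve(Sigma, S)
  gfi <- 1 - sum(diag((M - diag(p)) %*% (M - diag(p)))) / sum(diag(M %*% M))
  cfi_of <- function(Tt, Tb) {
    den <- max(Tb - baseline$df, Tt - df, 0)
    if (den <= 0) 1 else 1 - max(Tt - df, 0) / den
  }
  out <- list(rmsea = rmsea, srmr = srmr, gfi = gfi,
              cfi = cfi_of(Tstat, baseline$T),
              T = Tstat, df = df,
              T_baseline = baseline$T, df_baseline = baseline$df)
  if (!is.null(fit$scaling_c) && is.finite(fit$scaling_c)) {
    Tb_sc <- if (is.finite(baseline$T_scaled)) baseline$T_scaled
             else baseline$T / fit$scaling_c
    Tsc <- if (df > 0) Tstat / fit$scaling_c else 0
    out$rmsea_scaled <- if (df <= 0) 0 else
      sqrt(max(Tsc - df, 0) / (df * (N - 1)))
    out$cfi_scaled <- cfi_of(Tsc, Tb_sc)
  }
  out
}

#' Independence (baseline) model statistics
#'
#' The baseline model frees every variance and fixes all covariances to zero,
#' so its implied covariance is `diag(diag(S))` and its discrepancy has the
#' closed form \eqn{F_b = -\ln|R|} with R the sample correlation matrix.
#'
#' @param S sample covariance matrix.
#' @param N sample size.
#' @param data optional raw data to compute a mean-adjusted scaled baseline
#'   statistic.
#' @return list with `T`, `df`, `fml`, and `T_scaled` (NA without data).
#' @export
baseline_model <- function(S, N, data = NULL) {
  p <- nrow(S)
  R <- stats::cov2cor(S)
  fb <- -determinant(R, logarithm = TRUE)$modulus[[1]]
  Tb <- max((N - 1) * fb, 0)
  dfb <- p * (p + 1) / 2 - p
  Tb_sc <- NA_real_
  if (!is.null(data)) {
    # scaling for the diagonal model: parameters are the p variances
    Zc <- scale(as.matrix(data), center = TRUE, scale = FALSE)
    n <- nrow(Zc)
    idx <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
    Dmat <- Zc[, idx[, 1L], drop = FALSE] * Zc[, idx[, 2L], drop = FALSE]
    dbar <- colMeans(Dmat)
    G4 <- crossprod(Dmat) / n - tcrossprod(dbar)
    Sigb <- diag(diag(S), p)
    Sinv <- solve(Sigb)
    Dp <- duplication_matrix(p)
    W <- 0.5 * t(Dp) %*% (Sinv %x% Sinv) %*% Dp
    # Delta: derivative of vech(diag(v)) wrt the p variances
    ps <- p * (p + 1) / 2
    Delta <- matrix(0, ps, p)
    pos <- 0L
    for (j in seq_len(p)) for (i in j:p) {
      pos <- pos + 1L
      if (i == j) Delta[pos, j] <- 1
    }
    WD <- W %*% Delta
    U <- W - WD %*% solve(crossprod(Delta, WD), t(WD))
    cb <- max(sum(U * G4), 1e-12) / dfb
    Tb_sc <- Tb / cb
  }
  list(T = Tb, df = dfb, fml = fb, T_scaled = Tb_sc)
}
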