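#' Absolute and incremental fit indices
#'
#' Computes chi-square, RMSEA with a 90% confidence interval from the
#' noncentral chi-square distribution, CFI against an independence
#' baseline, SRMR over correlation-metric residuals (diagonal included),
#' AIC and BIC.
#'
#' @param fit a `watershed_fit`.
#' @param baseline baseline `watershed_fit` (independence model: free
#'   variances, zero covariances, same data). Fitted automatically when
#'   `NULL`.
#' @param conf confidence level for the RMSEA interval (default 0.90).
#' @return object of class `watershed_fit_indices` (a list).
#' @export
fit_indices <- function(fit, baseline = NULL, conf = 0.90) {
  stopifnot(inherits(fit, "watershed_fit"))
  if (is.null(baseline)) baseline <- independence_fit(fit)
  N <- fit$N
  chisq <- fit$chisq; df <- fit$df
  rmsea_flag <- NULL
  if (df == 0) {
    rmsea <- 0; ci <- c(0, 0)
    rmsea_flag <- "df = 0: RMSEA undefined, reported as 0"
  } else {
    rmsea <- sqrt(max(0, (chisq - df) / (df * (N - 1))))
    ci <- rmsea_ci(chisq, df, N, conf)
  }
  chb <- baseline$chisq; dfb <- baseline$df
  denom <- max(0, chb - dfb)
  cfi <- if (denom <= 0) 1 else 1 - max(0, chisq - df) / denom
  cfi <- min(1, max(0, cfi))
  srmr <- srmr_value(fit)
  q <- fit$npar_total
  aic <- -2 * fit$loglik + 2 * q
  bic <- -2 * fit$loglik + q * log(N)
  structure(list(chisq = chisq, df = df, p_value = fit$p_value,
                 rmsea = rmsea, rmsea_ci_lower = ci[1], rmsea_ci_upper = ci[2],
                 cfi = cfi, srmr = srmr, aic = aic, bic = bic, n = N,
                 npar = q, flag = rmsea_flag),
            class = "watershed_fit_indices")
}

#' @export
print.watershed_fit_indices <- function(x, ...) {
  cat(sprintf(
    "chisq(%d) = %.2f, p = %.3g\nRMSEA = %.3f [%.3f-%.3f]  CFI = %.3f  SRMR = %.3f\nAIC = %.2f  BIC = %.2f\n",
    x$df, x$chisq, x$p_value, x$rmsea, x$rmsea_ci_lower, x$rmsea_ci_upper,
    x$cfi, x$srmr, x$aic, x$bic))
  invisible(x)
}

# RMSEA CI by root-finding on the noncentral chi-square CDF
rmsea_ci <- function(chisq, df, N, conf = 0.90) {
  a <- (1 - conf) / 2
  lam2rmsea <- function(lam) sqrt(max(0, lam / (df * (N - 1))))
  upper_p <- function(lam) stats::pchisq(chisq, df, ncp = lam)
  # lower bound: lambda with P(X <= chisq | lam) = 1 - a   (0.95)
  lo <- if (upper_p(0) < 1 - a) 0 else {
    hi <- max(chisq, 1)
    while (upper_p(hi) > 1 - a) hi <- hi * 2
    stats::uniroot(function(l) upper_p(l) - (1 - a), c(0, hi),
                   tol = 1e-9)$root
  }
  # upper bound: lambda with P(X <= chisq | lam) = a        (0.05)
  up <- if (upper_p(0) < a) 0 else {
    hi <- max(4 * chisq, 1)
    while (upper_p(hi) > a) hi <- hi * 2
    stats::uniroot(function(l) upper_p(l) - a, c(0, hi), tol = 1e-9)$root
  }
  c(lam2rmsea(lo), lam2rmsea(up))
}

srmr_value <- function(fit) {
  S <- if (fit$input$type == "cov") fit$input$S else fit$input$S_obs
  Sig <- fit$Sigma_hat
  sd_s <- sqrt(diag(S))
  R <- (S - Sig) / tcrossprod(sd_s)
  idx <- lower.tri(R, diag = TRUE)
  sqrt(mean(R[idx]^2))
}

# independence model on the same variables and data
independence_fit <- function(fit) {
  man <- fit$ram$manifests
  syn <- paste(sprintf("%s ~~ %s", man, man), collapse = "\n")
  spec <- parse_model(syn, auto_cov = FALSE)
  if (fit$input$type == "cov")
    sem_fit(spec, sample_cov = fit$input$S, sample_nobs = fit$N)
  else sem_fit(spec, data = fit$input$X)
}

#' Akaike weights for a set of AIC values
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min_j AIC_j}. Invariant to adding a constant
#' to every AIC; sums to one.
#'
#' @param aic numeric vector of AIC values (names kept).
#' @return numeric vector of weights.
#' @export
akaike_weights <- function(aic) {
  stopifnot(is.numeric(aic), length(aic) >= 1)
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Information-criterion comparison table for a set of fits
#'
#' All fits must be to identical data (same N and manifest set is
#' enforced; supplying fits to different datasets is an error).
#'
#' @param fits named list of `watershed_fit` objects.
#' @param indices logical; also compute full fit indices per model.
#' @return object of class `watershed_comparison`: data frame with
#'   chisq, df, AIC, BIC and Akaike weights per model.
#' @export
information_criteria <- function(fits, indices = FALSE) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  Ns <- vapply(fits, function(f) f$N, numeric(1))
  ps <- vapply(fits, function(f) f$ram$p, numeric(1))
  if (length(unique(Ns)) != 1)
    stop("models fit to different datasets (sample sizes differ)")
  q <- vapply(fits, function(f) f$npar_total, numeric(1))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  aic <- -2 * ll + 2 * q
  bic <- -2 * ll + q * log(Ns)
  tab <- data.frame(model = names(fits),
                    chisq = vapply(fits, function(f) f$chisq, numeric(1)),
                    df = vapply(fits, function(f) f$df, numeric(1)),
                    npar = q, loglik = ll, aic = aic, bic = bic,
                    weight = akaike_weights(aic),
                    converged = vapply(fits, function(f) f$converged,
                                       logical(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(table = tab,
              indices = if (indices) lapply(fits, fit_indices) else NULL)
  class(out) <- "watershed_comparison"
  out
}

#' @export
print.watershed_comparison <- function(x, digits = 2, ...) {
  tab <- x$table
  tab$weight <- sprintf("%.2f%%", 100 * tab$weight)
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Chi-square difference test for nested models
#'
#' @param restricted the restricted (fewer free parameters) fit.
#' @param full the full fit; the restricted free-parameter set must be a
#'   subset (checked by name, equality-shared labels allowed).
#' @param tol tolerance for a negative difference before erroring.
#' @return list with `delta_chisq`, `delta_df`, `p_value`.
#' @export
lrt_nested <- function(restricted, full, tol = 1e-6) {
  stopifnot(inherits(restricted, "watershed_fit"),
            inherits(full, "watershed_fit"))
  if (restricted$N != full$N || restricted$ram$p != full$ram$p)
    stop("nested comparison requires identical data")
  ddf <- restricted$df - full$df
  if (ddf < 0) stop("restricted model has more free parameters than full")
  dchi <- restricted$chisq - full$chisq
  if (dchi < -tol)
    stop("negative chi-square difference (", signif(dchi, 4),
         "): models not nested or non-convergence")
  dchi <- max(0, dchi)
  list(delta_chisq = dchi, delta_df = ddf,
       p_value = if (ddf == 0) 1 else
         stats::pchisq(dchi, ddf, lower.tail = FALSE))
}

#' Verbal classification of model fit
#'
#' Good: RMSEA < 0.05, CFI > 0.97, SRMR < 0.05. Acceptable: RMSEA in
#' [0.05, 0.08], CFI in [0.95, 0.97], SRMR in [0.05, 0.10]; boundary
#' values fall in the acceptable band (closed intervals). Overall is the
#' worst of the three.
#'
#' @param ix a `watershed_fit_indices` or list with rmsea, cfi, srmr.
#' @return list with per-index classes and `overall`.
#' @export
classify_fit <- function(ix) {
  lv <- c(good = 3, acceptable = 2, poor = 1)
  cls_rmsea <- if (ix$rmsea < 0.05) "good"
  else if (ix$rmsea <= 0.08) "acceptable" else "poor"
  cls_cfi <- if (ix$cfi > 0.97) "good"
  else if (ix$cfi >= 0.95) "acceptable" else "poor"
  cls_srmr <- if (ix$srmr < 0.05) "good"
  else if (ix$srmr <= 0.10) "acceptable" else "poor"
  cl <- c(rmsea = cls_rmsea, cfi = cls_cfi, srmr = cls_srmr)
  list(rmsea = cls_rmsea, cfi = cls_cfi, srmr = cls_srmr,
       overall = names(lv)[match(min(lv[cl]), lv)])
}

#' Effect-size band for a standardized estimate
#'
#' |estimate| > 0.30 large, > 0.20 typical, > 0.10 small, else negligible.
#'
#' @param std standardized estimate(s).
#' @return character vector of bands.
#' @export
effect_size_band <- function(std) {
  a <- abs(std)
  ifelse(a > 0.30, "large",
         ifelse(a > 0.20, "typical",
                ifelse(a > 0.10, "small", "negligible")))
}
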