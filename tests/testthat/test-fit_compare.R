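# minimal stand-in fit object for direct formula checks
fake_fit <- function(chisq, df, N, p = 8) {
  S <- diag(p); dimnames(S) <- list(paste0("v", 1:p), paste0("v", 1:p))
  structure(list(chisq = chisq, df = df, N = N,
                 p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
                 loglik = -1000, npar_total = p * (p + 1) / 2 - df,
                 input = list(type = "cov", S = S), Sigma_hat = S,
                 ram = list(p = p)),
            class = "watershed_fit")
}

test_that("fit indices implement the pinned formulas", {
  # chisq == df -> RMSEA 0; CFI direct formula
  ix <- fit_indices(fake_fit(18, 18, 551), baseline = fake_fit(500, 28, 551))
  expect_equal(ix$rmsea, 0)
  ix2 <- fit_indices(fake_fit(40, 18, 551), baseline = fake_fit(500, 28, 551))
  expect_equal(ix2$cfi, 1 - 22 / 472, tolerance = 1e-12)
  expect_equal(ix2$rmsea, sqrt((40 - 18) / (18 * 550)), tolerance = 1e-12)
  # saturated model: SRMR 0, CFI 1, flagged RMSEA
  ix3 <- fit_indices(fake_fit(0, 0, 551), baseline = fake_fit(500, 28, 551))
  expect_equal(ix3$srmr, 0); expect_equal(ix3$cfi, 1)
  expect_match(ix3$flag, "df = 0")
})

test_that("RMSEA confidence interval matches an independent oracle", {
  # published 3-factor fit: chisq(18) = 41.74, N = 551 -> 0.049 [.030, .068]
  ix <- fit_indices(fake_fit(41.74, 18, 551),
                    baseline = fake_fit(2000, 28, 551))
  expect_equal(round(ix$rmsea, 3), 0.049)
  expect_equal(round(ix$rmsea_ci_lower, 3), 0.030)
  # published upper bound used the robust-scaled statistic; plain-ML value
  # agrees to ~5e-4
  expect_lt(abs(ix$rmsea_ci_upper - 0.068), 1e-3)
  # oracle: numeric integration of the noncentral density instead of pchisq
  ncp_cdf <- function(q, df, ncp)
    stats::integrate(function(x) stats::dchisq(x, df, ncp), 0, q,
                     rel.tol = 1e-10)$value
  lam_lo <- 18 * 550 * ix$rmsea_ci_lower^2
  lam_hi <- 18 * 550 * ix$rmsea_ci_upper^2
  expect_equal(ncp_cdf(41.74, 18, lam_lo), 0.95, tolerance = 1e-6)
  expect_equal(ncp_cdf(41.74, 18, lam_hi), 0.05, tolerance = 1e-6)
})

test_that("Akaike weights are correct, normalized and shift-invariant", {
  expect_equal(akaike_weights(c(5, 5, 5)), rep(1 / 3, 3))
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.731, 0.269))
  for (k in 1:5) {
    set.seed(k)
    a <- rnorm(6, 1000, 10)
    expect_equal(sum(akaike_weights(a)), 1)
    expect_equal(akaike_weights(a), akaike_weights(a + 123.4),
                 tolerance = 1e-12)
  }
})

test_that("printed measurement-model AICs reproduce printed weights", {
  w_nki <- akaike_weights(c(single = 7155.64, twoA = 7155.74,
                            twoB = 7109.43, three = 7102.74))
  expect_equal(unname(round(100 * w_nki, 2)), c(0, 0, 3.40, 96.60),
               tolerance = 0.1)
  w_calm <- akaike_weights(c(single = 9697.18, twoA = 9696.44,
                             twoB = 9668.58, three = 9670.55))
  expect_equal(unname(round(100 * w_calm, 2)), c(0, 0, 72.85, 27.15),
               tolerance = 0.2)
})

test_that("nested likelihood-ratio tests behave and guard misuse", {
  f <- fake_fit(40, 18, 551)
  same <- lrt_nested(f, f)
  expect_equal(same$delta_chisq, 0)
  expect_equal(same$delta_df, 0)
  expect_equal(same$p_value, 1)
  expect_error(lrt_nested(fake_fit(40, 18, 551), fake_fit(10, 20, 551)),
               "more free parameters")
  expect_error(lrt_nested(fake_fit(10, 20, 551), fake_fit(40, 18, 551)),
               "negative chi-square")
  expect_error(lrt_nested(fake_fit(40, 18, 551), fake_fit(30, 17, 300)),
               "identical data")
})

test_that("equality constraints on unequal paths are detected with power", {
  # paths 0.5 vs 0.2: rejection rate near 1 at alpha = .05
  rej <- vapply(1:40, function(i) {
    dat <- gen_two_path(2000, 500 + i, b1 = 0.5, b2 = 0.2, rho = 0.3)
    S <- stats::cov(dat)
    ff <- sem_fit(parse_model("y ~ x1 + x2"), sample_cov = S,
                  sample_nobs = 2000)
    fr <- sem_fit(parse_model("y ~ b*x1 + b*x2"), sample_cov = S,
                  sample_nobs = 2000)
    lrt_nested(fr, ff)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("fit classification applies the published bands", {
  cl1 <- classify_fit(list(rmsea = 0.026, cfi = 0.981, srmr = 0.043))
  expect_equal(cl1$overall, "good")
  cl2 <- classify_fit(list(rmsea = 0.053, cfi = 0.928, srmr = 0.088))
  expect_equal(cl2$rmsea, "acceptable")
  expect_equal(cl2$cfi, "poor")
  expect_equal(cl2$srmr, "acceptable")
  expect_equal(cl2$overall, "poor")
  # closed boundary: exactly 0.05 RMSEA is acceptable, not good
  expect_equal(classify_fit(list(rmsea = 0.05, cfi = 0.99,
                                 srmr = 0.01))$rmsea, "acceptable")
  expect_equal(effect_size_band(c(0.05, 0.15, 0.25, 0.72)),
               c("negligible", "small", "typical", "large"))
})

test_that("AIC ordering and decisive LRTs agree on nested fixtures", {
  cc <- calm_cohort(800, seed = 77)
  b <- cc$config$battery
  S <- stats::cov(cc$data[, task_cols(b)])
  ff <- sem_fit(build_cognitive_regression(b, "free"), sample_cov = S,
                sample_nobs = 800)
  fz <- sem_fit(build_cognitive_regression(b, "zero_memory"),
                sample_cov = S, sample_nobs = 800)
  lrt <- lrt_nested(fz, ff)
  cmp <- information_criteria(list(free = ff, zero_memory = fz))
  if (lrt$delta_chisq > 20 && lrt$delta_df <= 2)
    expect_lt(cmp$table$aic[1], cmp$table$aic[2])
  expect_gt(lrt$delta_chisq, 20)  # memory contributes strongly by design
})

test_that("information_criteria validates input and normalizes weights", {
  expect_error(information_criteria(list()), "length")
  f1 <- fake_fit(40, 18, 551); f2 <- fake_fit(30, 17, 300)
  expect_error(information_criteria(list(f1, f2)), "different datasets")
})
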