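test_that("implied covariance follows the RAM algebra", {
  # no paths: Sigma = diag of the residuals
  s <- parse_model("a ~~ 2*a\nb ~~ 3*b", auto_cov = FALSE)
  ram <- build_ram(s)
  expect_equal(implied_covariance(ram, numeric(0)),
               diag(c(2, 3)), ignore_attr = TRUE)
  # one factor, loadings (1, 1), factor variance 1, residuals 0
  s2 <- parse_model("f =~ 1*a + 1*b\na ~~ 0*a\nb ~~ 0*b\nf ~~ 1*f")
  expect_equal(implied_covariance(build_ram(s2), numeric(0)),
               matrix(1, 2, 2), ignore_attr = TRUE)
})

test_that("implied covariance matches a Monte-Carlo oracle", {
  # moderate draw count here; the full 1e6-draw check runs in acceptance
  cfg <- cohort_config("calm", n = 200000, imaging_fraction = 1, seed = 31)
  dat <- preprocess_speed(generate_cohort(cfg), cfg$battery)$data
  cols <- c(task_cols(cfg$battery), cfg$battery$tracts)
  S_emp <- stats::cov(dat[, cols])
  S_thr <- config_implied_cov(cfg)[cols, cols]
  expect_lt(max(abs(S_emp - S_thr)), 0.02)
})

test_that("ml_discrepancy implements F_ML", {
  S <- triad_cov()
  expect_equal(ml_discrepancy(S, S), 0)
  S2 <- matrix(c(2, 1, 1, 2), 2); Sig2 <- diag(2) * 2
  expect_equal(ml_discrepancy(S2, Sig2), log(4 / 3), tolerance = 1e-12)
  # permutation symmetry
  set.seed(5)
  A <- crossprod(matrix(rnorm(25), 5)); B <- crossprod(matrix(rnorm(25), 5))
  pr <- sample(5)
  expect_equal(ml_discrepancy(A, B), ml_discrepancy(A[pr, pr], B[pr, pr]))
  expect_error(ml_discrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "eigenvalue")
})

test_that("covariance fit equals the closed-form triad solution", {
  set.seed(7)
  dat <- gen_factor_data(300, 7, c(0.8, 0.7, 0.6), names = c("a", "b", "c"))
  S <- stats::cov(dat)
  f <- sem_fit(parse_model("f =~ a + b + c"), sample_cov = S,
               sample_nobs = 300)
  expect_true(f$converged)
  oracle <- triad_solution(S)
  expect_equal(unname(f$theta["f=~b"]), unname(oracle["lambda2"]),
               tolerance = 1e-6)
  expect_equal(unname(f$theta["f=~c"]), unname(oracle["lambda3"]),
               tolerance = 1e-6)
  expect_equal(unname(f$theta["f~~f"]), unname(oracle["psi"]),
               tolerance = 1e-6)
  expect_equal(unname(f$theta[c("a~~a", "b~~b", "c~~c")]),
               unname(oracle[c("theta1", "theta2", "theta3")]),
               tolerance = 1e-6)
})

test_that("FIML reduces to covariance ML without missingness", {
  set.seed(11)
  dat <- gen_factor_data(400, 11, c(0.8, 0.7, 0.6), names = c("a", "b", "c"))
  spec <- parse_model("f =~ a + b + c")
  ctl <- list(grad_tol = 1e-8, rel_tol = 1e-14)
  fr <- sem_fit(spec, data = dat, control = ctl)
  N <- nrow(dat)
  # identity: 2(l_sat - l_model) = N * F_ML on the biased covariance
  Sb <- stats::cov(dat) * (N - 1) / N
  expect_equal(fr$chisq, N * ml_discrepancy(Sb, fr$Sigma_hat),
               tolerance = 1e-8)
  # estimates equal the covariance-ML fit to the ML (biased) covariance
  fc <- sem_fit(spec, sample_cov = Sb, sample_nobs = N, control = ctl)
  expect_equal(fr$theta, fc$theta, tolerance = 1e-6)
  # duplicating every row exactly doubles the casewise log-likelihood
  ram <- build_ram(spec)
  ll1 <- fiml_loglik(dat, ram, fr$theta, mu = fr$mu)
  ll2 <- fiml_loglik(rbind(dat, dat), ram, fr$theta, mu = fr$mu)
  expect_equal(as.numeric(ll2), 2 * as.numeric(ll1), tolerance = 1e-10)
})

test_that("FIML recovers truth under MCAR missingness", {
  set.seed(13)
  n <- 20000
  lam <- c(0.8, 0.7, 0.6, 0.75)
  dat <- gen_factor_data(n, 13, lam, names = c("a", "b", "c", "d"))
  full <- dat
  dat$b[sample(n, round(0.3 * n))] <- NA
  dat$c[sample(n, round(0.3 * n))] <- NA
  spec <- parse_model("f =~ a + b + c + d")
  fm <- sem_fit(spec, data = dat)
  fc <- sem_fit(spec, data = full)
  expect_true(fm$converged)
  expect_equal(fm$theta, fc$theta, tolerance = 0.05)
  # against the generating loadings (marker scale)
  expect_equal(unname(fm$theta["f=~b"]), lam[2] / lam[1], tolerance = 0.05)
  # all-missing rows are dropped and logged
  dat2 <- dat; dat2[1:7, ] <- NA
  fdrop <- sem_fit(spec, data = dat2)
  expect_match(paste(fdrop$messages, collapse = " "), "7 all-missing")
})

test_that("standardized solutions behave like correlations where they must", {
  # 2-factor toy: standardized latent covariance is psi12 / sqrt(psi11 psi22)
  cc <- calm_cohort(500, seed = 17)
  b <- cc$config$battery
  S <- stats::cov(cc$data[, task_cols(b)])
  f <- sem_fit(build_measurement_model(b, "three"), sample_cov = S,
               sample_nobs = 500)
  std <- standardized_solution(f)
  th <- f$theta
  expect_equal(
    std$std[std$lhs == "gf" & std$rhs == "wm" & std$op == "~~"],
    unname(th["gf~~wm"] / sqrt(th["gf~~gf"] * th["wm~~wm"])),
    tolerance = 1e-10)
  lat_cor <- std$std[std$op == "~~" & std$lhs %in% f$ram$latents &
                       std$rhs %in% f$ram$latents & std$lhs != std$rhs]
  expect_true(all(abs(lat_cor) <= 1))
})

test_that("suppression pushes standardized paths past -1", {
  # two predictors correlated .95 with opposing true paths
  dat <- gen_two_path(20000, 19, b1 = 1.2, b2 = -0.8, rho = 0.95,
                      resid = 0.2)
  f <- sem_fit(parse_model("y ~ x1 + x2"), sample_cov = stats::cov(dat),
               sample_nobs = nrow(dat))
  std <- standardized_solution(f)
  b2_std <- std$std[std$op == "~" & std$rhs == "x2"]
  expect_lt(b2_std, -1)
})

test_that("r_squared matches its definition and guards inputs", {
  S <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("y", "x"),
                                                    c("y", "x")))
  f <- sem_fit(parse_model("y ~ x"), sample_cov = S, sample_nobs = 1000)
  expect_equal(unname(r_squared(f, "y")), 0.36, tolerance = 1e-6)
  expect_error(r_squared(f, "x"), "not endogenous")
  f0 <- sem_fit(parse_model("y ~ 0*x"), sample_cov = S, sample_nobs = 1000)
  expect_equal(unname(r_squared(f0, "y")), 0)
})

test_that("factor scores are regression scores", {
  # single-indicator latent: score equals the centered indicator
  cc <- calm_cohort(300, seed = 23)
  f <- sem_fit(build_measurement_model(cc$config$battery, "three"),
               data = cc$data)
  sc <- factor_scores(f)
  mr <- cc$data$matrix_reasoning
  expect_equal(unname(sc[, "gf"]), unname(mr - f$mu["matrix_reasoning"]),
               tolerance = 1e-8)
  # permuting rows permutes scores identically
  pr <- sample(nrow(cc$data))
  sc2 <- factor_scores(f, cc$data[pr, ])
  expect_equal(sc2, sc[pr, ], tolerance = 1e-12)
  # high-reliability battery: scores track the true factor
  dat <- gen_factor_data(10000, 29, rep(0.8, 6))
  fs <- sem_fit(parse_model(paste("f =~", paste(colnames(dat),
                                                collapse = " + "))),
                data = dat)
  s <- factor_scores(fs)
  expect_gt(stats::cor(s[, "f"], attr(gen_factor_data(10000, 29, rep(0.8, 6)),
                                      "eta")), 0.95)
})

test_that("reported solutions are optimizer-clean", {
  # converged flag implies small analytic gradient; jittered restarts agree
  set.seed(37)
  dat <- gen_factor_data(500, 37, c(0.8, 0.7, 0.6, 0.5))
  spec <- parse_model(paste("f =~", paste(colnames(dat), collapse = " + ")))
  S <- stats::cov(dat)
  f <- sem_fit(spec, sample_cov = S, sample_nobs = 500)
  expect_true(f$converged)
  expect_lte(f$gmax, 1e-5)
  base <- start_values <- f$theta
  fmins <- vapply(1:10, function(k) {
    st <- f$theta * (1 + 0.25 * sin(seq_along(f$theta) + k))
    sem_fit(spec, sample_cov = S, sample_nobs = 500, start = st)$F_min
  }, numeric(1))
  expect_lt(max(fmins) - min(fmins), 1e-6)
})

test_that("Heywood cases are flagged, not hidden", {
  S <- matrix(c(1, .8, .8, .8, 1, .5, .8, .5, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  f <- sem_fit(parse_model("f =~ a + b + c"), sample_cov = S,
               sample_nobs = 200)
  expect_true(f$heywood)
  expect_match(paste(f$messages, collapse = " "), "Heywood")
})

test_that("observed-information standard errors are calibrated", {
  # z = est/se approximately N(0,1) across replicates for a true null path
  zs <- vapply(1:40, function(i) {
    dat <- gen_two_path(500, 400 + i, b1 = 0.5, b2 = 0, rho = 0.3)
    f <- sem_fit(parse_model("y ~ x1 + x2"), sample_cov = stats::cov(dat),
                 sample_nobs = 500, se = "observed")
    unname(f$theta["y~x2"] / f$se["y~x2"])
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.5)
  expect_gt(stats::sd(zs), 0.6); expect_lt(stats::sd(zs), 1.6)
})
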