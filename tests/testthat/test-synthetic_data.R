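test_that("generation is seed-reproducible and seed-sensitive", {
  cfg <- cohort_config("calm", n = 400, seed = 101)
  d1 <- generate_cohort(cfg)
  d2 <- generate_cohort(cfg)
  expect_identical(d1, d2)
  cfg2 <- cohort_config("calm", n = 400, seed = 102)
  d3 <- generate_cohort(cfg2)
  expect_false(identical(d1$matrix_reasoning, d3$matrix_reasoning))
  # different seeds, same distribution: covariances agree loosely
  big1 <- generate_cohort(cohort_config("calm", n = 20000,
                                        imaging_fraction = 1, seed = 103))
  big2 <- generate_cohort(cohort_config("calm", n = 20000,
                                        imaging_fraction = 1, seed = 104))
  cols <- cohort_battery("calm")$wm
  expect_lt(max(abs(stats::cov(big1[, cols]) - stats::cov(big2[, cols]))),
            0.06)
})

test_that("imaging missingness hits the configured fraction", {
  cfg <- cohort_config("calm", n = 10000, seed = 107)  # 165/551 default
  d <- generate_cohort(cfg)
  frac <- mean(!is.na(d$slf))
  expect_lt(abs(frac - 165 / 551), 0.02)
  # tract columns are jointly missing (modality-level missingness)
  expect_identical(is.na(d$slf), is.na(d$ilf))
  # cognitive tasks unaffected
  expect_false(anyNA(d[, cohort_battery("calm")$wm]))
})

test_that("degenerate residuals make indicators collinear", {
  cfg <- cohort_config("calm", n = 200, imaging_fraction = 1, seed = 109,
                       loading = 1)
  d <- generate_cohort(cfg)
  b <- cfg$battery
  expect_equal(stats::cor(d$digit_recall, d$backward_digit), 1)
  expect_equal(stats::cor(d$digit_recall, d$dot_matrix), 1)
})

test_that("generated covariance matches the configured truth", {
  cfg <- cohort_config("calm", n = 100000, imaging_fraction = 1, seed = 113)
  d <- preprocess_speed(generate_cohort(cfg), cfg$battery)$data
  cols <- c(task_cols(cfg$battery), cfg$battery$tracts)
  expect_lt(max(abs(stats::cov(d[, cols]) -
                      config_implied_cov(cfg)[cols, cols])), 0.03)
})

test_that("speed preprocessing matches the published transforms", {
  b <- cohort_battery("calm")
  d <- data.frame(digit_recall = 1, backward_digit = 1, dot_matrix = 1,
                  mr_x = 1, matrix_reasoning = 1,
                  trails = c(1, exp(-1), 2), rapid_naming = 1, rbbs = 1)
  out <- preprocess_speed(d, b)
  expect_equal(out$data$trails, c(0, 1, -log(2)))  # y = log(1/x)
  # monotonic: faster raw time -> larger transformed speed
  x <- sort(stats::rlnorm(50))
  d2 <- d[rep(1, 50), ]; d2$trails <- x
  y <- preprocess_speed(d2, b)$data$trails
  expect_true(all(diff(y) < 0))
  # nonpositive response times flagged invalid
  d3 <- d[rep(1, 4), ]; d3$trails <- c(0.5, 0, -1, 2)
  out3 <- preprocess_speed(d3, b)
  expect_equal(out3$exclusions$n_invalid[out3$exclusions$task == "trails"], 2)
  expect_true(all(is.na(out3$data$trails[2:3])))
})

test_that("the 2 SD trim removes the expected normal tail mass", {
  nki <- cohort_battery("nki")
  set.seed(127)
  n <- 100000
  d <- data.frame(trails = stats::rlnorm(n), motor_speed = stats::rnorm(n),
                  sensory_motor = stats::rlnorm(n))
  out <- preprocess_speed(d, nki)
  trimmed <- out$exclusions$n_trimmed[out$exclusions$task == "motor_speed"]
  expect_equal(trimmed / n, 2 * stats::pnorm(-2), tolerance = 0.1)
  expect_equal(sum(is.na(out$data$motor_speed)), trimmed)
})

test_that("age-moderated generation reduces to the constant model", {
  base <- cohort_config("calm", n = 800, imaging_fraction = 1, seed = 131)
  const <- cohort_config("calm", n = 800, imaging_fraction = 1, seed = 131,
                         age_effect = list(
                           "gf~wm" = function(a) rep(0.72, length(a))))
  d_base <- generate_cohort(base)
  d_const <- age_moderated_cohort(const)
  expect_equal(d_base, d_const)
  expect_error(age_moderated_cohort(base), "age_effect")
})

test_that("dip-shaped path profiles are recoverable segment by segment", {
  dip <- function(a) ifelse(a < 8, 0.8, ifelse(a < 12, 0.2, 0.9))
  cfg <- cohort_config("calm", n = 9000, imaging_fraction = 1, seed = 137,
                       age_effect = list("gf~wm" = dip))
  dat <- preprocess_speed(age_moderated_cohort(cfg), cfg$battery)$data
  spec <- build_cognitive_regression(cfg$battery, "free")
  seg <- cut(dat$age, c(-Inf, 8, 12, Inf), labels = FALSE)
  est <- vapply(1:3, function(s) {
    f <- sem_fit(spec, data = dat[seg == s, ])
    # marker scale: latent wm is scaled by its first loading (0.7)
    unname(f$theta["gf~wm"]) * cfg$loading
  }, numeric(1))
  expect_equal(est, c(0.8, 0.2, 0.9), tolerance = 0.12)
  expect_true(which.min(est) == 2)
})

test_that("ages are uniform over the configured range", {
  cfg <- cohort_config("calm", n = 10000, seed = 139)
  d <- generate_cohort(cfg)
  ks <- suppressWarnings(
    stats::ks.test(d$age, "punif", cfg$age_range[1], cfg$age_range[2]))
  expect_lt(unname(ks$statistic), 0.02)
  expect_gte(min(d$age), cfg$age_range[1])
  expect_lte(max(d$age), cfg$age_range[2])
})

test_that("generated columns drive the whole pipeline unchanged", {
  for (cohort in c("calm", "nki")) {
    cfg <- cohort_config(cohort, n = 300, seed = 149)
    d <- generate_cohort(cfg)
    expect_true(all(c("id", "age", task_cols(cfg$battery),
                      cfg$battery$tracts) %in% colnames(d)))
  }
})
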