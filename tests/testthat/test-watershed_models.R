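test_that("cohort batteries carry the published task structure", {
  calm <- cohort_battery("calm"); nki <- cohort_battery("nki")
  expect_length(calm$wm, 4); expect_length(calm$gf, 1)
  expect_length(calm$speed, 3)
  expect_length(nki$wm, 3); expect_length(nki$gf, 4); expect_length(nki$speed, 3)
  expect_length(calm$tracts, 10)
  expect_setequal(calm$tracts, c("uf", "slf", "ifof", "atr", "cst",
                                 "fmaj", "fmin", "cg", "ch", "ilf"))
  expect_false(anyDuplicated(task_cols(calm)) > 0)
  # speed-native task is trimmed, not inverted
  expect_false(nki$speed_rt[["motor_speed"]])
  expect_true(nki$speed_trim[["motor_speed"]])
})

test_that("df bookkeeping for every variant matches the hand enumeration", {
  # frozen fixture table, hand-enumerated from p(p+1)/2 - q
  expected <- list(
    calm = c(single = 20, twoA = 19, twoB = 19, three = 18,
             original = 78, zero_paths_to_speed = 88,
             zero_paths_to_memory = 88, equal_tract_paths = 96,
             altA = 89, altB = 10, altC = 88, altD = 68),
    nki = c(single = 35, twoA = 34, twoB = 34, three = 32,
            original = 112, zero_paths_to_speed = 122,
            zero_paths_to_memory = 122, equal_tract_paths = 130,
            altA = 123, altB = 40, altC = 122, altD = 102))
  for (cohort in names(expected)) {
    b <- cohort_battery(cohort)
    for (v in names(expected[[cohort]])) {
      spec <- if (v %in% c("single", "twoA", "twoB", "three"))
        build_measurement_model(b, v) else build_watershed(b, v)
      expect_equal(degrees_of_freedom(spec),
                   unname(expected[[cohort]][v]),
                   label = paste(cohort, v))
    }
  }
  expect_equal(degrees_of_freedom(
    build_wm_single_factor(cohort_battery("calm")$tracts)), 35)
  expect_error(build_wm_single_factor(letters[1:9]))
})

test_that("constraint variants shift df exactly as printed", {
  b <- cohort_battery("calm")
  ws <- build_watershed(b, "original")
  expect_equal(degrees_of_freedom(build_watershed(b, "zero_paths_to_speed")) -
                 degrees_of_freedom(ws), 10)
  expect_equal(degrees_of_freedom(build_watershed(b, "equal_tract_paths")) -
                 degrees_of_freedom(ws), 18)
  expect_equal(degrees_of_freedom(build_cognitive_regression(b, "equal_paths")) -
                 degrees_of_freedom(build_cognitive_regression(b, "free")), 1)
})

test_that("single-factor white-matter model detects misfit and fit", {
  # truth with 3 tract clusters: the 1-factor model must fit poorly
  set.seed(41); n <- 5000
  tr <- cohort_battery("calm")$tracts
  block <- rep(1:3, c(4, 3, 3))
  R <- outer(block, block, function(a, b) ifelse(a == b, 0.75, 0.05))
  diag(R) <- 1
  X <- matrix(rnorm(n * 10), n) %*% chol(R)
  colnames(X) <- tr
  f_bad <- sem_fit(build_wm_single_factor(tr), sample_cov = stats::cov(X),
                   sample_nobs = n)
  expect_lt(fit_indices(f_bad)$cfi, 0.95)
  # truth with one factor: the model must fit well
  Y <- gen_factor_data(5000, 43, rep(0.65, 10), names = tr)
  f_good <- sem_fit(build_wm_single_factor(tr), sample_cov = stats::cov(Y),
                    sample_nobs = 5000)
  expect_lt(fit_indices(f_good)$rmsea, 0.05)
})

test_that("single-path probe recovers a lone true path", {
  # truth: only one tract drives working memory; tracts uncorrelated so the
  # probe equals the full-model estimate (no suppression possible)
  cfg <- cohort_config("calm", n = 10000, imaging_fraction = 1, seed = 47,
                       tract_cor = 0)
  cfg$g_w[] <- 0; cfg$g_w["fmin"] <- 0.36
  cfg$g_s[] <- 0
  cfg$resid["wm"] <- 1 - 0.36^2   # unit working-memory variance
  cfg$resid["speed"] <- 1
  cfg$psi_ws <- 0.5
  dat <- preprocess_speed(generate_cohort(cfg), cfg$battery)$data
  pr <- single_path_probe(cfg$battery, "fmin", "wm", data = dat)
  expect_equal(pr$std, 0.36, tolerance = 0.05)
  expect_gt(pr$z, 10)
  full <- sem_fit(build_watershed(cfg$battery, "original"), data = dat)
  full_std <- standardized_solution(full)
  b_full <- full_std$std[full_std$lhs == "wm" & full_std$op == "~" &
                           full_std$rhs == "fmin"]
  expect_equal(pr$std, b_full, tolerance = 0.05)
})

test_that("model selection separates the two watershed architectures", {
  # scaled-down check (10 replicates per direction); the 100-replicate run
  # with the full alternative set is in the acceptance suite
  pick <- function(truth, seed) {
    cfg <- cohort_config("calm", n = 2000, imaging_fraction = 1,
                         seed = seed, truth = truth)
    dat <- preprocess_speed(generate_cohort(cfg), cfg$battery)$data
    S <- stats::cov(dat[, c(task_cols(cfg$battery), cfg$battery$tracts)])
    fo <- sem_fit(build_watershed(cfg$battery, "original"),
                  sample_cov = S, sample_nobs = 2000)
    fa <- sem_fit(build_watershed(cfg$battery, "altA"),
                  sample_cov = S, sample_nobs = 2000)
    information_criteria(list(original = fo, altA = fa))$table$weight
  }
  won_orig <- vapply(1:10, function(i)
    pick("original", 600 + i)[1] > 0.5, logical(1))
  won_alt <- vapply(1:10, function(i)
    pick("altA", 700 + i)[2] > 0.5, logical(1))
  expect_gte(mean(won_orig), 0.8)
  expect_gte(mean(won_alt), 0.8)
})

test_that("the full analysis report is complete, pure and serializable", {
  cc <- calm_cohort(600, seed = 53)
  rep1 <- run_full_analysis(cc$data, cc$config$battery)
  expect_s3_class(rep1, "watershed_report")
  expect_equal(nrow(rep1$measurement$comparison), 4)
  expect_equal(sum(rep1$measurement$comparison$weight), 1)
  expect_named(rep1$watershed$r2, c("wm", "speed", "gf"))
  expect_true(all(unlist(rep1$watershed$r2) >= 0 &
                    unlist(rep1$watershed$r2) <= 1))
  expect_equal(nrow(rep1$watershed$alternatives), 5)
  expect_equal(rep1$watershed$constrained_tests$zero_paths_to_speed$delta_df,
               10)
  # purity: same input, byte-identical JSON
  j1 <- jsonlite::toJSON(unclass(rep1), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  rep2 <- run_full_analysis(cc$data, cc$config$battery)
  j2 <- jsonlite::toJSON(unclass(rep2), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  expect_identical(j1, j2)
  # missing columns abort with a named diagnostic
  expect_error(run_full_analysis(cc$data[, -3], cc$config$battery),
               "lacks columns")
})
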