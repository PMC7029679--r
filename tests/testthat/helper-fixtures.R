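# Shared fixture generators. Everything is seeded by the caller; no fixture
# lives on disk.

# regression y ~ x with an age-dependent path (change point / dip / null)
gen_path_data <- function(n, seed, b_of_age = function(a) 0.5,
                          resid = 0.5, age_range = c(5, 18)) {
  set.seed(seed)
  age <- stats::runif(n, age_range[1], age_range[2])
  x <- stats::rnorm(n)
  y <- b_of_age(age) * x + stats::rnorm(n, 0, sqrt(resid))
  data.frame(age = age, x = x, y = y)
}

# two-predictor regression y ~ x1 + x2 with predictor correlation rho
gen_two_path <- function(n, seed, b1, b2, rho = 0.3, resid = 0.5) {
  set.seed(seed)
  z <- stats::rnorm(n)
  x1 <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
  x2 <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
  y <- b1 * x1 + b2 * x2 + stats::rnorm(n, 0, sqrt(resid))
  data.frame(x1 = x1, x2 = x2, y = y)
}

# single common factor with given standardized loadings
gen_factor_data <- function(n, seed, loadings, names = NULL) {
  set.seed(seed)
  eta <- stats::rnorm(n)
  X <- sapply(loadings, function(l)
    l * eta + stats::rnorm(n, 0, sqrt(max(1 - l^2, 1e-8))))
  colnames(X) <- if (is.null(names)) paste0("v", seq_along(loadings))
  else names
  out <- as.data.frame(X)
  attr(out, "eta") <- eta
  out
}

# population covariance of a 1-factor model, marker scaling
triad_cov <- function(lambda = c(1, 0.8, 0.6), psi = 2,
                      theta = c(0.5, 0.4, 0.3),
                      names = c("a", "b", "c")) {
  S <- tcrossprod(lambda) * psi + diag(theta)
  dimnames(S) <- list(names, names)
  S
}

# closed-form triad solution for a 1-factor/3-indicator model with marker
# scaling: psi = s12 s13 / s23, lambda2 = s12 / psi, lambda3 = s13 / psi
triad_solution <- function(S) {
  psi <- S[1, 2] * S[1, 3] / S[2, 3]
  c(lambda2 = S[1, 2] / psi, lambda3 = S[1, 3] / psi,
    theta1 = S[1, 1] - psi,
    theta2 = S[2, 2] - S[1, 2]^2 / psi,
    theta3 = S[3, 3] - S[1, 3]^2 / psi,
    psi = psi)
}

task_cols <- function(battery) c(battery$wm, battery$gf, battery$speed)

# small CALM-like cohort, preprocessed, complete imaging unless stated
calm_cohort <- function(n, seed, imaging_fraction = 1, ...) {
  cfg <- cohort_config("calm", n = n, imaging_fraction = imaging_fraction,
                       seed = seed, ...)
  list(config = cfg,
       data = preprocess_speed(generate_cohort(cfg), cfg$battery)$data)
}
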