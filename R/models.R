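#' Cognitive battery and tract list for a cohort
#'
#' Task batteries for the two developmental cohorts: a referred
#' (clinical) cohort with 4 working-memory tasks, a single fluid-reasoning
#' task and 3 speed tasks, and a community cohort with 3 working-memory,
#' 4 fluid-reasoning and 3 speed tasks. Both use mean fractional
#' anisotropy of the 10 Johns Hopkins atlas tracts, averaged over
#' hemispheres.
#'
#' @param cohort `"calm"` (referred) or `"nki"` (community).
#' @return object of class `cohort_battery` with task lists, tract names,
#'   and reaction-time preprocessing flags per speed task.
#' @export
cohort_battery <- function(cohort = c("calm", "nki")) {
  cohort <- match.arg(cohort)
  tracts <- c("uf", "slf", "ifof", "atr", "cst",
              "fmaj", "fmin", "cg", "ch", "ilf")
  if (cohort == "calm") {
    b <- list(cohort = "calm",
              wm = c("digit_recall", "backward_digit", "dot_matrix", "mr_x"),
              gf = "matrix_reasoning",
              speed = c("trails", "rapid_naming", "rbbs"),
              # all three are response-time tasks: invert (1/x) + log
              speed_rt = c(trails = TRUE, rapid_naming = TRUE, rbbs = TRUE),
              speed_trim = c(trails = FALSE, rapid_naming = FALSE,
                             rbbs = FALSE),
              tracts = tracts)
  } else {
    b <- list(cohort = "nki",
              wm = c("digit_span_fwd", "digit_span_bwd", "n_back"),
              gf = c("matrix_reasoning", "block_design", "similarities",
                     "verbal_reasoning"),
              speed = c("trails", "motor_speed", "sensory_motor"),
              # motor speed is speed-native already; it gets a +/-2 SD trim
              speed_rt = c(trails = TRUE, motor_speed = FALSE,
                           sensory_motor = TRUE),
              speed_trim = c(trails = FALSE, motor_speed = TRUE,
                             sensory_motor = FALSE),
              tracts = tracts)
  }
  stopifnot(length(b$tracts) == 10L,
            !anyDuplicated(c(b$wm, b$gf, b$speed)))
  structure(b, class = "cohort_battery")
}

#' @export
print.cohort_battery <- function(x, ...) {
  cat("cohort battery '", x$cohort, "': ", length(x$wm), " WM + ",
      length(x$gf), " gf + ", length(x$speed), " speed tasks, ",
      length(x$tracts), " tracts\n", sep = "")
  invisible(x)
}

tasks_of <- function(battery) c(battery$wm, battery$gf, battery$speed)

factor_line <- function(name, ind) paste(name, "=~", paste(ind, collapse = " + "))

#' Measurement models of cognition
#'
#' @param battery a `cohort_battery`.
#' @param variant `"single"` (one factor on all tasks), `"twoA"`
#'   (fluid reasoning merged with speed vs working memory), `"twoB"`
#'   (fluid reasoning merged with working memory vs speed), or
#'   `"three"` (separate working-memory, fluid-reasoning and speed
#'   factors). Factors covary freely; marker-variable scaling.
#' @return a `watershed_spec`.
#' @export
build_measurement_model <- function(battery,
                                    variant = c("three", "single",
                                                "twoA", "twoB")) {
  variant <- match.arg(variant)
  syn <- switch(variant,
    single = factor_line("g", tasks_of(battery)),
    twoA = paste(factor_line("gfspeed", c(battery$gf, battery$speed)),
                 factor_line("wm", battery$wm), sep = "\n"),
    twoB = paste(factor_line("gfwm", c(battery$gf, battery$wm)),
                 factor_line("speed", battery$speed), sep = "\n"),
    three = paste(factor_line("wm", battery$wm),
                  factor_line("gf", battery$gf),
                  factor_line("speed", battery$speed), sep = "\n"))
  parse_model(syn)
}

#' Regression form of the cognitive model
#'
#' Fluid reasoning regressed on the working-memory and speed factors with
#' a free covariance between the predictors. The `"free"` variant is
#' covariance-equivalent to the 3-factor measurement model.
#'
#' @param battery a `cohort_battery`.
#' @param constraint `"free"`, `"equal_paths"` (one shared path value),
#'   `"zero_memory"` or `"zero_speed"` (path fixed to 0).
#' @return a `watershed_spec`.
#' @export
build_cognitive_regression <- function(battery,
                                       constraint = c("free", "equal_paths",
                                                      "zero_memory",
                                                      "zero_speed")) {
  constraint <- match.arg(constraint)
  reg <- switch(constraint,
                free = "gf ~ wm + speed",
                equal_paths = "gf ~ b1*wm + b1*speed",
                zero_memory = "gf ~ 0*wm + speed",
                zero_speed = "gf ~ wm + 0*speed")
  syn <- paste(factor_line("wm", battery$wm),
               factor_line("gf", battery$gf),
               factor_line("speed", battery$speed),
               reg, sep = "\n")
  parse_model(syn)
}

#' Single-factor model of white matter microstructure
#'
#' One factor over the 10 tract means (marker scaling); df = 35.
#'
#' @param tracts character vector of 10 tract names.
#' @return a `watershed_spec`.
#' @export
build_wm_single_factor <- function(tracts) {
  stopifnot(length(tracts) == 10L)
  parse_model(factor_line("fa", tracts))
}

#' Watershed path models and alternatives
#'
#' The original watershed regresses the working-memory and speed factors
#' each on all 10 tract means (tract residual inter-covariances all free),
#' fluid reasoning on working memory and speed, with a free residual
#' covariance between working memory and speed. Variants:
#' \describe{
#'   \item{altA}{serial hierarchy: tracts -> speed -> working memory ->
#'     fluid reasoning.}
#'   \item{altB}{no latents: each fluid-reasoning task regressed on all
#'     working-memory and speed tasks, each of those on all tracts, with
#'     free residual covariances within the fluid-reasoning set and within
#'     the working-memory/speed set (an interpretation; see vignette).}
#'   \item{altC}{inverted hierarchy: tracts -> fluid reasoning ->
#'     {working memory, speed} (interpretation).}
#'   \item{altD}{flat: fluid reasoning regressed directly on tracts,
#'     working memory and speed; the two factors are exogenous and covary
#'     with each other and with every tract.}
#'   \item{zero_paths_to_speed / zero_paths_to_memory}{all 10 tract paths
#'     to that endophenotype fixed to zero (Delta-df = 10).}
#'   \item{equal_tract_paths}{tract paths equal across tracts within each
#'     endophenotype (Delta-df = 18).}
#' }
#'
#' @param battery a `cohort_battery`.
#' @param variant model variant, see Details.
#' @return a `watershed_spec`.
#' @export
build_watershed <- function(battery,
                            variant = c("original", "altA", "altB", "altC",
                                        "altD", "zero_paths_to_speed",
                                        "zero_paths_to_memory",
                                        "equal_tract_paths")) {
  variant <- match.arg(variant)
  tr <- battery$tracts
  meas <- paste(factor_line("wm", battery$wm),
                factor_line("gf", battery$gf),
                factor_line("speed", battery$speed), sep = "\n")
  reg_on <- function(out, preds, mod = NULL)
    paste(out, "~", paste(if (is.null(mod)) preds
                          else paste0(mod, "*", preds), collapse = " + "))
  syn <- switch(variant,
    original = paste(meas, reg_on("wm", tr), reg_on("speed", tr),
                     "gf ~ wm + speed", "wm ~~ speed", sep = "\n"),
    zero_paths_to_speed = paste(meas, reg_on("wm", tr),
                                reg_on("speed", tr, "0"),
                                "gf ~ wm + speed", "wm ~~ speed", sep = "\n"),
    zero_paths_to_memory = paste(meas, reg_on("wm", tr, "0"),
                                 reg_on("speed", tr),
                                 "gf ~ wm + speed", "wm ~~ speed",
                                 sep = "\n"),
    equal_tract_paths = paste(meas, reg_on("wm", tr, "bw"),
                              reg_on("speed", tr, "bs"),
                              "gf ~ wm + speed", "wm ~~ speed", sep = "\n"),
    altA = paste(meas, reg_on("speed", tr), "wm ~ speed", "gf ~ wm",
                 sep = "\n"),
    altC = paste(meas, reg_on("gf", tr), "wm ~ gf", "speed ~ gf",
                 "wm ~~ speed", sep = "\n"),
    altD = paste(meas, paste("gf ~ wm + speed +", paste(tr, collapse = " + ")),
                 sep = "\n"),
    altB = {
      inter <- c(battery$wm, battery$speed)
      down <- battery$gf
      lines <- c(vapply(down, function(g) reg_on(g, inter), character(1)),
                 vapply(inter, function(t) reg_on(t, tr), character(1)))
      rescov <- function(v) {
        if (length(v) < 2) return(character(0))
        cmb <- utils::combn(v, 2)
        paste(cmb[1, ], "~~", cmb[2, ])
      }
      paste(c(lines, rescov(inter), rescov(down)), collapse = "\n")
    })
  parse_model(syn)
}

#' Single-path probe for suppression diagnostics
#'
#' Refits the watershed with all tract paths removed except one
#' tract -> endophenotype path, and returns its standardized estimate.
#' Used to check whether a strongly negative path in the full model flips
#' sign when estimated on its own (a suppression signature of modeling
#' several highly correlated paths simultaneously).
#'
#' @param battery a `cohort_battery`.
#' @param tract one of `battery$tracts`.
#' @param endophenotype `"wm"` or `"speed"`.
#' @param data raw data (or NULL), `sample_cov`/`sample_nobs` otherwise.
#' @param sample_cov,sample_nobs covariance-input alternative.
#' @return list with `est`, `std`, `se`, `z`, and the underlying fit.
#' @export
single_path_probe <- function(battery, tract,
                              endophenotype = c("wm", "speed"),
                              data = NULL, sample_cov = NULL,
                              sample_nobs = NULL) {
  endophenotype <- match.arg(endophenotype)
  stopifnot(tract %in% battery$tracts)
  meas <- paste(factor_line("wm", battery$wm),
                factor_line("gf", battery$gf),
                factor_line("speed", battery$speed), sep = "\n")
  syn <- paste(meas, paste(endophenotype, "~", tract),
               "gf ~ wm + speed", "wm ~~ speed", sep = "\n")
  spec <- parse_model(syn)
  fit <- sem_fit(spec, data = data, sample_cov = sample_cov,
                 sample_nobs = sample_nobs, se = "observed")
  if (!fit$converged) stop("single-path probe did not converge")
  pn <- paste0(endophenotype, "~", tract)
  std <- standardized_solution(fit)
  row <- std[std$lhs == endophenotype & std$op == "~" & std$rhs == tract, ]
  list(tract = tract, endophenotype = endophenotype,
       est = unname(fit$theta[pn]),
       std = row$std[1],
       se = if (!is.null(fit$se)) unname(fit$se[pn]) else NA_real_,
       z = if (!is.null(fit$se)) unname(fit$theta[pn] / fit$se[pn])
       else NA_real_,
       fit = fit)
}

#' Run the complete watershed analysis
#'
#' Executes, in fixed order: the measurement-model competition
#' (single/twoA/twoB/three), the cognitive regression comparisons (free
#' vs equal paths, zero-memory, zero-speed), the white-matter
#' single-factor dimensionality test, the watershed model with its
#' constrained and alternative variants compared by Akaike weights, R2
#' for the endophenotypes and fluid reasoning, and single-path probes for
#' any tract path with standardized estimate below `probe_threshold`.
#'
#' @param data raw per-subject data containing all battery task columns
#'   and tract columns (NA = missing).
#' @param battery a `cohort_battery`.
#' @param probe_threshold standardized-estimate threshold that triggers a
#'   sign-flip probe (default -1).
#' @return object of class `watershed_report` (nested list, JSON-ready).
#' @export
run_full_analysis <- function(data, battery, probe_threshold = -1) {
  need <- c(tasks_of(battery), battery$tracts)
  miss <- setdiff(need, colnames(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  fit1 <- function(spec) {
    f <- sem_fit(spec, data = data)
    if (!f$converged) stop("required fit did not converge")
    f
  }
  # 1. measurement models
  mm <- lapply(c(single = "single", twoA = "twoA", twoB = "twoB",
                 three = "three"),
               function(v) fit1(build_measurement_model(battery, v)))
  mm_cmp <- information_criteria(mm)
  three_std <- standardized_solution(fit1(build_measurement_model(battery,
                                                                  "three")))
  lat_cov <- three_std[three_std$op == "~~" &
                         three_std$lhs %in% c("wm", "gf", "speed") &
                         three_std$rhs %in% c("wm", "gf", "speed") &
                         three_std$lhs != three_std$rhs, ]
  # 2. cognitive regression comparisons
  cg <- lapply(c(free = "free", equal_paths = "equal_paths",
                 zero_memory = "zero_memory", zero_speed = "zero_speed"),
               function(v) fit1(build_cognitive_regression(battery, v)))
  cg_tests <- lapply(cg[c("equal_paths", "zero_memory", "zero_speed")],
                     lrt_nested, full = cg$free)
  cg_std <- standardized_solution(cg$free)
  reg_paths <- cg_std[cg_std$op == "~" & cg_std$lhs == "gf", ]
  # 3. white-matter dimensionality
  wmf <- fit1(build_wm_single_factor(battery$tracts))
  wmf_ix <- fit_indices(wmf)
  # 4. watershed + constraints + alternatives
  ws <- fit1(build_watershed(battery, "original"))
  ws_ix <- fit_indices(ws)
  ws_tests <- lapply(c(zero_paths_to_speed = "zero_paths_to_speed",
                       zero_paths_to_memory = "zero_paths_to_memory",
                       equal_tract_paths = "equal_tract_paths"),
                     function(v) lrt_nested(
                       fit1(build_watershed(battery, v)), full = ws))
  alts <- lapply(c(altA = "altA", altB = "altB", altC = "altC",
                   altD = "altD"),
                 function(v) fit1(build_watershed(battery, v)))
  alt_cmp <- information_criteria(c(list(original = ws), alts))
  r2 <- r_squared(ws, c("wm", "speed", "gf"))
  ws_std <- standardized_solution(ws)
  tract_paths <- ws_std[ws_std$op == "~" & ws_std$lhs %in% c("wm", "speed") &
                          ws_std$rhs %in% battery$tracts, ]
  # 5. sign-flip probes
  flips <- tract_paths[tract_paths$std < probe_threshold, ]
  probes <- if (nrow(flips)) lapply(seq_len(nrow(flips)), function(i)
    single_path_probe(battery, flips$rhs[i], flips$lhs[i], data = data)[
      c("tract", "endophenotype", "est", "std", "se", "z")])
  else list()

  structure(list(
    cohort = battery$cohort, n = nrow(data),
    measurement = list(comparison = mm_cmp$table,
                       latent_correlations = lat_cov[, c("lhs", "rhs", "std")]),
    cognitive = list(
      regression_paths = reg_paths[, c("lhs", "rhs", "est", "std")],
      tests = cg_tests),
    white_matter = list(indices = unclass(wmf_ix)[c("chisq", "df", "rmsea",
                                                    "cfi", "srmr")],
                        classification = classify_fit(wmf_ix)),
    watershed = list(
      indices = unclass(ws_ix)[c("chisq", "df", "rmsea", "cfi", "srmr")],
      classification = classify_fit(ws_ix),
      r2 = as.list(r2),
      tract_paths = tract_paths[, c("lhs", "rhs", "est", "std")],
      constrained_tests = ws_tests,
      alternatives = alt_cmp$table,
      probes = probes)), class = "watershed_report")
}

#' @export
print.watershed_report <- function(x, ...) {
  cat("watershed analysis report, cohort '", x$cohort, "' (n = ", x$n,
      ")\n\nmeasurement model comparison:\n", sep = "")
  print(format(x$measurement$comparison, digits = 3), row.names = FALSE)
  cat("\nwatershed R2:",
      paste(sprintf("%s = %.1f%%", names(x$watershed$r2),
                    100 * unlist(x$watershed$r2)), collapse = ", "), "\n")
  cat("watershed vs alternatives (Akaike weights):\n")
  print(format(x$watershed$alternatives, digits = 3), row.names = FALSE)
  invisible(x)
}
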