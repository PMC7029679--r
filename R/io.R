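#' Load a rectangular per-subject data table
#'
#' CSV dialect: comma-separated, `.` decimal, UTF-8, mandatory header,
#' empty cell = missing. Non-numeric cells and duplicate headers are
#' errors; the missingness per column is attached as an attribute.
#'
#' @param path CSV file path.
#' @return data frame of doubles with attribute `missing_log`
#'   (per-column missing counts) and `n_rows`.
#' @export
load_table <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (anyDuplicated(colnames(raw)))
    stop("duplicate headers: ",
         paste(unique(colnames(raw)[duplicated(colnames(raw))]),
               collapse = ", "))
  out <- raw
  for (j in seq_along(raw)) {
    x <- trimws(raw[[j]])
    x[x == ""] <- NA
    conv <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(conv))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1L], colnames(raw)[j], x[bad[1L]]))
    out[[j]] <- conv
  }
  attr(out, "missing_log") <- vapply(out, function(c) sum(is.na(c)),
                                     integer(1))
  attr(out, "n_rows") <- nrow(out)
  out
}

#' Load a covariance (or correlation) matrix from CSV
#'
#' @param path square numeric CSV, header row = variable names.
#' @param n sample size to attach.
#' @return list with `S` (symmetrized matrix), `n`, and `standardized`
#'   flag (`TRUE` when the diagonal is all ones, i.e. a correlation
#'   matrix was supplied).
#' @export
load_covariance <- function(path, n) {
  tab <- utils::read.csv(path, check.names = FALSE)
  S <- as.matrix(tab)
  if (nrow(S) != ncol(S))
    stop("covariance input is not square: ", nrow(S), " x ", ncol(S))
  rownames(S) <- colnames(S)
  storage.mode(S) <- "double"
  asym <- max(abs(S - t(S)))
  if (asym > 1e-8) stop("covariance asymmetric beyond tolerance (max |S - t(S)| = ",
                        signif(asym, 3), ")")
  if (asym > 1e-12) warning("covariance symmetrized (asymmetry ",
                            signif(asym, 3), ")")
  S <- (S + t(S)) / 2
  list(S = S, n = as.integer(n),
       standardized = all(abs(diag(S) - 1) < 1e-12))
}

model_from_name <- function(name, battery) {
  meas <- c("single", "twoA", "twoB", "three")
  regs <- c("free", "equal_paths", "zero_memory", "zero_speed")
  wsv <- c("original", "altA", "altB", "altC", "altD",
           "zero_paths_to_speed", "zero_paths_to_memory",
           "equal_tract_paths")
  if (name %in% meas) build_measurement_model(battery, name)
  else if (name %in% regs) build_cognitive_regression(battery, name)
  else if (name == "wm_single") build_wm_single_factor(battery$tracts)
  else if (name %in% wsv) build_watershed(battery, name)
  else stop("unknown model name '", name, "'")
}

config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(paste(s, collapse = ""))
  h <- 0
  for (c in v) h <- (h * 31 + c) %% 2147483647
  sprintf("%08x", h)
}

write_manifest <- function(dir, cmd, opts, seed) {
  jsonlite::write_json(
    list(command = cmd, options = opts, seed = seed,
         config_hash = config_hash(opts),
         package_version = as.character(utils::packageVersion("watershed")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

parse_argv <- function(argv) {
  opts <- list(); i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (!startsWith(a, "--")) stop("expected --option, got '", a, "'")
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[[i + 1L]], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else { opts[[key]] <- argv[[i + 1L]]; i <- i + 2L }
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `fit`, `compare`, `tree`, `report`. Every run
#' writes its artifacts plus a `manifest.json` (options, seed, config
#' hash, versions) under `--out`'s directory. Returns the exit code
#' (0 success) rather than quitting, so it is testable in-process; the
#' installed `watershed` script wraps it in `quit(status = ...)`.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (!length(argv)) stop("usage: watershed <simulate|fit|compare|tree|report> [--options]")
    cmd <- argv[[1L]]
    opts <- parse_argv(argv[-1L])
    seed <- as.integer(opts$seed %||% 1L)
    battery <- cohort_battery(opts$battery %||% "calm")
    prep <- function(dat) preprocess_speed(dat, battery)$data
    switch(cmd,
      simulate = {
        cfgopts <- if (!is.null(opts$config)) jsonlite::fromJSON(opts$config)
        else list()
        cfg <- cohort_config(
          cohort = cfgopts$cohort %||% (opts$battery %||% "calm"),
          n = cfgopts$n, imaging_fraction = cfgopts$imaging_fraction,
          truth = cfgopts$truth %||% "original", seed = seed)
        dat <- generate_cohort(cfg)
        out <- opts$out %||% "cohort.csv"
        utils::write.csv(dat, out, row.names = FALSE, na = "")
        write_manifest(dirname(out), "simulate", opts, seed)
        message("wrote ", out, " (", nrow(dat), " subjects)")
      },
      fit = {
        dat <- prep(load_table(opts$data))
        spec <- if (!is.null(opts$syntax))
          parse_model(paste(readLines(opts$syntax), collapse = "\n"))
        else model_from_name(opts$model %||% "original", battery)
        f <- sem_fit(spec, data = dat, se = "observed")
        if (!f$converged) stop("fit did not converge (model ",
                               opts$model %||% "custom", ")")
        ix <- fit_indices(f)
        out <- opts$out %||% "fit.json"
        jsonlite::write_json(list(
          model = opts$model %||% "custom",
          indices = unclass(ix)[c("chisq", "df", "p_value", "rmsea",
                                  "rmsea_ci_lower", "rmsea_ci_upper",
                                  "cfi", "srmr", "aic", "bic")],
          classification = classify_fit(ix),
          estimates = standardized_solution(f),
          r2 = as.list(r_squared(f))), out, auto_unbox = TRUE,
          digits = NA, pretty = TRUE)
        write_manifest(dirname(out), "fit", opts, seed)
      },
      compare = {
        dat <- prep(load_table(opts$data))
        nms <- strsplit(opts$models, ",", fixed = TRUE)[[1L]]
        if (!length(nms)) stop("empty model list")
        fits <- lapply(nms, function(nm)
          sem_fit(model_from_name(nm, battery), data = dat))
        names(fits) <- nms
        cmp <- information_criteria(fits)
        out <- opts$out %||% "comparison.json"
        jsonlite::write_json(cmp$table, out, digits = NA, pretty = TRUE)
        write_manifest(dirname(out), "compare", opts, seed)
      },
      tree = {
        dat <- prep(load_table(opts$data))
        spec <- model_from_name(opts$model %||% "original", battery)
        cfg <- tree_config(opts$focus,
                           covariate = opts$covariate %||% "age",
                           min_group_n = as.integer(opts[["min-n"]] %||% 50L),
                           max_groups = as.integer(opts[["max-groups"]] %||% 4L),
                           folds = as.integer(opts$folds %||% 10L),
                           seed = seed)
        tree <- grow_tree(spec, dat, cfg)
        out <- opts$out %||% "tree.json"
        jsonlite::write_json(list(focus = tree$focus, splits = tree$splits,
                                  leaves = tree$leaves), out,
                             digits = NA, pretty = TRUE)
        writeLines(tree_markdown(stats::setNames(list(tree), tree$focus)),
                   sub("\\.json$", ".md", out))
        write_manifest(dirname(out), "tree", opts, seed)
      },
      report = {
        dat <- prep(load_table(opts$data))
        rep <- run_full_analysis(dat, battery)
        out_dir <- opts$out %||% "."
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(unclass(rep),
                             file.path(out_dir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             force = TRUE)
        writeLines(report_markdown(rep), file.path(out_dir, "report.md"))
        write_manifest(out_dir, "report", opts, seed)
      },
      stop("unknown subcommand '", cmd, "'"))
    0L
  }, error = function(e) {
    message("watershed error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

report_markdown <- function(rep) {
  tab <- rep$measurement$comparison
  fmt_row <- function(v) paste0("| ", paste(v, collapse = " | "), " |")
  lines <- c(sprintf("# Watershed analysis report (%s, n = %d)",
                     rep$cohort, rep$n),
             "", "## Measurement model comparison", "",
             fmt_row(c("Model", "chisq(df)", "AIC", "BIC", "AIC weight")),
             fmt_row(rep("---", 5)))
  for (i in seq_len(nrow(tab)))
    lines <- c(lines, fmt_row(c(
      tab$model[i],
      sprintf("%.2f (%d)", tab$chisq[i], tab$df[i]),
      sprintf("%.2f", tab$aic[i]), sprintf("%.2f", tab$bic[i]),
      sprintf("%.2f%%", 100 * tab$weight[i]))))
  ws <- rep$watershed
  lines <- c(lines, "", "## Watershed model", "",
             sprintf("- R2: %s",
                     paste(sprintf("%s = %.1f%%", names(ws$r2),
                                   100 * unlist(ws$r2)), collapse = ", ")),
             sprintf("- fit: chisq(%d) = %.2f, RMSEA = %.3f, CFI = %.3f, SRMR = %.3f (%s)",
                     ws$indices$df, ws$indices$chisq, ws$indices$rmsea,
                     ws$indices$cfi, ws$indices$srmr,
                     ws$classification$overall),
             "", "## Alternatives (Akaike weights)", "",
             fmt_row(c("Model", "AIC", "weight")), fmt_row(rep("---", 3)))
  at <- ws$alternatives
  for (i in seq_len(nrow(at)))
    lines <- c(lines, fmt_row(c(at$model[i], sprintf("%.2f", at$aic[i]),
                                sprintf("%.2f%%", 100 * at$weight[i]))))
  lines
}
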