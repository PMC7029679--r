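# covariance parameter names are stored with alphabetically ordered sides
canon_param <- function(pn) {
  if (grepl("~~", pn, fixed = TRUE)) {
    v <- sort(strsplit(pn, "~~", fixed = TRUE)[[1L]])
    paste0(v[1L], "~~", v[2L])
  } else pn
}

#' Candidate covariate thresholds for a SEM-tree split
#'
#' Midpoints between consecutive distinct sorted covariate values,
#' restricted so both resulting groups hold at least `min_group_n`
#' subjects.
#'
#' @param age numeric covariate values.
#' @param min_group_n minimum group size (default 50).
#' @return ordered numeric vector of thresholds (possibly empty).
#' @export
candidate_splits <- function(age, min_group_n = 50L) {
  age <- age[!is.na(age)]
  n <- length(age)
  if (n < 2L * min_group_n) return(numeric(0))
  s <- sort(age)
  i <- seq_len(n - 1L)
  ok <- s[i] != s[i + 1L] & i >= min_group_n & (n - i) >= min_group_n
  unique((s[which(ok)] + s[which(ok) + 1L]) / 2)
}

thin_candidates <- function(cand, max_candidates) {
  if (length(cand) <= max_candidates) return(cand)
  cand[unique(round(seq(1, length(cand), length.out = max_candidates)))]
}

#' SEM-tree configuration
#'
#' Defaults follow the published analysis settings: minimum group size 50,
#' 10-fold cross-validation, at most 4 age groups. `max_candidates` caps
#' how many quantile-spaced thresholds from [candidate_splits()] are
#' CV-scored per node; `alpha` is the significance level of the
#' Bonferroni-corrected split confirmation test.
#'
#' @param focus single focus parameter name (e.g. `"gf~wm"`,
#'   `"wm~~speed"`); the only parameter allowed to differ across groups.
#' @param covariate covariate column name (default `"age"`).
#' @param min_group_n minimum subjects per group (default 50).
#' @param max_groups maximum number of leaves (default 4).
#' @param folds cross-validation folds (default 10).
#' @param max_candidates cap on CV-scored thresholds per node (default 30).
#' @param alpha significance level of the confirmation test (default 0.05).
#' @param seed integer seed governing fold assignment.
#' @return a configuration list for [grow_tree()] / [evaluate_split()].
#' @export
tree_config <- function(focus, covariate = "age", min_group_n = 50L,
                        max_groups = 4L, folds = 10L, max_candidates = 30L,
                        alpha = 0.05, seed = 1L) {
  stopifnot(length(focus) == 1L, min_group_n >= 1L, folds >= 2L,
            max_groups >= 1L, alpha > 0, alpha <= 1)
  list(focus = focus, covariate = covariate,
       min_group_n = as.integer(min_group_n),
       max_groups = as.integer(max_groups), folds = as.integer(folds),
       max_candidates = as.integer(max_candidates), alpha = alpha,
       seed = as.integer(seed))
}

# node-level confirmation: 2-group (focus free) vs invariant likelihood-ratio
# test at the selected threshold, on the full node data
split_lrt <- function(ram, X, age, threshold, focus) {
  side <- factor(ifelse(age <= threshold, "L", "R"), levels = c("L", "R"))
  gs <- group_stats(X, side)
  if (length(gs) < 2L) return(1)
  f1 <- tryCatch(fit_multigroup(ram, gs, focus = character()),
                 error = function(e) NULL)
  f2 <- tryCatch(fit_multigroup(ram, gs, focus = focus),
                 error = function(e) NULL)
  if (is.null(f1) || is.null(f2) || !f1$converged || !f2$converged) return(1)
  stats::pchisq(max(0, 2 * (f2$loglik - f1$loglik)), df = 1,
                lower.tail = FALSE)
}

#' Cross-validated score of a candidate SEM-tree split
#'
#' Fits, on each training fold, a 2-group model in which only the focus
#' parameter differs between the two sides of the threshold (all other
#' parameters equality-constrained; group means saturated in both
#' models), and an invariant model with the focus shared as well. The
#' score is the summed held-out log-likelihood gain of the 2-group model.
#' Fold assignment is seeded and stratified by split side. A split whose
#' subgroup fits fail is disqualified with score `-Inf`.
#'
#' @param spec model (`watershed_spec`, ram, or syntax).
#' @param data raw data with complete manifest rows plus the covariate.
#' @param threshold covariate cut (from [candidate_splits()]).
#' @param config list from `tree_config()`: `focus`, `covariate`,
#'   `folds`, `seed`.
#' @return list with `score`, per-fold gains, and `ok` flag.
#' @export
evaluate_split <- function(spec, data, threshold, config) {
  ram <- if (inherits(spec, "watershed_ram")) spec else
    build_ram(if (is.character(spec)) parse_model(spec) else spec)
  age <- data[[config$covariate]]
  X <- as.matrix(as.data.frame(data)[, ram$manifests, drop = FALSE])
  keep <- stats::complete.cases(X) & !is.na(age)
  X <- X[keep, , drop = FALSE]; age <- age[keep]
  eval_split_core(ram, X, age, threshold, config, warm = NULL)
}

eval_split_core <- function(ram, X, age, threshold, config, warm = NULL,
                            rng_offset = 0L, verbose = FALSE,
                            use_folds = NULL) {
  say <- if (verbose) function(...) cat(..., "\n") else function(...) NULL
  k <- config$folds
  side <- factor(ifelse(age <= threshold, "L", "R"), levels = c("L", "R"))
  nL <- sum(side == "L"); nR <- sum(side == "R")
  if (nL < 2 || nR < 2) return(list(score = -Inf, folds = numeric(0),
                                    ok = FALSE))
  # seeded fold assignment, stratified by side
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(config$seed + rng_offset)
  # ranks within side, not row positions: fold membership is then invariant
  # to permuting subject rows
  fold <- integer(length(age))
  idxL <- which(side == "L"); idxL <- idxL[order(age[idxL])]
  idxR <- which(side == "R"); idxR <- idxR[order(age[idxR])]
  fold[idxL] <- sample(rep_len(seq_len(k), nL))
  fold[idxR] <- sample(rep_len(seq_len(k), nR))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  gains <- rep(NA_real_, k)
  warm1 <- warm
  say("split", threshold, "nL", nL, "nR", nR, "k", k)
  for (f in (if (is.null(use_folds)) seq_len(k) else use_folds)) {
    say("fold", f, "begins")
    tr <- fold != f; te <- !tr
    if (!any(te)) { say("fold", f, "empty test set"); next }
    gs <- group_stats(X[tr, , drop = FALSE], side[tr])
    if (length(gs) < 2L || any(vapply(gs, `[[`, numeric(1), "n") <=
                                 ram$p)) {
      say("fold", f, "group too small:", length(gs),
          vapply(gs, `[[`, numeric(1), "n"))
      next
    }
    # scoring fits use a looser (still tight) convergence than final fits
    ctl_score <- list(grad_tol = 1e-3, rel_tol = 1e-7, iter_max = 200L)
    f1 <- tryCatch(fit_multigroup(ram, gs, focus = character(),
                                  start = warm1, control = ctl_score),
                   error = function(e) { say("f1 error:",
                                             conditionMessage(e)); NULL })
    if (is.null(f1) || !f1$converged) {
      say("fold", f, "invariant fit failed; gmax:",
          if (!is.null(f1)) f1$gmax else NA)
      return(list(score = -Inf, folds = gains, ok = FALSE))
    }
    warm1 <- f1$theta
    st2 <- c(f1$theta, stats::setNames(
      rep(f1$theta[config$focus], 2),
      paste0(config$focus, "@", 1:2)))
    st2 <- st2[setdiff(names(st2), config$focus)]
    f2 <- tryCatch(fit_multigroup(ram, gs, focus = config$focus,
                                  start = st2, control = ctl_score),
                   error = function(e) { say("f2 error:",
                                             conditionMessage(e)); NULL })
    if (is.null(f2) || !f2$converged) {
      say("fold", f, "focus-free fit failed; gmax:",
          if (!is.null(f2)) f2$gmax else NA)
      return(list(score = -Inf, folds = gains, ok = FALSE))
    }
    ll1 <- ll2 <- 0
    for (g in seq_along(gs)) {
      rows_te <- which(te & side == names(gs)[g])
      if (!length(rows_te)) next
      Xte <- X[rows_te, , drop = FALSE]
      ll1 <- ll1 + mvn_loglik_rows(Xte, gs[[g]]$mu, f1$Sigma_g[[g]])
      ll2 <- ll2 + mvn_loglik_rows(Xte, gs[[g]]$mu, f2$Sigma_g[[g]])
    }
    say("fold", f, "ll1", ll1, "ll2", ll2)
    gains[f] <- ll2 - ll1
  }
  if (all(is.na(gains))) return(list(score = -Inf, folds = gains,
                                     ok = FALSE))
  list(score = sum(gains, na.rm = TRUE), folds = gains, ok = TRUE)
}

#' Grow a SEM tree over an age covariate
#'
#' Greedy recursive partitioning: at each node the best positive
#' cross-validated split (ties broken toward the younger threshold) is
#' accepted and both children are visited (younger first), until
#' `max_groups` leaves, the minimum group size, or no positive score.
#' Only the single focus parameter may differ across groups; everything
#' else is equality-constrained. Leaf estimates come from one joint
#' multi-group fit over the final partition.
#'
#' @param spec model (`watershed_spec`, ram, or syntax string).
#' @param data raw data: complete manifest rows plus the covariate column.
#' @param config from `tree_config()`; defaults follow the published
#'   settings (min_group_n = 50, folds = 10, max_groups = 4).
#' @return object of class `sem_tree`.
#' @export
grow_tree <- function(spec, data, config) {
  ram <- if (inherits(spec, "watershed_ram")) spec else
    build_ram(if (is.character(spec)) parse_model(spec) else spec)
  config$focus <- canon_param(config$focus)
  stopifnot(config$focus %in% ram$par_names)
  age <- data[[config$covariate]]
  if (is.null(age)) stop("covariate column '", config$covariate,
                         "' not found")
  X <- as.matrix(as.data.frame(data)[, ram$manifests, drop = FALSE])
  keep <- stats::complete.cases(X) & !is.na(age)
  X <- X[keep, , drop = FALSE]; age <- age[keep]
  N <- nrow(X)
  if (N < 2L * config$min_group_n && config$max_groups > 1L)
    config$max_groups <- 1L

  # root fit (single group) must succeed
  mu0 <- colMeans(X)
  S0 <- crossprod(sweep(X, 2L, mu0)) / N
  root <- tryCatch(fit_multigroup(ram, list(list(S = S0, n = N)),
                                  focus = character()),
                   error = function(e) NULL)
  if (is.null(root) || !root$converged) stop("root model fit failed")

  env <- new.env(parent = emptyenv())
  env$leaves <- 1L
  env$node_id <- 0L
  env$splits <- numeric(0)

  recurse <- function(idx, depth) {
    env$node_id <- env$node_id + 1L
    node <- list(id = env$node_id, n = length(idx),
                 age_range = range(age[idx]), split = NA_real_,
                 score = NA_real_, children = NULL)
    if (env$leaves >= config$max_groups) return(node)
    cand <- thin_candidates(candidate_splits(age[idx], config$min_group_n),
                            config$max_candidates)
    if (!length(cand)) return(node)
    Xn <- X[idx, , drop = FALSE]; an <- age[idx]
    k <- config$folds
    # successive halving: screen every candidate on the first folds, finish
    # the full k-fold score only for the strongest few (fold assignment is
    # deterministic, so partial and final evaluations use the same folds)
    if (k > 4L) {
      screen <- vapply(cand, function(tcut)
        eval_split_core(ram, Xn, an, tcut, config, warm = root$theta,
                        rng_offset = node$id,
                        use_folds = 1:3)$score, numeric(1))
      top <- order(screen, decreasing = TRUE)
      top <- top[is.finite(screen[top])]
      top <- utils::head(top, max(4L, ceiling(length(cand) / 5)))
      finish <- vapply(top, function(j) {
        ev <- eval_split_core(ram, Xn, an, cand[j], config,
                              warm = root$theta, rng_offset = node$id,
                              use_folds = 4:k)
        if (!is.finite(ev$score)) -Inf else screen[j] + ev$score
      }, numeric(1))
      scores <- rep(-Inf, length(cand)); scores[top] <- finish
    } else {
      scores <- vapply(cand, function(tcut)
        eval_split_core(ram, Xn, an, tcut, config, warm = root$theta,
                        rng_offset = node$id)$score, numeric(1))
    }
    best <- NULL
    ok <- is.finite(scores) & scores > 0
    if (any(ok)) {           # ascending order: ties keep younger threshold
      j <- which(ok)[which.max(scores[ok])]
      best <- list(threshold = cand[j], score = scores[j])
    }
    if (is.null(best)) return(node)
    # multiplicity-corrected confirmation of the selected split
    pv <- split_lrt(ram, X[idx, , drop = FALSE], age[idx], best$threshold,
                    config$focus)
    if (pv >= config$alpha / length(cand)) return(node)
    env$leaves <- env$leaves + 1L
    env$splits <- c(env$splits, best$threshold)
    node$split <- best$threshold
    node$score <- best$score
    left <- idx[age[idx] <= best$threshold]
    right <- idx[age[idx] > best$threshold]
    node$children <- list(recurse(left, depth + 1L),
                          recurse(right, depth + 1L))
    node
  }
  tree <- recurse(seq_len(N), 0L)

  # leaf partition in age order
  cuts <- sort(env$splits)
  leaf_of <- findInterval(age, c(-Inf, cuts, Inf), left.open = FALSE)
  leaf_of <- cut(age, breaks = c(-Inf, cuts, Inf), labels = FALSE)
  gs <- group_stats(X, factor(leaf_of, levels = sort(unique(leaf_of))))
  final <- if (length(gs) > 1L)
    fit_multigroup(ram, gs, focus = config$focus, start = NULL)
  else root
  est <- if (length(gs) > 1L)
    final$theta[paste0(config$focus, "@", seq_along(gs))]
  else root$theta[config$focus]
  leaves <- data.frame(
    leaf = seq_along(gs),
    age_lo = c(-Inf, cuts), age_hi = c(cuts, Inf),
    n = vapply(gs, `[[`, numeric(1), "n"),
    estimate = unname(est))

  structure(list(root = tree, splits = cuts, leaves = leaves,
                 focus = config$focus, config = config,
                 n = N, fit = final,
                 theta_root = root$theta), class = "sem_tree")
}

#' @export
print.sem_tree <- function(x, ...) {
  cat("SEM tree on focus '", x$focus, "': ", nrow(x$leaves),
      " leaf group(s)", sep = "")
  if (length(x$splits)) {
    cat("\n  ")
    est <- sprintf("%.2f", x$leaves$estimate)
    sp <- sprintf("| %.2f |", x$splits)
    cat(paste(c(rbind(est, c(sp, ""))), collapse = " "), "\n")
  } else cat(" (no split)\n  estimate:",
             sprintf("%.3f", x$leaves$estimate[1]), "\n")
  invisible(x)
}

#' Markdown table of SEM-tree results (split ages and segment estimates)
#' @param trees named list of `sem_tree` objects (one per focus parameter).
#' @return character vector of markdown lines.
#' @export
tree_markdown <- function(trees) {
  if (inherits(trees, "sem_tree")) trees <- list(trees)
  kmax <- max(vapply(trees, function(t) length(t$splits), numeric(1)))
  hdr <- c("Path", "Estimate Before")
  for (i in seq_len(kmax)) hdr <- c(hdr, sprintf("Age Split %d", i),
                                    "Estimate Between")
  lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"),
                    "|"))
  for (nm in names(trees)) {
    t <- trees[[nm]]
    cells <- sprintf("%.2f", t$leaves$estimate[1])
    for (i in seq_len(kmax)) {
      if (i <= length(t$splits))
        cells <- c(cells, sprintf("**%.2f**", t$splits[i]),
                   sprintf("%.2f", t$leaves$estimate[i + 1]))
      else cells <- c(cells, "—", "—")
    }
    lines <- c(lines, paste0("| ", paste(c(nm, cells), collapse = " | "),
                             " |"))
  }
  lines
}
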