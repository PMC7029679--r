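#' Normal-theory maximum-likelihood discrepancy
#'
#' \eqn{F_{ML} = \ln|\Sigma| - \ln|S| + tr(S\Sigma^{-1}) - p}; zero iff
#' \eqn{\Sigma = S}.
#'
#' @param S sample covariance (p x p, positive definite).
#' @param Sigma implied covariance (p x p, positive definite).
#' @return nonnegative scalar discrepancy.
#' @export
ml_discrepancy <- function(S, Sigma) {
  stopifnot(is.matrix(S), is.matrix(Sigma), all(dim(S) == dim(Sigma)))
  p <- nrow(S)
  for (nm in c("S", "Sigma")) {
    M <- if (nm == "S") S else Sigma
    ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      stop(nm, " is not positive definite (smallest eigenvalue ",
           signif(ev, 4), ")")
  }
  cS <- chol(S); cSig <- chol(Sigma)
  ld_S <- 2 * sum(log(diag(cS))); ld_Sig <- 2 * sum(log(diag(cSig)))
  max(0, ld_Sig - ld_S + sum(chol2inv(cSig) * S) - p)
}

# ---- starting values -------------------------------------------------------

start_values <- function(ram, S_obs) {
  # S_obs: observed covariance over manifests (named)
  theta <- numeric(ram$npar)
  vobs <- diag(S_obs)[ram$manifests]
  marker_of <- vapply(ram$latents, function(lt) {
    j <- match(lt, ram$vars)
    hit <- which(ram$A0[, j] == 1 & seq_len(ram$nv) <= ram$p)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  endo <- unique(c(ram$A_cells[, 1],
                   which(rowSums(ram$A0 != 0) > 0)))  # receives a path
  seen <- rep(FALSE, ram$npar)
  set1 <- function(k, val) if (!seen[k]) { theta[k] <<- val; seen[k] <<- TRUE }
  if (nrow(ram$A_cells))
    for (r in seq_len(nrow(ram$A_cells))) set1(ram$A_par[r], 0.5)
  if (nrow(ram$S_cells)) for (r in seq_len(nrow(ram$S_cells))) {
    i <- ram$S_cells[r, 1]; j <- ram$S_cells[r, 2]
    if (i == j) {
      if (i <= ram$p) set1(ram$S_par[r], 0.5 * vobs[i])
      else {
        mk <- marker_of[ram$vars[i]]
        set1(ram$S_par[r], if (!is.na(mk)) 0.5 * vobs[mk] else 0.5)
      }
    } else if (i <= ram$p && j <= ram$p && !i %in% endo && !j %in% endo)
      set1(ram$S_par[r], S_obs[i, j])   # exogenous manifest covariance
    else set1(ram$S_par[r], 0)
  }
  names(theta) <- ram$par_names
  theta
}

# ---- covariance-input objective -------------------------------------------

# returns list(fn, gr) for minimizing F_ML(theta); analytic RAM gradient
# (compiled kernel)
make_cov_objective <- function(ram, S) {
  p <- ram$p
  ld_S <- 2 * sum(log(diag(chol(S))))
  ci <- ram_cidx(ram)
  npar <- ram$npar
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  compute <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$res)
    r <- ram_group_obj(theta, ram$A0, ram$S0, ci$Acells, ci$Apar,
                       ci$Scells, ci$Spar, p, S, 1.0, npar, TRUE)
    res <- if (isTRUE(r$ok))
      list(val = r$val - ld_S - p, grad = as.vector(r$grad))
    else {
      d <- theta - cache$start
      list(val = 1e10 * (1 + sum(d * d)), grad = 2e10 * d)
    }
    cache$theta <- theta; cache$res <- res
    res
  }
  list(fn = function(th) compute(th)$val,
       gr = function(th) compute(th)$grad,
       cache = cache)
}

# ---- FIML (raw data) -------------------------------------------------------

build_patterns <- function(X) {
  obs <- !is.na(X)
  key <- apply(obs, 1L, function(z) paste(as.integer(z), collapse = ""))
  pats <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    o <- which(obs[rows[1L], ])
    if (!length(o)) next
    Xo <- X[rows, o, drop = FALSE]
    n <- nrow(Xo)
    xb <- colMeans(Xo)
    Xc <- sweep(Xo, 2L, xb)
    pats[[length(pats) + 1L]] <- list(o = o, n = n, xbar = xb,
                                      S = crossprod(Xc) / n)
  }
  pats
}

# objective = -loglik/N for theta = c(structural, means); analytic gradient
# (compiled kernel; patterns carry zero-based observed indices)
make_fiml_objective <- function(ram, pats, N) {
  p <- ram$p; npar <- ram$npar
  ci <- ram_cidx(ram)
  pats0 <- lapply(pats, function(pt) {
    pt$o <- as.integer(pt$o - 1L); pt
  })
  cache <- new.env(parent = emptyenv()); cache$theta <- NULL
  compute <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$res)
    r <- ram_fiml_obj(theta[seq_len(npar)], theta[npar + seq_len(p)],
                      ram$A0, ram$S0, ci$Acells, ci$Apar, ci$Scells,
                      ci$Spar, p, pats0, 1 / N, npar, TRUE)
    res <- if (isTRUE(r$ok)) list(val = r$val, grad = as.vector(r$grad))
    else {
      d <- theta - cache$start
      list(val = 1e10 * (1 + sum(d * d)), grad = 2e10 * d)
    }
    cache$theta <- theta; cache$res <- res
    res
  }
  list(fn = function(th) compute(th)$val,
       gr = function(th) compute(th)$grad,
       cache = cache)
}

#' Casewise (FIML) log-likelihood of raw data under a RAM model
#'
#' Sums, over missingness patterns, the multivariate-normal log-density of
#' each row's observed sub-vector under the corresponding sub-matrix of the
#' implied covariance. Rows with no observed variable are excluded (their
#' count is attached as attribute `n_dropped`).
#'
#' @param data data frame or matrix containing the model's manifest columns;
#'   `NA` marks missing entries.
#' @param ram a `watershed_ram` (or spec).
#' @param theta free-parameter vector.
#' @param mu mean vector used for the density; defaults to the observed
#'   column means (saturated means).
#' @return scalar log-likelihood with attribute `n_dropped`.
#' @export
fiml_loglik <- function(data, ram, theta, mu = NULL) {
  if (inherits(ram, "watershed_spec")) ram <- build_ram(ram)
  X <- as.matrix(as.data.frame(data)[, ram$manifests, drop = FALSE])
  drop <- rowSums(!is.na(X)) == 0
  if (any(drop)) X <- X[!drop, , drop = FALSE]
  if (is.null(mu)) mu <- colMeans(X, na.rm = TRUE)
  pats <- build_patterns(X)
  Sig <- implied_covariance(ram, theta)
  ll <- 0
  for (pt in pats) {
    o <- pt$o
    co <- chol(Sig[o, o, drop = FALSE])
    Soi <- chol2inv(co)
    d <- pt$xbar - mu[o]
    C <- pt$S + tcrossprod(d)
    ll <- ll - pt$n / 2 *
      (length(o) * log(2 * pi) + 2 * sum(log(diag(co))) + sum(Soi * C))
  }
  attr(ll, "n_dropped") <- sum(drop)
  ll
}

# EM for the saturated multivariate normal with missing data
em_saturated <- function(X, max_iter = 1000L, tol = 1e-10) {
  p <- ncol(X)
  obs <- !is.na(X)
  if (all(obs)) {
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2L, mu)) / nrow(X)
    ll <- -nrow(X) / 2 * (p * log(2 * pi) +
                            as.numeric(determinant(S)$modulus) + p)
    return(list(mu = mu, Sigma = S, loglik = ll, iter = 0L))
  }
  n <- nrow(X)
  mu <- colMeans(X, na.rm = TRUE)
  S <- stats::cov(X, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  diag(S) <- pmax(diag(S), 1e-6)
  ev <- eigen(S, symmetric = TRUE)
  S <- ev$vectors %*% (pmax(ev$values, 1e-6) * t(ev$vectors))
  key <- apply(obs, 1L, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(n), key)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p); T2 <- matrix(0, p, p); ll <- 0
    for (rows in groups) {
      o <- which(obs[rows[1L], ]); m <- which(!obs[rows[1L], ])
      Xo <- X[rows, o, drop = FALSE]
      ng <- nrow(Xo)
      So <- S[o, o, drop = FALSE]
      co <- chol(So); Soi <- chol2inv(co)
      dc <- sweep(Xo, 2L, mu[o])
      ll <- ll - ng / 2 * (length(o) * log(2 * pi) +
                             2 * sum(log(diag(co)))) -
        0.5 * sum((dc %*% Soi) * dc)
      Xhat <- matrix(0, ng, p)
      Xhat[, o] <- Xo
      Cadd <- matrix(0, p, p)
      if (length(m)) {
        G <- S[m, o, drop = FALSE] %*% Soi
        Xhat[, m] <- matrix(mu[m], ng, length(m), byrow = TRUE) + dc %*% t(G)
        Cmm <- S[m, m, drop = FALSE] - G %*% S[o, m, drop = FALSE]
        Cadd[m, m] <- ng * Cmm
      }
      T1 <- T1 + colSums(Xhat)
      T2 <- T2 + crossprod(Xhat) + Cadd
    }
    mu_new <- T1 / n
    S_new <- T2 / n - tcrossprod(mu_new)
    S_new <- (S_new + t(S_new)) / 2
    mu <- mu_new; S <- S_new
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = S, loglik = ll, iter = it)
}

# ---- main fitting front end ------------------------------------------------

#' Fit a latent-variable model by ML (covariance input) or FIML (raw data)
#'
#' Covariance input minimizes the normal-theory discrepancy
#' \eqn{F_{ML}} and reports \eqn{\chi^2 = (N-1) F_{min}} (Wishart
#' convention). Raw input maximizes the casewise full-information
#' likelihood with saturated means, and reports
#' \eqn{\chi^2 = 2(\ell_{sat} - \ell_{model})} with the saturated model
#' obtained by EM. Convergence requires the analytic gradient max-norm to
#' fall below `control$grad_tol` (default 1e-5); non-converged fits are
#' flagged, never silently returned as converged. Negative estimated
#' residual variances (Heywood cases) are allowed but flagged.
#'
#' @param model a `watershed_spec`, `watershed_ram`, or model syntax string.
#' @param data data frame / matrix of raw scores (NA = missing), or `NULL`.
#' @param sample_cov sample covariance matrix (named), if no raw data.
#' @param sample_nobs sample size for covariance input.
#' @param se `"none"` (default) or `"observed"` for observed-information
#'   standard errors.
#' @param start optional named start vector.
#' @param control list: `grad_tol` (1e-5), `rel_tol` (1e-10), `iter_max`
#'   (2000), `n_restarts` (3).
#' @return an object of class `watershed_fit`.
#' @export
sem_fit <- function(model, data = NULL, sample_cov = NULL, sample_nobs = NULL,
                    se = c("none", "observed"), start = NULL,
                    control = list()) {
  se <- match.arg(se)
  ctl <- utils::modifyList(list(grad_tol = 1e-5, rel_tol = 1e-10,
                                iter_max = 2000L, n_restarts = 3L), control)
  spec <- if (is.character(model)) parse_model(model)
  else if (inherits(model, "watershed_ram")) model$spec else model
  ram <- if (inherits(model, "watershed_ram")) model else build_ram(spec)
  df <- degrees_of_freedom(spec)

  msgs <- character()
  if (!is.null(data)) {
    X <- as.matrix(as.data.frame(data)[, ram$manifests, drop = FALSE])
    storage.mode(X) <- "double"
    drop <- rowSums(!is.na(X)) == 0
    if (any(drop)) {
      msgs <- c(msgs, sprintf("%d all-missing rows excluded", sum(drop)))
      X <- X[!drop, , drop = FALSE]
    }
    N <- nrow(X)
    pats <- build_patterns(X)
    complete <- all(!is.na(X))
    mu0 <- colMeans(X, na.rm = TRUE)
    S_obs <- stats::cov(X, use = "pairwise.complete.obs")
    S_obs[is.na(S_obs)] <- 0
    obj <- make_fiml_objective(ram, pats, N)
    th0 <- if (is.null(start)) c(start_values(ram, S_obs), mu0)
    else c(start[ram$par_names], mu0)
    input <- list(type = "raw", N = N, X = X, n_dropped = sum(drop),
                  S_obs = S_obs)
  } else {
    stopifnot(!is.null(sample_cov), !is.null(sample_nobs))
    S <- as.matrix(sample_cov)
    if (is.null(dimnames(S)) && nrow(S) == ram$p)
      dimnames(S) <- list(ram$manifests, ram$manifests)
    S <- S[ram$manifests, ram$manifests]
    if (max(abs(S - t(S))) > 1e-8) stop("sample covariance not symmetric")
    S <- (S + t(S)) / 2
    N <- sample_nobs
    if (N <= ram$p) stop("sample size must exceed number of manifests")
    obj <- make_cov_objective(ram, S)
    th0 <- if (is.null(start)) start_values(ram, S) else start[ram$par_names]
    input <- list(type = "cov", N = N, S = S)
  }
  # damp paths/covariances towards a feasible (PD) start if needed
  dampable <- unique(c(ram$A_par,
                       ram$S_par[ram$S_cells[, 1] != ram$S_cells[, 2]]))
  damp <- 0L
  while (obj$fn(th0) >= 1e9 && damp < 8L) {
    th0[dampable] <- th0[dampable] * 0.5
    damp <- damp + 1L
  }
  obj$cache$start <- th0

  best <- NULL
  for (k in 0:ctl$n_restarts) {
    st <- if (k == 0) th0 else th0 * (1 + 0.2 * sin(seq_along(th0) * k)) +
      0.05 * cos(seq_along(th0) + k)
    opt <- tryCatch(
      stats::nlminb(st, obj$fn, obj$gr,
                    control = list(iter.max = ctl$iter_max,
                                   eval.max = 4L * ctl$iter_max,
                                   rel.tol = ctl$rel_tol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    opt$gmax <- max(abs(obj$gr(opt$par)))
    if (opt$gmax > ctl$grad_tol) {
      # polish: BFGS tightens the gradient where nlminb stops on f-change
      pol <- tryCatch(
        stats::optim(opt$par, obj$fn, obj$gr, method = "BFGS",
                     control = list(maxit = 200L, reltol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(pol) && pol$value <= opt$objective + 1e-10) {
        opt$par <- pol$par
        opt$objective <- min(opt$objective, pol$value)
        opt$gmax <- max(abs(obj$gr(opt$par)))
      }
    }
    if (is.null(best) || opt$objective < best$objective - 1e-12 ||
        (abs(opt$objective - best$objective) <= 1e-12 &&
         opt$gmax < best$gmax)) best <- opt
    if (!is.null(best) && best$gmax <= ctl$grad_tol) break
  }
  if (is.null(best)) stop("optimization failed for all starting points")
  converged <- is.finite(best$objective) && best$gmax <= ctl$grad_tol &&
    best$objective < 1e9

  theta_all <- best$par
  theta <- stats::setNames(theta_all[seq_len(ram$npar)], ram$par_names)
  mu <- if (input$type == "raw")
    stats::setNames(theta_all[ram$npar + seq_len(ram$p)], ram$manifests)
  else NULL

  Sigma_hat <- implied_covariance(ram, theta)
  full <- ram_total_cov(ram, theta)

  # Heywood screen: negative free variances
  hey <- FALSE
  if (nrow(ram$S_cells)) {
    dg <- ram$S_cells[, 1] == ram$S_cells[, 2]
    if (any(dg) && any(theta[ram$S_par[dg]] < 0)) {
      hey <- TRUE
      msgs <- c(msgs, "Heywood case: negative estimated variance")
    }
  }

  if (input$type == "cov") {
    F_min <- max(0, best$objective)
    chisq <- (N - 1) * F_min
    Sb <- (N - 1) / N * input$S
    cS <- chol(Sb); cH <- chol(Sigma_hat)
    loglik <- -(N / 2) * (ram$p * log(2 * pi) + 2 * sum(log(diag(cH))) +
                            sum(chol2inv(cH) * Sb))
    loglik_sat <- -(N / 2) * (ram$p * log(2 * pi) +
                                2 * sum(log(diag(cS))) + ram$p)
    npar_total <- ram$npar
  } else {
    loglik <- -N * best$objective
    sat <- em_saturated(input$X)
    loglik_sat <- sat$loglik
    chisq <- max(0, 2 * (loglik_sat - loglik))
    F_min <- chisq / (N - 1)
    npar_total <- ram$npar + ram$p
  }

  res <- structure(list(
    spec = spec, ram = ram, theta = theta, mu = mu,
    input = input, N = N,
    F_min = F_min, loglik = loglik, loglik_sat = loglik_sat,
    chisq = chisq, df = df,
    p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
    npar = ram$npar, npar_total = npar_total,
    converged = converged, gmax = best$gmax, heywood = hey,
    messages = msgs, objective = obj,
    Sigma_hat = Sigma_hat, V_full = full$V,
    se = NULL, vcov = NULL), class = "watershed_fit")

  if (se == "observed") {
    H <- num_hessian(obj$gr, theta_all)
    scale <- if (input$type == "cov") (N - 1) / 2 else N
    V <- tryCatch(solve(scale * H), error = function(e) NULL)
    if (!is.null(V)) {
      sev <- sqrt(pmax(diag(V), 0))
      res$se <- stats::setNames(sev[seq_len(ram$npar)], ram$par_names)
      res$vcov <- V[seq_len(ram$npar), seq_len(ram$npar), drop = FALSE]
    } else res$messages <- c(res$messages, "information matrix singular")
  }
  res
}

num_hessian <- function(gr, x, eps = 1e-6) {
  n <- length(x)
  g0 <- gr(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + h
    H[, i] <- (gr(xp) - g0) / h
  }
  (H + t(H)) / 2
}

#' @export
print.watershed_fit <- function(x, ...) {
  cat(sprintf(
    "watershed fit (%s input): chisq(%d) = %.2f, p = %.3g, npar = %d%s\n",
    x$input$type, x$df, x$chisq, x$p_value, x$npar,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  if (x$heywood) cat("  note: Heywood case flagged\n")
  invisible(x)
}

#' @export
coef.watershed_fit <- function(object, ...) object$theta

#' @export
logLik.watershed_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar_total, nobs = object$N,
            class = "logLik")
}

#' Standardized solution of a fitted model
#'
#' Rescales estimates by model-implied standard deviations: loadings and
#' paths become correlations-per-SD, covariances become correlations.
#' Standardized regression paths are not bounded by 1 in magnitude
#' (suppression among highly correlated predictors can push them past
#' -1 or +1).
#'
#' @param fit a `watershed_fit`.
#' @return data frame with columns lhs, op, rhs, est, std.
#' @export
standardized_solution <- function(fit) {
  stopifnot(inherits(fit, "watershed_fit"))
  ram <- fit$ram
  V <- fit$V_full
  sd_all <- sqrt(pmax(diag(V), 0))
  if (any(sd_all == 0))
    stop("zero model-implied variance for: ",
         paste(ram$vars[sd_all == 0], collapse = ", "))
  tab <- fit$spec$table
  idx <- stats::setNames(seq_len(ram$nv), ram$vars)
  est <- ifelse(is.na(tab$fixed), fit$theta[tab$par], tab$fixed)
  std <- numeric(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    if (tab$op[r] == "=~") {        # latent -> indicator
      std[r] <- est[r] * sd_all[idx[tab$lhs[r]]] / sd_all[idx[tab$rhs[r]]]
    } else if (tab$op[r] == "~") {  # predictor -> outcome
      std[r] <- est[r] * sd_all[idx[tab$rhs[r]]] / sd_all[idx[tab$lhs[r]]]
    } else {
      std[r] <- est[r] / (sd_all[idx[tab$lhs[r]]] * sd_all[idx[tab$rhs[r]]])
    }
  }
  out <- data.frame(lhs = tab$lhs, op = tab$op, rhs = tab$rhs,
                    free = is.na(tab$fixed), est = est, std = std,
                    stringsAsFactors = FALSE)
  if (!is.null(fit$se)) {
    out$se <- ifelse(is.na(tab$fixed), fit$se[tab$par], NA_real_)
    out$z <- out$est / out$se
  }
  out
}

#' Proportion of explained variance for an endogenous variable
#'
#' `1 - residual variance / model-implied total variance`.
#'
#' @param fit a `watershed_fit`.
#' @param variable variable name; `NULL` returns all endogenous variables.
#' @return named numeric vector of R-squared values in `[0, 1]`.
#' @export
r_squared <- function(fit, variable = NULL) {
  stopifnot(inherits(fit, "watershed_fit"))
  tab <- fit$spec$table
  endo <- unique(c(tab$rhs[tab$op == "=~"], tab$lhs[tab$op == "~"]))
  if (is.null(variable)) variable <- endo
  bad <- setdiff(variable, endo)
  if (length(bad))
    stop("not endogenous: ", paste(bad, collapse = ", "))
  ram <- fit$ram
  m <- ram_fill(ram, fit$theta)
  V <- fit$V_full
  idx <- stats::setNames(seq_len(ram$nv), ram$vars)
  out <- vapply(variable, function(v) {
    i <- idx[[v]]
    r2 <- 1 - m$S[i, i] / V[i, i]
    min(1, max(0, r2))
  }, numeric(1))
  out
}

#' Regression-method factor scores
#'
#' Linear in the observed data: `scores = (x - mu) Sigma^-1 Cov(x, eta)`
#' using the model-implied covariance. Rows with any missing manifest get
#' `NA` scores (complete-data rows only).
#'
#' @param fit a `watershed_fit`.
#' @param data raw data; defaults to the data the model was fit to.
#' @return matrix of per-subject latent scores (one column per latent).
#' @export
factor_scores <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "watershed_fit"))
  ram <- fit$ram
  if (!length(ram$latents)) stop("model has no latent variables")
  if (is.null(data)) {
    if (fit$input$type != "raw") stop("raw data required for factor scores")
    X <- fit$input$X
  } else X <- as.matrix(as.data.frame(data)[, ram$manifests, drop = FALSE])
  mu <- if (!is.null(fit$mu)) fit$mu else colMeans(X, na.rm = TRUE)
  cov_x_eta <- fit$V_full[ram$man_idx, ram$p + seq_along(ram$latents),
                          drop = FALSE]
  Wt <- solve(fit$Sigma_hat, cov_x_eta)
  ok <- stats::complete.cases(X)
  scores <- matrix(NA_real_, nrow(X), length(ram$latents),
                   dimnames = list(NULL, ram$latents))
  if (any(ok)) scores[ok, ] <- sweep(X[ok, , drop = FALSE], 2L, mu) %*% Wt
  scores
}
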