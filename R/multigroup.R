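# Multi-group covariance ML with parameter sharing.
#
# All parameters are equality-constrained across groups except the `focus`
# parameters, which get one copy per group ("par@g"). Group means are
# saturated and profiled out (each group's ML mean is its sample mean), so
# the objective depends on the group covariances only:
#   D(theta) = sum_g n_g [ log|Sigma_g| + tr(Sigma_g^-1 S_g) ] / (2N)
# with S_g the group's biased (/n_g) covariance.

fit_multigroup <- function(ram, groups, focus = character(),
                           start = NULL, control = list()) {
  stopifnot(inherits(ram, "watershed_ram"), length(groups) >= 1)
  ctl <- utils::modifyList(list(grad_tol = 1e-5, rel_tol = 1e-10,
                                iter_max = 1000L), control)
  G <- length(groups)
  bad <- setdiff(focus, ram$par_names)
  if (length(bad)) stop("focus parameter(s) not in model: ",
                        paste(bad, collapse = ", "))
  shared <- setdiff(ram$par_names, focus)
  comb_names <- c(shared,
                  unlist(lapply(seq_len(G), function(g)
                    if (length(focus)) paste0(focus, "@", g) else character())))
  ncomb <- length(comb_names)
  # per-group index into the combined vector, in ram$par_names order
  idx_g <- lapply(seq_len(G), function(g) {
    i <- match(ram$par_names, shared)
    f <- match(ram$par_names, focus)
    take <- !is.na(f)
    i[take] <- length(shared) + (g - 1L) * length(focus) + f[take]
    i
  })
  N <- sum(vapply(groups, `[[`, numeric(1), "n"))
  p <- ram$p; npar <- ram$npar
  ci <- ram_cidx(ram)
  wg <- vapply(groups, function(g) g$n / (2 * N), numeric(1))
  cache <- new.env(parent = emptyenv()); cache$theta <- NULL
  compute <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$res)
    val <- 0; grad <- numeric(ncomb); ok <- TRUE
    for (g in seq_len(G)) {
      r <- ram_group_obj(theta[idx_g[[g]]], ram$A0, ram$S0, ci$Acells,
                         ci$Apar, ci$Scells, ci$Spar, p, groups[[g]]$S,
                         wg[g], npar, TRUE)
      if (!isTRUE(r$ok)) { ok <- FALSE; break }
      val <- val + r$val
      grad[idx_g[[g]]] <- grad[idx_g[[g]]] + as.vector(r$grad)
    }
    res <- if (ok) list(val = val, grad = grad)
    else {
      d <- theta - cache$start
      list(val = 1e10 * (1 + sum(d * d)), grad = 2e10 * d)
    }
    cache$theta <- theta; cache$res <- res
    res
  }

  if (is.null(start)) {
    Sw <- Reduce(`+`, lapply(groups, function(g) g$n * g$S)) / N
    dimnames(Sw) <- list(ram$manifests, ram$manifests)
    base <- start_values(ram, Sw)
    start <- c(base[shared],
               unlist(lapply(seq_len(G), function(g) base[focus])))
  }
  names(start) <- comb_names
  cache$start <- start
  fn <- function(t) compute(t)$val
  gr <- function(t) compute(t)$grad
  opt <- stats::nlminb(start, fn, gr,
                       control = list(iter.max = ctl$iter_max,
                                      eval.max = 4L * ctl$iter_max,
                                      rel.tol = ctl$rel_tol))
  gmax <- max(abs(gr(opt$par)))
  if (gmax > ctl$grad_tol) {
    pol <- tryCatch(stats::optim(opt$par, fn, gr, method = "BFGS",
                                 control = list(maxit = 200L,
                                                reltol = 1e-14)),
                    error = function(e) NULL)
    if (!is.null(pol) && pol$value <= opt$objective + 1e-10) {
      opt$par <- pol$par; gmax <- max(abs(gr(opt$par)))
    }
  }
  theta <- stats::setNames(opt$par, comb_names)
  Sig_g <- lapply(seq_len(G), function(g)
    implied_covariance(ram, unname(theta[idx_g[[g]]])))
  ll <- 0
  for (g in seq_len(G)) {
    cS <- chol(Sig_g[[g]])
    ll <- ll - groups[[g]]$n / 2 *
      (p * log(2 * pi) + 2 * sum(log(diag(cS))) +
         sum(chol2inv(cS) * groups[[g]]$S))
  }
  list(theta = theta, loglik = ll, converged = gmax <= ctl$grad_tol,
       gmax = gmax, Sigma_g = Sig_g, idx_g = idx_g,
       npar = ncomb, comb_names = comb_names, focus = focus)
}

group_stats <- function(X, side) {
  lapply(split(seq_len(nrow(X)), side), function(ix) {
    Xi <- X[ix, , drop = FALSE]
    mu <- colMeans(Xi)
    list(S = crossprod(sweep(Xi, 2L, mu)) / nrow(Xi), n = nrow(Xi),
         mu = mu, rows = ix)
  })
}

mvn_loglik_rows <- function(X, mu, Sigma) {
  if (!nrow(X)) return(0)
  cS <- chol(Sigma)
  d <- sweep(X, 2L, mu)
  z <- d %*% chol2inv(cS)
  -nrow(X) / 2 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(cS)))) -
    0.5 * sum(z * d)
}
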