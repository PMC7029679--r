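#' Compile a model specification to RAM matrices
#'
#' The reticular action model writes the implied covariance of the
#' manifest variables as \eqn{\Sigma = F (I-A)^{-1} S (I-A)^{-T} F^T}
#' with `A` holding directed paths (loadings and regressions), `S` the
#' symmetric (co)variances, and `F` selecting manifest rows.
#'
#' @param spec a `watershed_spec`.
#' @return an object of class `watershed_ram` with fixed-value matrices,
#'   free-cell indices, the parameter map, and bookkeeping used by the
#'   fitting engine.
#' @export
build_ram <- function(spec) {
  stopifnot(inherits(spec, "watershed_spec"))
  vars <- c(spec$manifests, spec$latents)
  nv <- length(vars)
  p <- length(spec$manifests)
  idx <- stats::setNames(seq_len(nv), vars)
  tab <- spec$table

  A0 <- matrix(0, nv, nv, dimnames = list(vars, vars))
  S0 <- matrix(0, nv, nv, dimnames = list(vars, vars))
  # free cells: (row, col, parameter id)
  Ai <- Aj <- Si <- Sj <- integer(); Ap <- Sp <- character()

  for (r in seq_len(nrow(tab))) {
    op <- tab$op[r]
    if (op == "=~") { i <- idx[[tab$rhs[r]]]; j <- idx[[tab$lhs[r]]] }
    else if (op == "~") { i <- idx[[tab$lhs[r]]]; j <- idx[[tab$rhs[r]]] }
    else { i <- idx[[tab$lhs[r]]]; j <- idx[[tab$rhs[r]]] }
    if (op == "~~") {
      if (is.na(tab$fixed[r])) {
        Si <- c(Si, i); Sj <- c(Sj, j); Sp <- c(Sp, tab$par[r])
      } else { S0[i, j] <- S0[j, i] <- tab$fixed[r] }
    } else {
      if (is.na(tab$fixed[r])) {
        Ai <- c(Ai, i); Aj <- c(Aj, j); Ap <- c(Ap, tab$par[r])
      } else { A0[i, j] <- tab$fixed[r] }
    }
  }

  # acyclicity of the directed part (structure: fixed nonzero or free)
  adj <- A0 != 0
  if (length(Ai)) adj[cbind(Ai, Aj)] <- TRUE
  reach <- adj
  for (k in seq_len(nv)) reach <- (reach | (reach %*% adj) > 0)
  if (any(diag(reach) > 0))
    stop("cyclic directed paths among: ",
         paste(vars[diag(reach) > 0], collapse = ", "))

  # latent scaling must exist (fixed loading or fixed variance)
  for (lt in spec$latents) {
    ld <- tab$op == "=~" & tab$lhs == lt
    vr <- tab$op == "~~" & tab$lhs == lt & tab$rhs == lt
    if (!any(!is.na(tab$fixed[ld])) && !any(!is.na(tab$fixed[vr])))
      stop("identification error: latent '", lt, "' has no scaling constraint")
  }

  par_names <- unique(c(Ap, Sp))
  # resolve to the spec-wide free-parameter ordering for stability
  par_names <- unique(stats::na.omit(tab$par))
  pmap <- lapply(stats::setNames(par_names, par_names), function(pn) {
    cells <- list()
    ka <- which(Ap == pn)
    if (length(ka)) cells <- c(cells, lapply(ka, function(k)
      c(matrix = "A", row = Ai[k], col = Aj[k])))
    ks <- which(Sp == pn)
    if (length(ks)) cells <- c(cells, lapply(ks, function(k)
      c(matrix = "S", row = Si[k], col = Sj[k])))
    cells
  })

  structure(list(
    vars = vars, manifests = spec$manifests, latents = spec$latents,
    man_idx = seq_len(p), nv = nv, p = p,
    A0 = A0, S0 = S0,
    A_cells = cbind(row = Ai, col = Aj),
    A_par = match(Ap, par_names),
    S_cells = cbind(row = Si, col = Sj),
    S_par = match(Sp, par_names),
    par_names = par_names, npar = length(par_names),
    param_map = pmap, spec = spec), class = "watershed_ram")
}

#' @export
print.watershed_ram <- function(x, ...) {
  cat("RAM matrices:", x$nv, "variables (", x$p, "manifest ),",
      x$npar, "free parameters\n")
  invisible(x)
}

# fill A and S for a parameter vector
ram_fill <- function(ram, theta) {
  A <- ram$A0; S <- ram$S0
  if (nrow(ram$A_cells)) A[ram$A_cells] <- theta[ram$A_par]
  if (nrow(ram$S_cells)) {
    S[ram$S_cells] <- theta[ram$S_par]
    S[ram$S_cells[, c(2, 1), drop = FALSE]] <- theta[ram$S_par]
  }
  list(A = A, S = S)
}

# full-variable model-implied covariance B S B', B = (I-A)^-1
ram_total_cov <- function(ram, theta) {
  m <- ram_fill(ram, theta)
  B <- solve(diag(ram$nv) - m$A)
  V <- B %*% m$S %*% t(B)
  list(V = V, B = B, A = m$A, S = m$S)
}

#' Model-implied covariance matrix of the manifest variables
#'
#' @param ram a `watershed_ram` (or a `watershed_spec`, compiled on the fly).
#' @param theta numeric vector of free parameter values, in
#'   `ram$par_names` order (names, if present, are checked).
#' @return p x p implied covariance `F (I-A)^-1 S (I-A)^-T F'`.
#' @export
implied_covariance <- function(ram, theta) {
  if (inherits(ram, "watershed_spec")) ram <- build_ram(ram)
  stopifnot(inherits(ram, "watershed_ram"), length(theta) == ram$npar)
  if (!is.null(names(theta))) theta <- theta[ram$par_names]
  m <- ram_fill(ram, theta)
  IA <- diag(ram$nv) - m$A
  B <- tryCatch(solve(IA), error = function(e)
    stop("singular (I - A); check directed paths involving: ",
         paste(ram$vars[colSums(m$A != 0) > 0], collapse = ", ")))
  V <- B %*% m$S %*% t(B)
  Sig <- V[ram$man_idx, ram$man_idx, drop = FALSE]
  dimnames(Sig) <- list(ram$manifests, ram$manifests)
  (Sig + t(Sig)) / 2
}
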