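#' Parse lavaan-style model syntax into a model specification
#'
#' Understands three operators, one relation per line (`#` starts a comment):
#' \describe{
#'   \item{`=~`}{measurement: `factor =~ ind1 + ind2 + ...`}
#'   \item{`~`}{regression: `outcome ~ pred1 + b1*pred2 + ...`}
#'   \item{`~~`}{(co)variance: `a ~~ b`, `a ~~ a`}
#' }
#' A term may carry a modifier `value*name` (numeric value fixes the
#' parameter; any other token is an equality label shared by all parameters
#' carrying it, so `gf ~ b1*wm + b1*speed` estimates one path value).
#' `0*x` fixes a parameter to zero.
#'
#' Defaults follow confirmatory factor analysis conventions:
#' each latent is scaled by fixing its first loading to 1 ("marker
#' variable") unless a loading is explicitly fixed or `std_lv = TRUE`;
#' a single-indicator latent gets loading 1 and indicator residual 0;
#' every variable receives a free (residual) variance unless one is given;
#' covariances among exogenous variables are free unless stated.
#'
#' @param text model syntax string (possibly multi-line).
#' @param std_lv logical; if `TRUE`, identify latents by fixing their
#'   (residual) variances to 1 and freeing all loadings.
#' @param auto_cov logical; free covariances among exogenous variables
#'   automatically (default `TRUE`). Set `FALSE` for independence-style
#'   baselines.
#' @return an object of class `watershed_spec`.
#' @export
parse_model <- function(text, std_lv = FALSE, auto_cov = TRUE) {
  stopifnot(is.character(text), length(text) >= 1L)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines_raw <- lines
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  if (!any(keep)) stop("parse error: empty model syntax")

  rows <- list()
  name_rx <- "^[A-Za-z._][A-Za-z0-9._]*$"
  for (k in which(keep)) {
    ln <- lines[[k]]
    op <- if (grepl("=~", ln, fixed = TRUE)) "=~"
    else if (grepl("~~", ln, fixed = TRUE)) "~~"
    else if (grepl("~", ln, fixed = TRUE)) "~"
    else stop(sprintf("parse error on line %d: no operator in '%s'",
                      k, trimws(lines_raw[[k]])))
    parts <- strsplit(ln, op, fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("parse error on line %d: expected 'lhs %s rhs'", k, op))
    lhs <- trimws(parts[[1L]])
    if (!grepl(name_rx, lhs))
      stop(sprintf("parse error on line %d: bad left-hand name '%s'", k, lhs))
    terms <- trimws(strsplit(parts[[2L]], "+", fixed = TRUE)[[1L]])
    if (!length(terms) || any(!nzchar(terms)))
      stop(sprintf("parse error on line %d: empty term", k))
    for (tm in terms) {
      mod <- NA_character_
      nm <- tm
      if (grepl("*", tm, fixed = TRUE)) {
        bits <- strsplit(tm, "*", fixed = TRUE)[[1L]]
        if (length(bits) != 2L)
          stop(sprintf("parse error on line %d: bad modifier '%s'", k, tm))
        mod <- trimws(bits[[1L]]); nm <- trimws(bits[[2L]])
      }
      if (!grepl(name_rx, nm))
        stop(sprintf("parse error on line %d: bad variable name '%s'", k, nm))
      force_free <- !is.na(mod) && mod == "NA"   # lavaan-style NA* = free
      fixed <- if (force_free) NA_real_
      else suppressWarnings(as.numeric(mod))
      rows[[length(rows) + 1L]] <- data.frame(
        lhs = lhs, op = op, rhs = nm,
        fixed = fixed,
        label = if (!is.na(mod) && is.na(fixed) && !force_free) mod
        else NA_character_,
        force_free = force_free,
        user = TRUE, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)

  latents <- unique(tab$lhs[tab$op == "=~"])
  all_names <- unique(c(rbind(tab$lhs, tab$rhs)))  # order of appearance-ish
  all_names <- unique(c(tab$lhs[1L], all_names))
  manifests <- setdiff(unique(unlist(Map(c, tab$lhs, tab$rhs))), latents)
  # stable order: first appearance scanning rows lhs-then-rhs
  appear <- unique(unlist(mapply(function(a, b) c(a, b), tab$lhs, tab$rhs,
                                 SIMPLIFY = FALSE)))
  manifests <- appear[appear %in% manifests]
  latents <- appear[appear %in% latents]

  if (any(tab$op == "=~" & tab$rhs %in% latents))
    stop("specification error: higher-order factors are not supported")
  dup <- duplicated(tab[, c("lhs", "op", "rhs")]) |
    (tab$op == "~~" & duplicated(data.frame(a = pmin(tab$lhs, tab$rhs),
                                            b = pmax(tab$lhs, tab$rhs),
                                            op = tab$op)))
  if (any(dup & tab$op != "~")) tab <- tab[!dup, ]

  # canonical order for symmetric rows
  sw <- tab$op == "~~" & tab$lhs > tab$rhs
  tmp <- tab$lhs[sw]; tab$lhs[sw] <- tab$rhs[sw]; tab$rhs[sw] <- tmp

  # scaling constraints per latent
  for (lt in latents) {
    ld <- which(tab$op == "=~" & tab$lhs == lt)
    has_fixed_loading <- any(!is.na(tab$fixed[ld]))
    var_row <- which(tab$op == "~~" & tab$lhs == lt & tab$rhs == lt)
    has_fixed_var <- length(var_row) && any(!is.na(tab$fixed[var_row]))
    has_forced <- any(tab$force_free[ld])
    if (length(ld) == 1L) {
      if (is.na(tab$fixed[ld]) && !tab$force_free[ld]) tab$fixed[ld] <- 1
      ind <- tab$rhs[ld]
      rv <- which(tab$op == "~~" & tab$lhs == ind & tab$rhs == ind)
      if (!length(rv))
        tab <- rbind(tab, data.frame(lhs = ind, op = "~~", rhs = ind,
                                     fixed = 0, label = NA_character_,
                                     force_free = FALSE, user = FALSE))
    } else if (std_lv && !has_fixed_loading && !has_fixed_var) {
      if (!length(var_row))
        tab <- rbind(tab, data.frame(lhs = lt, op = "~~", rhs = lt,
                                     fixed = 1, label = NA_character_,
                                     force_free = FALSE, user = FALSE))
    } else if (!has_fixed_loading && !has_fixed_var && !has_forced) {
      tab$fixed[ld[1L]] <- 1  # marker variable
    }
  }

  # free variances for every variable lacking one
  for (v in c(manifests, latents)) {
    if (!any(tab$op == "~~" & tab$lhs == v & tab$rhs == v))
      tab <- rbind(tab, data.frame(lhs = v, op = "~~", rhs = v,
                                   fixed = NA_real_, label = NA_character_,
                                   force_free = FALSE, user = FALSE))
  }

  # free covariances among exogenous variables
  endo <- unique(c(tab$rhs[tab$op == "=~"], tab$lhs[tab$op == "~"]))
  exo <- setdiff(c(manifests, latents), endo)
  if (auto_cov && length(exo) > 1L) {
    for (i in seq_len(length(exo) - 1L)) for (j in seq(i + 1L, length(exo))) {
      a <- min(exo[i], exo[j]); b <- max(exo[i], exo[j])
      if (!any(tab$op == "~~" & tab$lhs == a & tab$rhs == b))
        tab <- rbind(tab, data.frame(lhs = a, op = "~~", rhs = b,
                                     fixed = NA_real_, label = NA_character_,
                                     force_free = FALSE, user = FALSE))
    }
  }

  rownames(tab) <- NULL
  tab$name <- paste0(tab$lhs, tab$op, tab$rhs)
  # parameter ids: shared for equal labels, one per free parameter otherwise
  tab$par <- ifelse(is.na(tab$fixed),
                    ifelse(is.na(tab$label), tab$name, tab$label),
                    NA_character_)
  spec <- structure(list(latents = latents, manifests = manifests,
                         table = tab, std_lv = std_lv),
                    class = "watershed_spec")
  spec
}

#' Serialize a model specification back to model syntax
#'
#' `parse_model(model_syntax(spec))` reproduces the parameter map exactly.
#'
#' @param spec a `watershed_spec`.
#' @return single string of model syntax.
#' @export
model_syntax <- function(spec) {
  stopifnot(inherits(spec, "watershed_spec"))
  tab <- spec$table
  term <- ifelse(!is.na(tab$fixed), paste0(tab$fixed, "*", tab$rhs),
                 ifelse(!is.na(tab$label), paste0(tab$label, "*", tab$rhs),
                        ifelse(tab$force_free, paste0("NA*", tab$rhs),
                               tab$rhs)))
  paste(paste(tab$lhs, tab$op, term), collapse = "\n")
}

#' @export
print.watershed_spec <- function(x, ...) {
  cat("watershed model spec:", length(x$latents), "latent(s),",
      length(x$manifests), "manifest(s),",
      n_free_parameters(x), "free parameter(s), df =",
      degrees_of_freedom(x), "\n")
  invisible(x)
}

#' Number of distinct free parameters in a model
#' @param spec a `watershed_spec`.
#' @return integer count of distinct free parameters.
#' @export
n_free_parameters <- function(spec) {
  length(unique(stats::na.omit(spec$table$par)))
}

#' Degrees of freedom of a covariance-structure model
#'
#' `df = p(p+1)/2 - q` with `p` manifests and `q` distinct free parameters
#' (covariance-only analysis, no mean structure).
#'
#' @param spec a `watershed_spec`.
#' @return integer degrees of freedom.
#' @export
degrees_of_freedom <- function(spec) {
  p <- length(spec$manifests)
  df <- p * (p + 1L) / 2L - n_free_parameters(spec)
  if (df < 0) stop("under-identification: negative degrees of freedom (df = ",
                   df, ")")
  as.integer(df)
}

#' Necessary-condition identification report
#'
#' Checks the t-rule (df >= 0), a scaling constraint per latent, and fixed
#' residuals for single-indicator latents. These are necessary, not
#' sufficient, conditions; the report never errors.
#'
#' @param spec a `watershed_spec`.
#' @return list with `ok` flag and character vector `messages`.
#' @export
check_identification <- function(spec) {
  tab <- spec$table
  msgs <- character()
  p <- length(spec$manifests)
  q <- n_free_parameters(spec)
  if (p * (p + 1) / 2 - q < 0)
    msgs <- c(msgs, sprintf(
      "t-rule violated: %d free parameters > %d distinct moments",
      q, p * (p + 1) %/% 2))
  for (lt in spec$latents) {
    ld <- tab$op == "=~" & tab$lhs == lt
    vr <- tab$op == "~~" & tab$lhs == lt & tab$rhs == lt
    if (!any(!is.na(tab$fixed[ld])) && !any(!is.na(tab$fixed[vr])))
      msgs <- c(msgs, sprintf("no scaling constraint for latent '%s'", lt))
    if (sum(ld) == 1L) {
      ind <- tab$rhs[ld]
      rv <- tab$op == "~~" & tab$lhs == ind & tab$rhs == ind
      if (!any(!is.na(tab$fixed[rv])))
        msgs <- c(msgs, sprintf(
          "single-indicator latent '%s' needs the indicator residual fixed",
          lt))
    }
  }
  if (!length(msgs)) msgs <- "passes necessary conditions"
  list(ok = identical(msgs, "passes necessary conditions"), messages = msgs)
}

#' Serialize a model specification to JSON
#' @param spec a `watershed_spec`.
#' @param path optional file path; if missing, the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
spec_to_json <- function(spec, path = NULL) {
  out <- jsonlite::toJSON(list(latents = spec$latents,
                               manifests = spec$manifests,
                               std_lv = spec$std_lv,
                               table = spec$table), digits = NA,
                          na = "null", auto_unbox = TRUE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Read a model specification from JSON written by [spec_to_json()]
#' @param path file path or JSON string.
#' @return a `watershed_spec`.
#' @export
spec_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  tab <- as.data.frame(x$table, stringsAsFactors = FALSE)
  tab$fixed <- as.numeric(tab$fixed)
  structure(list(latents = as.character(x$latents),
                 manifests = as.character(x$manifests),
                 table = tab, std_lv = isTRUE(x$std_lv)),
            class = "watershed_spec")
}
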