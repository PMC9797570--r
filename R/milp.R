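# ---- solver-agnostic MILP container -----------------------------------
#
# A milp_model is a plain description: a variable table, sparse constraint
# triplets with two-sided row bounds, and a minimization objective. Every
# constraint row carries the tag of the model-equation group it encodes so
# models can be audited structurally.

milp_new <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$name <- character(); e$vkind <- character()
  e$lb <- numeric(); e$ub <- numeric(); e$group <- character()
  e$ri <- list(); e$rj <- list(); e$rx <- list()
  e$cl <- numeric(); e$cu <- numeric(); e$rtag <- character()
  e$obj <- list()
  e
}

# Add a block of variables; returns their column indices.
milp_add_vars <- function(m, names, kind = c("binary", "continuous"),
                          group, lb = NULL, ub = NULL) {
  kind <- match.arg(kind)
  n <- length(names)
  if (is.null(lb)) lb <- if (kind == "binary") rep(0, n) else rep(0, n)
  if (is.null(ub)) ub <- if (kind == "binary") rep(1, n) else rep(Inf, n)
  idx <- length(m$name) + seq_len(n)
  m$name <- c(m$name, names)
  m$vkind <- c(m$vkind, rep(kind, n))
  m$lb <- c(m$lb, rep_len(lb, n)); m$ub <- c(m$ub, rep_len(ub, n))
  m$group <- c(m$group, rep(group, n))
  idx
}

# Add one constraint row: sum(coef * x[idx]) in [lo, hi].
milp_add_row <- function(m, idx, coef, lo, hi, tag) {
  r <- length(m$cl) + 1L
  m$ri[[r]] <- rep(r, length(idx)); m$rj[[r]] <- idx; m$rx[[r]] <- coef
  m$cl[r] <- lo; m$cu[r] <- hi; m$rtag[r] <- tag
  invisible(r)
}

milp_set_objective <- function(m, idx, coef) {
  m$obj <- list(idx = idx, coef = coef)
  invisible(m)
}

# Freeze the builder environment into an immutable model object.
milp_finalize <- function(m, meta = list()) {
  nvar <- length(m$name)
  obj <- numeric(nvar)
  obj[m$obj$idx] <- m$obj$coef
  structure(list(
    kind = m$kind,
    vars = data.frame(name = m$name, kind = m$vkind, lb = m$lb, ub = m$ub,
                      group = m$group, stringsAsFactors = FALSE),
    A = list(i = unlist(m$ri), j = unlist(m$rj), x = unlist(m$rx)),
    cl = m$cl, cu = m$cu, row_tag = m$rtag,
    obj = obj, sense = "min", meta = meta),
    class = "milp_model")
}

#' @export
print.milp_model <- function(x, ...) {
  cat(sprintf("<milp_model '%s': %d variables (%d binary), %d constraints>\n",
              x$kind, nrow(x$vars), sum(x$vars$kind == "binary"),
              length(x$cl)))
  tab <- table(x$row_tag)
  for (t in names(tab)) cat(sprintf("  %-28s %5d row(s)\n", t, tab[[t]]))
  invisible(x)
}

#' Count model variables by structural group
#'
#' @param model a built MILP model
#' @param groups restrict to these variable groups (default: all)
#' @return named count per group
#' @export
milp_variable_census <- function(model, groups = NULL) {
  g <- model$vars$group
  if (!is.null(groups)) g <- g[g %in% groups]
  table(factor(g, levels = unique(g)))
}

#' Export a model in CPLEX LP format
#'
#' Solver-independent inspection format; any LP-capable solver can read it.
#'
#' @param model a \code{milp_model}
#' @param path output file path
#' @export
milp_write_lp <- function(model, path) {
  sane <- gsub("[^A-Za-z0-9_]", "_", model$vars$name)
  term <- function(j, x) sprintf("%+.12g %s", x, sane[j])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("\\ gduplan model export", "Minimize", " obj:"), con)
  oj <- which(model$obj != 0)
  writeLines(paste0("  ", paste(term(oj, model$obj[oj]), collapse = " ")), con)
  writeLines("Subject To", con)
  rows <- split(seq_along(model$A$i), model$A$i)
  for (r in seq_along(model$cl)) {
    ix <- rows[[as.character(r)]]
    lhs <- paste(term(model$A$j[ix], model$A$x[ix]), collapse = " ")
    lo <- model$cl[r]; hi <- model$cu[r]
    nm <- sprintf("c%d_%s", r, gsub("[^A-Za-z0-9_]", "_", model$row_tag[r]))
    if (is.finite(lo) && is.finite(hi) && lo == hi)
      writeLines(sprintf(" %s: %s = %.12g", nm, lhs, lo), con)
    else {
      if (is.finite(hi)) writeLines(sprintf(" %s_u: %s <= %.12g", nm, lhs, hi), con)
      if (is.finite(lo)) writeLines(sprintf(" %s_l: %s >= %.12g", nm, lhs, lo), con)
    }
  }
  writeLines("Bounds", con)
  for (v in seq_len(nrow(model$vars)))
    if (model$vars$kind[v] == "continuous")
      writeLines(sprintf(" 0 <= %s <= %s", sane[v],
                         ifelse(is.finite(model$vars$ub[v]),
                                sprintf("%.12g", model$vars$ub[v]), "inf")), con)
  writeLines("Binary", con)
  writeLines(paste(" ", sane[model$vars$kind == "binary"]), con)
  writeLines("End", con)
  invisible(path)
}

# Strict-inequality margin for the earliest-harvest upper constraint:
# cum[h-1] - cum[p] < G_min is realized as <= G_min - eps.
gdu_epsilon <- function(required_gdu) {
  pmax(1e-6 * required_gdu, 1e-4)
}

# Classed infeasibility condition carrying the offending populations.
stop_infeasible <- function(msg, offending, pairs = NULL) {
  cond <- structure(class = c("gduplan_infeasible", "error", "condition"),
                    list(message = msg, call = sys.call(-1),
                         offending = offending, pairs = pairs))
  stop(cond)
}
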