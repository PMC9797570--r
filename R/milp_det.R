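# ---- single-scenario MILP builders ------------------------------------
#
# Variable layout shared by both deterministic models:
#   t_p[i,j]  planting binaries, only for weeks inside population i's window
#             (the zero-outside-window constraint is enforced structurally)
#   t_h[i,j]  harvest binaries over all T weeks (optionally sparsified to
#             weeks reachable from some window week)
#   w[j]      week-used binaries
# Case 1 adds e_plus/e_minus deviation variables and the capacity-deviation
# balance; case 2 adds the continuous peak variable z with z >= A_j.

# Check maturity feasibility under one scenario before building; signals a
# gduplan_infeasible condition naming the offending populations.
.check_scenario_feasible <- function(instance, k) {
  p <- instance$populations
  hl <- instance$hlook[[k]]
  bad <- integer()
  for (i in seq_len(instance$N)) {
    win <- p$early_week[i]:p$late_week[i]
    if (all(is.na(hl[i, win]))) bad <- c(bad, p$id[i])
  }
  if (length(bad))
    stop_infeasible(paste0(
      "instance infeasible under scenario '", colnames(instance$gdu)[k],
      "': population(s) ", paste(bad, collapse = ", "),
      " cannot reach their required GDU from any window week"), bad)
  invisible(TRUE)
}

# Common core: planting/harvest binaries plus constraint groups (6)-(10).
.det_core <- function(m, instance, k, sparsify_harvest) {
  p <- instance$populations
  T_ <- instance$T; N <- instance$N
  cum <- instance$cum[, k]
  gduw <- cum[-1]  # GDU_j, j = 1..T
  tp <- vector("list", N); th <- vector("list", N)
  th_weeks <- vector("list", N)
  for (i in seq_len(N)) {
    win <- p$early_week[i]:p$late_week[i]
    tp[[i]] <- milp_add_vars(m, sprintf("t_p[%d,%d]", p$id[i], win),
                             "binary", "t_p")
    names(tp[[i]]) <- win
    hw <- if (sparsify_harvest) {
      r <- unique(instance$hlook[[k]][i, win])
      sort(r[!is.na(r)])
    } else seq_len(T_)
    th_weeks[[i]] <- hw
    th[[i]] <- milp_add_vars(m, sprintf("t_h[%d,%d]", p$id[i], hw),
                             "binary", "t_h")
    names(th[[i]]) <- hw
  }
  for (i in seq_len(N)) {
    win <- p$early_week[i]:p$late_week[i]
    hw <- th_weeks[[i]]
    g <- p$required_gdu[i]
    milp_add_row(m, tp[[i]], rep(1, length(win)), 1, 1, "one_planting(6)")
    milp_add_row(m, th[[i]], rep(1, length(hw)), 1, 1, "one_harvest(8)")
    # (9): sum_j t_h GDU_j - sum_j t_p GDU_j >= G_min
    milp_add_row(m, c(th[[i]], tp[[i]]), c(gduw[hw], -gduw[win]),
                 g, Inf, "gdu_reach(9)")
    # (10): sum_j t_h GDU_{j-1} - sum_j t_p GDU_j <= G_min - eps
    milp_add_row(m, c(th[[i]], tp[[i]]), c(cum[hw], -gduw[win]),
                 -Inf, g - gdu_epsilon(g), "gdu_earliest(10)")
  }
  w <- milp_add_vars(m, sprintf("w[%d]", seq_len(T_)), "binary", "w")
  for (j in seq_len(T_)) {
    hs <- unlist(lapply(th, function(v) v[names(v) == j]))
    # (11): N w_j >= sum_i t_h[i,j]
    if (length(hs))
      milp_add_row(m, c(w[j], hs), c(N, rep(-1, length(hs))), 0, Inf,
                   "week_link(11)")
  }
  list(tp = tp, th = th, w = w, th_weeks = th_weeks)
}

#' Build the deterministic case 1 MILP (fixed capacity)
#'
#' Linearized absolute-deviation model: minimize
#' \eqn{\sum_j (e_j^+ + e_j^-)} subject to one planting week inside each
#' window, one harvest week, the earliest-harvest constraint pair on
#' cumulative GDU, week-used linking, and the deviation balance
#' \eqn{w_j C - \sum_i HQ_i t^h_{ij} = e_j^+ - e_j^-}.
#'
#' @param instance a [gdu_instance()] with a capacity
#' @param scenario scenario column index or label (exactly one)
#' @param sparsify_harvest restrict harvest binaries to weeks reachable
#'   from some window week (smaller model, same optimum); default FALSE
#'   keeps the dense \code{N x T} harvest block
#' @return a \code{milp_model}; \code{meta} carries the variable maps used
#'   for extraction
#' @export
build_case1 <- function(instance, scenario = 1, sparsify_harvest = FALSE) {
  k <- .scenario_index(instance, scenario)
  if (is.na(instance$capacity))
    stop("build_case1: instance has no capacity (case 1 needs C)")
  .check_scenario_feasible(instance, k)
  m <- milp_new("case1_det")
  core <- .det_core(m, instance, k, sparsify_harvest)
  T_ <- instance$T
  hq <- active_hq(instance)
  ep <- milp_add_vars(m, sprintf("e_plus[%d]", seq_len(T_)), "continuous", "e_plus")
  en <- milp_add_vars(m, sprintf("e_minus[%d]", seq_len(T_)), "continuous", "e_minus")
  for (j in seq_len(T_)) {
    hs <- integer(); hc <- numeric()
    for (i in seq_len(instance$N)) {
      v <- core$th[[i]][names(core$th[[i]]) == j]
      if (length(v)) { hs <- c(hs, v); hc <- c(hc, -hq[i]) }
    }
    # (14): C w_j - sum HQ_i t_h[i,j] - e_plus + e_minus = 0
    milp_add_row(m, c(core$w[j], hs, ep[j], en[j]),
                 c(instance$capacity, hc, -1, 1), 0, 0, "deviation(14)")
  }
  milp_set_objective(m, c(ep, en), rep(1, 2 * T_))
  milp_finalize(m, meta = list(instance_dims = c(N = instance$N, K = 1L,
                                                 T = T_),
                               scenario = k, tp = core$tp, th = core$th,
                               w = core$w, ep = ep, en = en,
                               objective = "case1_det"))
}

#' Build the deterministic case 2 MILP (capacity sizing)
#'
#' Minimax model: minimize \eqn{z + \theta_w \sum_j w_j} with
#' \eqn{z \ge \sum_i HQ_i t^h_{ij}} for every week, over the same planting
#' window, one-harvest and earliest-harvest constraints as case 1. The
#' optimal \eqn{z} is the lowest storage capacity the site requires.
#'
#' @inheritParams build_case1
#' @export
build_case2 <- function(instance, scenario = 1, sparsify_harvest = FALSE) {
  k <- .scenario_index(instance, scenario)
  .check_scenario_feasible(instance, k)
  m <- milp_new("case2_det")
  core <- .det_core(m, instance, k, sparsify_harvest)
  T_ <- instance$T
  hq <- active_hq(instance)
  z <- milp_add_vars(m, "z", "continuous", "z")
  for (j in seq_len(T_)) {
    hs <- integer(); hc <- numeric()
    for (i in seq_len(instance$N)) {
      v <- core$th[[i]][names(core$th[[i]]) == j]
      if (length(v)) { hs <- c(hs, v); hc <- c(hc, -hq[i]) }
    }
    # (31): z - sum HQ_i t_h[i,j] >= 0
    milp_add_row(m, c(z, hs), c(1, hc), 0, Inf, "peak(31)")
  }
  milp_set_objective(m, c(z, core$w),
                     c(1, rep(instance$theta_w, T_)))
  milp_finalize(m, meta = list(instance_dims = c(N = instance$N, K = 1L,
                                                 T = T_),
                               scenario = k, tp = core$tp, th = core$th,
                               w = core$w, z = z, objective = "case2_det"))
}

.scenario_index <- function(instance, scenario) {
  if (is.character(scenario)) {
    k <- match(scenario, colnames(instance$gdu))
    if (is.na(k)) stop("unknown scenario label '", scenario, "'")
  } else k <- as.integer(scenario)
  if (k < 1 || k > instance$K) stop("scenario index out of range")
  k
}
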