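# ---- multi-scenario stochastic MILP (case 1) --------------------------
#
# One shared set of planting binaries; per-scenario harvest binaries and
# earliest-harvest constraints on each scenario's cumulative GDU; the weekly
# max envelope A_max[j] = max_k A_jk linearized exactly with per-(week,
# scenario) argmax-selection binaries y[j,k] and a big-M bound; capacity
# deviation |C - A_max[j]| linearized with d_plus/d_minus, charged on active
# weeks by default (literal all-weeks variant behind `all_weeks`).

#' Build the exact multi-scenario stochastic MILP for case 1
#'
#' Minimizes \eqn{\sum_j |C - A_j^{max}|} over a single planting schedule
#' shared by all K GDU scenarios, where \eqn{A_j^{max} = \max_k A_{jk}} is
#' the weekly max envelope of the per-scenario harvest quantities. The
#' envelope is linearized exactly: \eqn{A^{max}_j \ge A_{jk}} for all k plus
#' a selection binary row forcing equality with some scenario, so the model
#' cannot inflate the envelope toward the capacity. The per-scenario
#' earliest-harvest rule uses the same inequality pair as the deterministic
#' model (the literal per-scenario equality on accumulated GDU is
#' unsatisfiable for real-valued heat units).
#'
#' @param instance a [gdu_instance()] with a capacity (K >= 1 scenarios)
#' @param all_weeks charge \eqn{|C - A^{max}_j|} on every week of the
#'   horizon instead of active weeks only
#' @param audit_dense build the dense census layout (planting and harvest
#'   binaries over all \code{N x T} and \code{N x K x T} index tuples, as
#'   the printed variable-count formula assumes) instead of the sparsified
#'   production layout
#' @return a \code{milp_model} of kind \code{"case1_stoch"}
#' @export
build_stochastic_case1 <- function(instance, all_weeks = FALSE,
                                   audit_dense = FALSE) {
  if (is.na(instance$capacity))
    stop("build_stochastic_case1: instance has no capacity")
  p <- instance$populations
  T_ <- instance$T; N <- instance$N; K <- instance$K
  # maturity feasibility under every scenario, reported as pairs
  rep_ <- feasibility_report(instance)
  if (!attr(rep_, "instance_feasible")) {
    pairs <- rep_[!rep_$feasible, c("id", "scenario")]
    stop_infeasible(paste0(
      "stochastic model infeasible: ", nrow(pairs),
      " (population, scenario) pair(s) cannot reach the required GDU; ",
      "population(s) ", paste(attr(rep_, "offending"), collapse = ", ")),
      attr(rep_, "offending"), pairs = pairs)
  }
  hq <- active_hq(instance)
  bigM <- sum(hq)
  m <- milp_new("case1_stoch")

  tp <- vector("list", N)
  for (i in seq_len(N)) {
    win <- if (audit_dense) seq_len(T_) else p$early_week[i]:p$late_week[i]
    tp[[i]] <- milp_add_vars(m, sprintf("t_p[%d,%d]", p$id[i], win),
                             "binary", "t_p")
    names(tp[[i]]) <- win
  }
  th <- vector("list", K)
  for (k in seq_len(K)) {
    th[[k]] <- vector("list", N)
    for (i in seq_len(N)) {
      hw <- if (audit_dense) seq_len(T_) else {
        win <- p$early_week[i]:p$late_week[i]
        r <- unique(instance$hlook[[k]][i, win])
        sort(r[!is.na(r)])
      }
      th[[k]][[i]] <- milp_add_vars(
        m, sprintf("t_h[%d,%d,k%d]", p$id[i], hw, k), "binary", "t_hk")
      names(th[[k]][[i]]) <- hw
    }
  }
  y <- matrix(milp_add_vars(m, sprintf("y[%s]", outer(seq_len(T_), seq_len(K),
                                                      paste, sep = ",k")),
                            "binary", "y_sel"), T_, K)
  amax <- milp_add_vars(m, sprintf("A_max[%d]", seq_len(T_)), "continuous",
                        "A_max")

  for (i in seq_len(N)) {
    win <- p$early_week[i]:p$late_week[i]
    inwin <- names(tp[[i]]) %in% as.character(win)
    # (22): plant once inside the window
    milp_add_row(m, tp[[i]][inwin], rep(1, sum(inwin)), 1, 1,
                 "one_planting(22)")
    # (23): nothing outside (rows exist only in the dense layout)
    if (any(!inwin))
      milp_add_row(m, tp[[i]][!inwin], rep(1, sum(!inwin)), 0, 0,
                   "window_zero(23)")
  }
  for (k in seq_len(K)) {
    cum <- instance$cum[, k]
    gduw <- cum[-1]
    for (i in seq_len(N)) {
      win <- p$early_week[i]:p$late_week[i]
      hw <- as.integer(names(th[[k]][[i]]))
      g <- p$required_gdu[i]
      tpw <- as.integer(names(tp[[i]]))
      milp_add_row(m, th[[k]][[i]], rep(1, length(hw)), 1, 1,
                   "one_harvest(24)")
      milp_add_row(m, c(th[[k]][[i]], tp[[i]]), c(gduw[hw], -gduw[tpw]),
                   g, Inf, "gdu_reach(25a)")
      milp_add_row(m, c(th[[k]][[i]], tp[[i]]), c(cum[hw], -gduw[tpw]),
                   -Inf, g - gdu_epsilon(g), "gdu_earliest(25b)")
    }
  }
  # envelope rows: A_max[j] >= A_jk and A_max[j] <= A_jk + M (1 - y[j,k])
  th_by_week <- lapply(seq_len(K), function(k) {
    byw <- vector("list", T_)
    for (i in seq_len(N)) {
      hw <- as.integer(names(th[[k]][[i]]))
      for (s in seq_along(hw))
        byw[[hw[s]]] <- c(byw[[hw[s]]], stats::setNames(th[[k]][[i]][s], i))
    }
    byw
  })
  for (j in seq_len(T_)) {
    for (k in seq_len(K)) {
      hs <- th_by_week[[k]][[j]]
      hc <- if (length(hs)) -hq[as.integer(names(hs))] else numeric()
      milp_add_row(m, c(amax[j], hs), c(1, hc), 0, Inf, "envelope_ge(21)")
      milp_add_row(m, c(amax[j], hs, y[j, k]), c(1, hc, bigM),
                   -Inf, bigM, "envelope_sel(21)")
    }
    milp_add_row(m, y[j, ], rep(1, K), 1, 1, "envelope_pick(21)")
  }
  dp <- milp_add_vars(m, sprintf("d_plus[%d]", seq_len(T_)), "continuous",
                      "d_plus")
  dn <- milp_add_vars(m, sprintf("d_minus[%d]", seq_len(T_)), "continuous",
                      "d_minus")
  if (all_weeks) {
    W <- NULL
    for (j in seq_len(T_))
      milp_add_row(m, c(amax[j], dp[j], dn[j]), c(-1, -1, 1),
                   -instance$capacity, -instance$capacity, "deviation(19)")
  } else {
    W <- milp_add_vars(m, sprintf("W[%d]", seq_len(T_)), "binary", "W")
    for (j in seq_len(T_)) {
      hs <- unlist(lapply(th_by_week, function(byw) byw[[j]]))
      if (length(hs))
        milp_add_row(m, c(W[j], hs), c(N * K, rep(-1, length(hs))), 0, Inf,
                     "week_link(11)")
      milp_add_row(m, c(W[j], amax[j], dp[j], dn[j]),
                   c(instance$capacity, -1, -1, 1), 0, 0, "deviation(19)")
    }
  }
  milp_set_objective(m, c(dp, dn), rep(1, 2 * T_))
  milp_finalize(m, meta = list(
    instance_dims = c(N = N, K = K, T = T_),
    tp = tp, th = th, y = y, amax = amax, dp = dp, dn = dn, W = W,
    all_weeks = all_weeks, audit_dense = audit_dense,
    objective = "case1_stoch"))
}

#' Census of the core decision variables of a stochastic model
#'
#' Counts the variables of the four groups the model-size formula
#' \eqn{N K T + N T + K T + T} describes: per-scenario harvest binaries,
#' planting binaries, per-scenario weekly indicators, and the weekly max
#' envelope. The deviation auxiliaries introduced by the absolute-value
#' linearization are not part of that census (they belong to the linear
#' reformulation, not the model being counted). On a model built with
#' \code{audit_dense = TRUE} the census equals the formula exactly.
#'
#' @param model a model from [build_stochastic_case1()]
#' @return integer variable count
#' @export
audit_variable_count <- function(model) {
  if (!inherits(model, "milp_model") || model$kind != "case1_stoch")
    stop("audit_variable_count: expects a stochastic case 1 model")
  sum(model$vars$group %in% c("t_hk", "t_p", "y_sel", "A_max"))
}

#' Enumerate the dense stochastic variable census without building a model
#'
#' Materializes the four dense index sets of the stochastic formulation —
#' (population, week, scenario) harvest binaries, (population, week)
#' planting binaries, (week, scenario) per-scenario weekly indicators and
#' the per-week envelope — and counts them. Equivalent to
#' [audit_variable_count()] on a dense-built model, but usable at full
#' problem scale where materializing constraints would be pointless.
#'
#' @param N,K,T problem dimensions (populations, scenarios, weeks)
#' @return total variable count with a per-group breakdown in the
#'   \code{"groups"} attribute
#' @export
stochastic_variable_census <- function(N, K, T) {
  stopifnot(N >= 1, K >= 1, T >= 1)
  groups <- c(
    t_hk = nrow(expand.grid(i = seq_len(N), j = seq_len(T), k = seq_len(K))),
    t_p = nrow(expand.grid(i = seq_len(N), j = seq_len(T))),
    y_sel = nrow(expand.grid(j = seq_len(T), k = seq_len(K))),
    A_max = length(seq_len(T)))
  structure(sum(groups), groups = groups)
}
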