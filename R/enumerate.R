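#' Exhaustive enumeration of planting schedules
#'
#' Brute-force oracle for tiny instances: walks the Cartesian product of
#' every population's planting-window weeks, evaluates the requested
#' objective through the GDU engine, and returns the global optimum.
#' Assignments that leave any (population, scenario) pair unreached are
#' skipped as infeasible (the exact models require every population to be
#' harvested). Independent of the MILP and SA code paths by construction —
#' it only touches [evaluate_profile()] and the objective evaluators.
#'
#' @param instance a [gdu_instance()]
#' @param objective objective name, as in [schedule_objective()]
#' @param all_weeks passed through for \code{"case1_stoch"}
#' @param max_assignments guard against accidental combinatorial blow-up
#' @return list with \code{objective} (minimum value), \code{schedule}
#'   (an argmin), \code{n_evaluated}, \code{n_feasible}
#' @export
enumerate_optimum <- function(instance,
                              objective = c("case1_det", "case1_stoch",
                                            "case2_det", "case2_stoch"),
                              all_weeks = FALSE, max_assignments = 2e5) {
  objective <- match.arg(objective)
  p <- instance$populations
  if (objective %in% c("case1_det", "case2_det") && instance$K != 1L)
    stop("deterministic enumeration needs a single-scenario instance")
  windows <- lapply(seq_len(instance$N),
                    function(i) p$early_week[i]:p$late_week[i])
  n_total <- prod(vapply(windows, length, numeric(1)))
  if (n_total > max_assignments)
    stop("enumeration space has ", format(n_total),
         " assignments (> max_assignments)")
  hq <- active_hq(instance)
  best <- Inf; best_s <- NULL; n_feas <- 0L
  counter <- rep(1L, instance$N)
  lens <- vapply(windows, length, integer(1))
  idx <- cbind(seq_len(instance$N), 0L)
  repeat {
    s <- vapply(seq_len(instance$N), function(i) windows[[i]][counter[i]],
                integer(1))
    idx[, 2] <- s
    A <- matrix(0, instance$T, instance$K)
    feasible <- TRUE
    for (k in seq_len(instance$K)) {
      h <- instance$hlook[[k]][idx]
      if (anyNA(h)) { feasible <- FALSE; break }
      for (i in seq_len(instance$N)) A[h[i], k] <- A[h[i], k] + hq[i]
    }
    if (feasible) {
      n_feas <- n_feas + 1L
      Am <- if (instance$K == 1L) A[, 1] else apply(A, 1, max)
      val <- switch(objective,
        case1_det = sum(abs((Am > 0) * instance$capacity - Am)),
        case1_stoch = if (all_weeks) sum(abs(instance$capacity - Am))
                      else sum(abs(instance$capacity - Am[Am > 0])),
        case2_det = if (all(Am == 0)) 0
                    else max(Am) + instance$theta_w * sum(Am > 0),
        case2_stoch = { v <- Am[Am > 0]
                        if (length(v) < 2) 0 else sum(abs(diff(v))) })
      if (val < best) { best <- val; best_s <- s }
    }
    # advance the mixed-radix counter
    i <- 1L
    while (i <= instance$N) {
      counter[i] <- counter[i] + 1L
      if (counter[i] <= lens[i]) break
      counter[i] <- 1L; i <- i + 1L
    }
    if (i > instance$N) break
  }
  list(objective = if (is.finite(best)) best else NA_real_,
       schedule = if (!is.null(best_s))
         stats::setNames(best_s, as.character(p$id)) else NULL,
       n_evaluated = as.integer(n_total), n_feasible = n_feas)
}
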