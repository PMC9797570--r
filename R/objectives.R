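#' Weekly harvest profile of a planting schedule
#'
#' Derives, for every GDU scenario, the harvest week of each population
#' under the earliest-harvest rule and accumulates the weekly harvest
#' quantities \eqn{A_{jk} = \sum_i HQ_i [h_{ik} = j]} and their max
#' envelope \eqn{A_j^{max} = \max_k A_{jk}}. Populations that never reach
#' their required GDU under some scenario are reported in the
#' \code{unreached} component, never silently dropped (their quantity is
#' simply absent from that scenario's column).
#'
#' @param schedule planting weeks (validated against the windows)
#' @param instance a [gdu_instance()]
#' @return an object of class \code{harvest_profile}: list with \code{A}
#'   (T x K matrix, ears), \code{A_max} (length-T vector),
#'   \code{harvest_week} (N x K integer matrix, NA = unreached),
#'   \code{unreached} (data.frame id/scenario), \code{hq} (active HQ)
#' @export
evaluate_profile <- function(schedule, instance) {
  s <- validate_schedule(schedule, instance)
  hq <- active_hq(instance)
  T_ <- instance$T; K <- instance$K; N <- instance$N
  A <- matrix(0, T_, K, dimnames = list(NULL, colnames(instance$gdu)))
  H <- matrix(NA_integer_, N, K,
              dimnames = list(as.character(instance$populations$id),
                              colnames(instance$gdu)))
  idx <- cbind(seq_len(N), s)
  for (k in seq_len(K)) {
    h <- instance$hlook[[k]][idx]
    H[, k] <- h
    ok <- !is.na(h)
    if (any(ok)) {
      sums <- rowsum(hq[ok], h[ok])
      A[as.integer(rownames(sums)), k] <- sums
    }
  }
  un <- which(is.na(H), arr.ind = TRUE)
  unreached <- data.frame(
    id = instance$populations$id[un[, 1]],
    scenario = colnames(instance$gdu)[un[, 2]])
  structure(list(A = A, A_max = apply(A, 1, max), harvest_week = H,
                 unreached = unreached, hq = hq, schedule = s),
            class = "harvest_profile")
}

#' @export
print.harvest_profile <- function(x, ...) {
  act <- sum(x$A_max > 0)
  cat(sprintf("<harvest_profile: %d week(s) x %d scenario(s), %d active week(s), peak %.0f ears>\n",
              nrow(x$A), ncol(x$A), act, max(x$A_max)))
  if (nrow(x$unreached))
    cat("  unreached (population, scenario) pairs:", nrow(x$unreached), "\n")
  invisible(x)
}

#' Deterministic case 1 objective: total deviation from capacity
#'
#' \eqn{\sum_j |w_j C - A_j|} over the single scenario, where \eqn{w_j = 1}
#' exactly on harvesting weeks. Equals the optimal
#' \eqn{\sum_j (e_j^+ + e_j^-)} of the linearized absolute-value model at
#' the same schedule.
#'
#' @param profile a single-scenario [evaluate_profile()] result
#' @param capacity storage capacity C, ears
#' @return total absolute deviation, ears
#' @export
objective_case1_det <- function(profile, capacity) {
  A <- .profile_single(profile)
  sum(abs((A > 0) * capacity - A))
}

#' Stochastic case 1 objective: envelope deviation from capacity
#'
#' \eqn{\sum_j |C - A_j^{max}|}. By default the sum runs over active weeks
#' only (weeks where some scenario harvests something); the literal
#' all-weeks reading, which charges C for every empty week of the horizon,
#' is available via \code{all_weeks = TRUE}.
#'
#' @param profile an [evaluate_profile()] result (any K >= 1)
#' @param capacity storage capacity C, ears
#' @param all_weeks sum over all T weeks instead of active weeks
#' @export
objective_case1_stoch <- function(profile, capacity, all_weeks = FALSE) {
  Am <- profile$A_max
  if (!all_weeks) Am <- Am[Am > 0]
  sum(abs(capacity - Am))
}

#' Deterministic case 2 objective: minimax capacity plus week penalty
#'
#' \eqn{\max_j A_j + \theta_w \cdot \#\{j : A_j > 0\}} over the single
#' scenario; the max term is the lowest storage capacity the schedule
#' requires.
#'
#' @param profile a single-scenario [evaluate_profile()] result
#' @param theta_w penalty per harvesting week
#' @export
objective_case2_det <- function(profile, theta_w = 1) {
  A <- .profile_single(profile)
  if (all(A == 0)) return(0)
  max(A) + theta_w * sum(A > 0)
}

#' Stochastic case 2 objective: total variation of the max envelope
#'
#' Sum of absolute differences between consecutive active values of the max
#' envelope: with active weeks \eqn{j_1 < \dots < j_m},
#' \eqn{\sum_{r=1}^{m-1} |A^{max}_{j_r} - A^{max}_{j_{r+1}}|}. Zero iff the
#' envelope is constant over its active span — perfectly consistent weekly
#' harvest quantities.
#'
#' @param profile an [evaluate_profile()] result
#' @export
objective_case2_stoch <- function(profile) {
  v <- profile$A_max[profile$A_max > 0]
  if (length(v) < 2) return(0)
  sum(abs(diff(v)))
}

# Single-scenario weekly quantities, or error.
.profile_single <- function(profile) {
  if (ncol(profile$A) != 1L)
    stop("this objective is defined for single-scenario profiles (K = 1)")
  profile$A[, 1]
}

#' Evaluate a schedule under a named objective
#'
#' Convenience wrapper: profile + objective in one call. Used as the single
#' source of truth when cross-checking solver outputs.
#'
#' @param schedule planting weeks
#' @param instance a [gdu_instance()]
#' @param objective one of \code{"case1_det"}, \code{"case1_stoch"},
#'   \code{"case2_det"}, \code{"case2_stoch"}
#' @param all_weeks passed to [objective_case1_stoch()]
#' @param require_mature error if any (population, scenario) is unreached
#' @return the objective value
#' @export
schedule_objective <- function(schedule, instance,
                               objective = c("case1_det", "case1_stoch",
                                             "case2_det", "case2_stoch"),
                               all_weeks = FALSE, require_mature = TRUE) {
  objective <- match.arg(objective)
  prof <- evaluate_profile(schedule, instance)
  if (require_mature && nrow(prof$unreached))
    stop("schedule leaves ", nrow(prof$unreached),
         " (population, scenario) pair(s) unreached")
  switch(objective,
         case1_det = objective_case1_det(prof, instance$capacity),
         case1_stoch = objective_case1_stoch(prof, instance$capacity,
                                             all_weeks = all_weeks),
         case2_det = objective_case2_det(prof, instance$theta_w),
         case2_stoch = objective_case2_stoch(prof))
}
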