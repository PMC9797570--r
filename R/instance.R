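#' Validate a population table
#'
#' A population table describes the corn seed populations of one site:
#' one row per population with its planting window (1-based week indices),
#' required GDU to maturity and harvest quantities (ears) for the two
#' storage-capacity cases.
#'
#' @param populations data.frame with columns \code{id}, \code{early_week},
#'   \code{late_week}, \code{required_gdu}, \code{hq_case1}, \code{hq_case2}
#' @param horizon horizon T the windows must fit in
#' @return the validated data.frame (ids coerced to integer, invisibly the
#'   same object)
#' @export
validate_populations <- function(populations, horizon) {
  req <- c("id", "early_week", "late_week", "required_gdu",
           "hq_case1", "hq_case2")
  miss <- setdiff(req, names(populations))
  if (length(miss))
    stop("population table: missing column(s) ", paste(miss, collapse = ", "))
  populations <- populations[, req]
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop("population table row(s) ", paste(rows, collapse = ", "), ": ", what)
  }
  bad(duplicated(populations$id), "duplicate id")
  bad(!is.finite(populations$early_week) | populations$early_week < 1,
      "early_week must be >= 1")
  bad(!is.finite(populations$late_week) |
        populations$late_week > horizon, "late_week must be <= T")
  bad(populations$early_week > populations$late_week,
      "early_week must be <= late_week")
  bad(!is.finite(populations$required_gdu) | populations$required_gdu <= 0,
      "required_gdu must be > 0")
  bad(!is.finite(populations$hq_case1) | populations$hq_case1 < 0,
      "hq_case1 must be >= 0")
  bad(!is.finite(populations$hq_case2) | populations$hq_case2 < 0,
      "hq_case2 must be >= 0")
  populations$id <- as.integer(populations$id)
  populations$early_week <- as.integer(populations$early_week)
  populations$late_week <- as.integer(populations$late_week)
  populations
}

#' Assemble a scheduling instance
#'
#' Bundles one site's population table with its weekly GDU scenarios and
#' capacity configuration, and precomputes the cumulative-GDU and
#' harvest-week lookup tables used by every solver.
#'
#' @param populations population table (see [validate_populations()])
#' @param scenarios a list of [gdu_scenario()] objects, or a numeric matrix
#'   with T rows and one column per scenario (column names become labels)
#' @param capacity storage capacity C in ears (case 1); \code{NA} for
#'   capacity-sizing (case 2) instances
#' @param theta_w penalty per harvesting week in the case 2 objective
#'   (default 1)
#' @param hq_case which harvest-quantity column is active, 1 or 2
#' @param horizon horizon T in weeks; defaults to the scenario length
#' @return an object of class \code{gdu_instance}: a list with the validated
#'   inputs plus \code{gdu} (T x K matrix), \code{cum} ((T+1) x K), and
#'   \code{hlook} (list of K integer N x T matrices; entry \code{[i, p]} is
#'   the harvest week of population i when planted in week p, \code{NA} when
#'   unreached within the horizon)
#' @export
gdu_instance <- function(populations, scenarios, capacity = NA,
                         theta_w = 1, hq_case = 1, horizon = NULL) {
  if (is.matrix(scenarios)) {
    labs <- colnames(scenarios)
    if (is.null(labs)) labs <- paste0("s", seq_len(ncol(scenarios)))
    scenarios <- lapply(seq_len(ncol(scenarios)),
                        function(k) gdu_scenario(scenarios[, k], labs[k]))
  }
  if (!length(scenarios)) stop("gdu_instance: at least one scenario required")
  lens <- vapply(scenarios, function(s) length(s$weekly), integer(1))
  if (length(unique(lens)) != 1L)
    stop("gdu_instance: scenarios have differing lengths")
  T_ <- if (is.null(horizon)) lens[1] else as.integer(horizon)
  if (T_ != lens[1])
    stop("gdu_instance: scenario length ", lens[1], " != horizon ", T_)
  if (!is.na(capacity) && capacity <= 0)
    stop("gdu_instance: capacity must be > 0 when given")
  if (theta_w < 0) stop("gdu_instance: theta_w must be >= 0")
  if (!hq_case %in% c(1, 2)) stop("gdu_instance: hq_case must be 1 or 2")
  populations <- validate_populations(populations, T_)

  gdu <- vapply(scenarios, function(s) s$weekly, numeric(T_))
  gdu <- matrix(gdu, nrow = T_)
  colnames(gdu) <- unname(vapply(scenarios, function(s) s$label,
                                 character(1)))
  cum <- apply(gdu, 2, function(w) c(0, cumsum(w)))
  N <- nrow(populations)
  hlook <- lapply(seq_len(ncol(gdu)), function(k) {
    m <- matrix(NA_integer_, nrow = N, ncol = T_)
    for (i in seq_len(N))
      m[i, ] <- harvest_lookup_row(populations$required_gdu[i], cum[, k])
    m
  })
  names(hlook) <- colnames(gdu)
  structure(list(populations = populations, gdu = gdu, cum = cum,
                 hlook = hlook, capacity = capacity, theta_w = theta_w,
                 hq_case = as.integer(hq_case), T = T_,
                 K = ncol(gdu), N = N),
            class = "gdu_instance")
}

#' @export
print.gdu_instance <- function(x, ...) {
  cat(sprintf(
    "<gdu_instance: N=%d populations, K=%d scenario(s), T=%d weeks, %s, hq_case=%d>\n",
    x$N, x$K, x$T,
    if (is.na(x$capacity)) "capacity: to size (case 2)"
    else sprintf("capacity C=%g ears", x$capacity),
    x$hq_case))
  invisible(x)
}

#' Active harvest quantities of an instance
#'
#' @param instance a [gdu_instance()]
#' @return the HQ column selected by \code{hq_case}, in ears
#' @export
active_hq <- function(instance) {
  if (instance$hq_case == 1L) instance$populations$hq_case1
  else instance$populations$hq_case2
}

#' Check a planting schedule against the planting windows
#'
#' @param schedule integer vector of planting weeks, one per population in
#'   table order (names, if present, must match the population ids)
#' @param instance a [gdu_instance()]
#' @return the schedule as a named integer vector (names = population ids)
#' @export
validate_schedule <- function(schedule, instance) {
  p <- instance$populations
  if (length(schedule) != instance$N)
    stop("schedule: expected ", instance$N, " planting weeks, got ",
         length(schedule))
  s <- as.integer(schedule)
  if (!is.null(names(schedule))) {
    if (!identical(names(schedule), as.character(p$id)))
      stop("schedule: names do not match population ids in table order")
  }
  bad <- which(s < p$early_week | s > p$late_week | is.na(s))
  if (length(bad))
    stop("schedule: population(s) ", paste(p$id[bad], collapse = ", "),
         " planted outside their window")
  names(s) <- as.character(p$id)
  s
}

# Feasible planting weeks per population: inside the window and maturing
# within the horizon under every scenario. Returns an N x T logical matrix.
feasible_plant_weeks <- function(instance) {
  p <- instance$populations
  ok <- matrix(FALSE, instance$N, instance$T)
  for (i in seq_len(instance$N))
    ok[i, p$early_week[i]:p$late_week[i]] <- TRUE
  for (k in seq_len(instance$K))
    ok <- ok & !is.na(instance$hlook[[k]])
  ok
}

#' Per-(population, scenario) maturity feasibility report
#'
#' For each population and scenario, reports whether at least one week of
#' the planting window lets the population accumulate its required GDU
#' within the horizon. An instance is infeasible for the stochastic models
#' (and for any deterministic model on an affected scenario) when some
#' population has no feasible planting week under some scenario — the
#' situation a cold site exhibits when its heat supply cannot mature every
#' population in T weeks.
#'
#' @param instance a [gdu_instance()]
#' @return a data.frame with columns \code{id}, \code{scenario},
#'   \code{feasible}, \code{latest_feasible_plant_week} (NA when none);
#'   attributes \code{instance_feasible} (logical) and \code{offending}
#'   (sorted ids of populations infeasible under at least one scenario)
#' @export
feasibility_report <- function(instance) {
  p <- instance$populations
  rows <- vector("list", instance$K)
  for (k in seq_len(instance$K)) {
    hl <- instance$hlook[[k]]
    feas <- logical(instance$N)
    last <- rep(NA_integer_, instance$N)
    for (i in seq_len(instance$N)) {
      win <- p$early_week[i]:p$late_week[i]
      okw <- win[!is.na(hl[i, win])]
      feas[i] <- length(okw) > 0
      if (feas[i]) last[i] <- max(okw)
    }
    rows[[k]] <- data.frame(id = p$id,
                            scenario = colnames(instance$gdu)[k],
                            feasible = feas,
                            latest_feasible_plant_week = last)
  }
  rep_ <- do.call(rbind, rows)
  offending <- sort(unique(rep_$id[!rep_$feasible]))
  structure(rep_,
            instance_feasible = length(offending) == 0L,
            offending = offending)
}

#' Decision-variable count of the dense stochastic MILP
#'
#' Closed-form census of the multi-scenario formulation built dense: one
#' per-scenario harvest binary per (population, week, scenario), one
#' planting binary per (population, week), one per-scenario weekly
#' indicator per (scenario, week), and one max-envelope variable per week:
#' \eqn{N K T + N T + K T + T}.
#'
#' @param N number of populations
#' @param K number of GDU scenarios
#' @param T number of weeks in the horizon
#' @return the variable count
#' @export
count_stochastic_milp_variables <- function(N, K, T) {
  stopifnot(N >= 1, K >= 1, T >= 1,
            N == as.integer(N), K == as.integer(K), T == as.integer(T))
  N * K * T + N * T + K * T + T
}
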