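# ---- simulated annealing for the stochastic scheduling problem --------

#' Simulated annealing configuration
#'
#' Defaults follow the reference parameterization of the heuristic:
#' initial temperature 30,000, geometric decay 0.995 per iteration, 700
#' iterations, three populations moved at the peak week per step, planting
#' shifts of one or two weeks.
#'
#' @param T0 initial temperature (energy units)
#' @param alpha geometric decay rate per iteration, in \code{[0, 1]}
#' @param k_max iteration cap
#' @param moves_per_max_week populations shifted away from the tallest week
#'   per move
#' @param shift_range admissible planting shifts (absolute weeks)
#' @param objective energy: \code{"case1_stoch"} (envelope deviation from
#'   capacity) or \code{"case2_stoch"} (envelope total variation)
#' @param acceptance \code{"metropolis"} (standard; worse moves accepted
#'   with probability \code{exp(-dE/T)}) or \code{"literal"} (the
#'   sign-flipped exponent of the published pseudo-code, kept for
#'   comparison)
#' @param all_weeks passed to [objective_case1_stoch()]
#' @param seed RNG seed; \code{NULL} leaves the RNG state alone
#' @export
sa_config <- function(T0 = 30000, alpha = 0.995, k_max = 700,
                      moves_per_max_week = 3, shift_range = c(1L, 2L),
                      objective = c("case1_stoch", "case2_stoch"),
                      acceptance = c("metropolis", "literal"),
                      all_weeks = FALSE, seed = NULL) {
  objective <- match.arg(objective)
  acceptance <- match.arg(acceptance)
  stopifnot(T0 > 0, alpha >= 0, alpha <= 1, k_max >= 0,
            moves_per_max_week >= 0, all(shift_range >= 1))
  structure(list(T0 = T0, alpha = alpha, k_max = as.integer(k_max),
                 moves_per_max_week = as.integer(moves_per_max_week),
                 shift_range = as.integer(shift_range),
                 objective = objective, acceptance = acceptance,
                 all_weeks = all_weeks, seed = seed),
            class = "sa_config")
}

#' Annealing temperature schedule
#'
#' Geometric cooling \eqn{T_0 \alpha^k}.
#'
#' @param k iteration (0-based; k = 0 is the initial temperature)
#' @param cfg an [sa_config()]
#' @export
sa_temperature <- function(k, cfg) {
  stopifnot(all(k >= 0), all(k <= cfg$k_max))
  cfg$T0 * cfg$alpha^k
}

#' Random feasible initial schedule
#'
#' Each population's planting week is drawn uniformly from the window weeks
#' that let it mature within the horizon under every scenario. If some
#' population has no such week the instance is infeasible for the
#' stochastic problem and a \code{gduplan_infeasible} condition naming the
#' offending populations is signalled — the same diagnosis (and list) the
#' stochastic MILP builder produces.
#'
#' @param instance a [gdu_instance()]
#' @return a named planting schedule
#' @export
sa_initial_solution <- function(instance) {
  feas <- feasible_plant_weeks(instance)
  bad <- instance$populations$id[rowSums(feas) == 0]
  if (length(bad)) {
    rep_ <- feasibility_report(instance)
    stop_infeasible(paste0(
      "no feasible planting week for population(s) ",
      paste(sort(bad), collapse = ", ")),
      sort(bad), pairs = rep_[!rep_$feasible, c("id", "scenario")])
  }
  s <- vapply(seq_len(instance$N), function(i) {
    w <- which(feas[i, ])
    if (length(w) == 1L) w else sample(w, 1L)
  }, integer(1))
  validate_schedule(s, instance)
}

#' Metropolis acceptance test
#'
#' Improving or equal moves are always accepted; a worsening move is
#' accepted with probability \eqn{e^{-(E_{new}-E_{cur})/T}}. The
#' \code{"literal"} variant uses the published exponent
#' \eqn{e^{-(E_{cur}-E_{new})/T}} (capped at 1), which degenerates to
#' always accepting worse moves; it exists for side-by-side comparison
#' only.
#'
#' @param e_current,e_new energies
#' @param temperature current temperature (> 0)
#' @param acceptance \code{"metropolis"} or \code{"literal"}
#' @return logical: accept the new solution?
#' @export
sa_accept <- function(e_current, e_new, temperature,
                      acceptance = c("metropolis", "literal")) {
  acceptance <- match.arg(acceptance)
  stopifnot(temperature > 0)
  if (acceptance == "metropolis") {
    if (e_new <= e_current) return(TRUE)
    stats::runif(1) < exp(-(e_new - e_current) / temperature)
  } else {
    stats::runif(1) < min(1, exp(-(e_current - e_new) / temperature))
  }
}

# Energy of a schedule under the configured objective. Lean internal path:
# one lookup per scenario plus a short accumulation loop.
.sa_energy <- function(s, instance, cfg, hq, idx) {
  idx[, 2L] <- s
  T_ <- instance$T; K <- instance$K
  A <- matrix(0, T_, K)
  for (k in seq_len(K)) {
    h <- instance$hlook[[k]][idx]
    for (i in seq_along(h)) A[h[i], k] <- A[h[i], k] + hq[i]
  }
  Am <- A[, 1]
  if (K > 1L) for (k in 2:K) Am <- pmax(Am, A[, k])
  if (cfg$objective == "case1_stoch") {
    v <- if (cfg$all_weeks) Am else Am[Am > 0]
    list(energy = sum(abs(instance$capacity - v)), A = A, A_max = Am)
  } else {
    v <- Am[Am > 0]
    list(energy = if (length(v) < 2) 0 else sum(abs(diff(v))), A = A,
         A_max = Am)
  }
}

#' One neighborhood move of the annealer
#'
#' Implements the problem-specific neighborhood: (a) at the active week
#' with the largest envelope value, shift the planting weeks of the
#' \code{moves_per_max_week} harvested populations with the smallest
#' harvest quantities forward or backward by one or two weeks (uniformly
#' among window- and maturity-feasible shifts; a population with no
#' feasible shift is skipped); (b) for the active week with the smallest
#' envelope value, re-plant one population from the closest week with a
#' strictly larger envelope value (ties broken toward earlier weeks, then
#' smaller population id) so that its harvest lands on the minimal week
#' under the scenario attaining that week's envelope value, when such a
#' window- and maturity-feasible planting week exists. Either component may
#' be a no-op; the returned schedule carries the move log in attribute
#' \code{"moves"}.
#'
#' @param schedule current planting schedule
#' @param instance a [gdu_instance()]
#' @param cfg an [sa_config()]
#' @param state optional cached energy state for \code{schedule} (from the
#'   annealing loop); recomputed when NULL
#' @return a new feasible schedule
#' @export
sa_neighbor <- function(schedule, instance, cfg, state = NULL) {
  hq <- active_hq(instance)
  N <- instance$N
  idx <- cbind(seq_len(N), 0L)
  feas <- attr(instance, ".feas_cache")
  if (is.null(feas)) feas <- feasible_plant_weeks(instance)
  if (is.null(state)) state <- .sa_energy(schedule, instance, cfg, hq, idx)
  s <- schedule
  A <- state$A; Am <- state$A_max
  active <- which(Am > 0)
  if (!length(active)) return(structure(s, moves = "noop:empty"))
  ids <- instance$populations$id
  moves <- character()

  # (a) deflate the tallest week
  j_max <- active[which.max(Am[active])]
  k_max <- which.max(A[j_max, ])
  idx[, 2L] <- s
  h_kmax <- instance$hlook[[k_max]][idx]
  cand <- which(h_kmax == j_max)
  if (length(cand)) {
    # smallest harvest quantity first, ties by id
    ord <- cand[order(hq[cand], ids[cand])]
    pick <- ord[seq_len(min(cfg$moves_per_max_week, length(ord)))]
    shifts <- c(-cfg$shift_range, cfg$shift_range)
    for (i in pick) {
      newp <- s[i] + shifts
      newp <- newp[newp >= 1L & newp <= instance$T]
      newp <- newp[feas[cbind(i, newp)]]
      if (length(newp)) {
        s[i] <- if (length(newp) == 1L) newp else sample(newp, 1L)
        moves <- c(moves, paste0("shift:", ids[i]))
      } else moves <- c(moves, paste0("noop_shift:", ids[i]))
    }
  }

  # (b) fill the shallowest week from the closest taller week
  j_min <- active[which.min(Am[active])]
  taller <- active[Am[active] > Am[j_min]]
  moved <- FALSE
  if (length(taller)) {
    d <- abs(taller - j_min)
    j_from <- min(taller[d == min(d)])  # ties -> earlier week
    k_min <- which.max(A[j_min, ])
    idx[, 2L] <- s
    h_kmin <- instance$hlook[[k_min]][idx]
    donors <- which(h_kmin == j_from)
    donors <- donors[sort.list(ids[donors])]  # smaller id first
    for (i in donors) {
      lands <- which(feas[i, ] & instance$hlook[[k_min]][i, ] == j_min)
      lands <- lands[lands != s[i]]
      if (length(lands)) {
        s[i] <- min(lands)
        moves <- c(moves, paste0("fill:", ids[i]))
        moved <- TRUE
        break
      }
    }
  }
  if (!moved) moves <- c(moves, "noop_fill")
  structure(s, moves = moves)
}

#' Run the simulated annealing solver
#'
#' Starts from a random maturity-feasible schedule and runs \code{k_max}
#' iterations of neighbor generation, energy evaluation and acceptance
#' under geometric cooling, tracking the best schedule ever visited. Fully
#' reproducible under \code{cfg$seed}.
#'
#' @param instance a [gdu_instance()] (capacity required for the
#'   \code{"case1_stoch"} energy)
#' @param cfg an [sa_config()]
#' @return list with \code{result} (a \code{gdu_solve_result}; for case 2
#'   energies it carries \code{capacity}, the peak of the best envelope)
#'   and \code{trace} (data.frame k / temperature / current / best /
#'   accepted / moves)
#' @export
sa_anneal <- function(instance, cfg = sa_config()) {
  if (cfg$objective == "case1_stoch" && is.na(instance$capacity))
    stop("sa_anneal: case1_stoch energy needs an instance capacity")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  # cache feasibility on a local copy so repeated neighbor calls are cheap
  attr(instance, ".feas_cache") <- feasible_plant_weeks(instance)
  init <- tryCatch(sa_initial_solution(instance),
                   gduplan_infeasible = function(c) c)
  if (inherits(init, "gduplan_infeasible")) {
    return(list(result = structure(
      list(status = "infeasible", schedule = NULL, profile = NULL,
           objective = NA_real_, offending = init$offending,
           pairs = init$pairs, message = conditionMessage(init)),
      class = "gdu_solve_result"), trace = NULL))
  }
  hq <- active_hq(instance)
  idx <- cbind(seq_len(instance$N), 0L)
  cur <- init
  cur_state <- .sa_energy(cur, instance, cfg, hq, idx)
  best <- cur; best_e <- cur_state$energy
  k_max <- cfg$k_max
  temps <- cfg$T0 * cfg$alpha^seq_len(k_max)
  tr_cur <- numeric(k_max); tr_best <- numeric(k_max)
  tr_acc <- logical(k_max); tr_mv <- character(k_max)
  metropolis <- cfg$acceptance == "metropolis"
  for (k in seq_len(k_max)) {
    prop <- sa_neighbor(cur, instance, cfg, state = cur_state)
    prop_state <- .sa_energy(prop, instance, cfg, hq, idx)
    de <- prop_state$energy - cur_state$energy
    acc <- if (metropolis) {
      de <= 0 || stats::runif(1) < exp(-de / temps[k])
    } else {
      stats::runif(1) < min(1, exp(de / temps[k]))
    }
    if (acc) {
      cur <- prop; cur_state <- prop_state
      if (cur_state$energy < best_e) { best <- cur; best_e <- cur_state$energy }
    }
    tr_cur[k] <- cur_state$energy; tr_best[k] <- best_e
    tr_acc[k] <- acc
    tr_mv[k] <- paste(attr(prop, "moves"), collapse = ";")
  }
  trace <- data.frame(k = seq_len(k_max), temperature = temps,
                      current = tr_cur, best = tr_best, accepted = tr_acc,
                      moves = tr_mv)
  attr(instance, ".feas_cache") <- NULL
  attr(best, "moves") <- NULL
  profile <- evaluate_profile(best, instance)
  # exact re-evaluation through the public objective path
  obj <- if (cfg$objective == "case1_stoch")
    objective_case1_stoch(profile, instance$capacity, cfg$all_weeks)
  else objective_case2_stoch(profile)
  # with integer ear counts both paths sum the same integers, so this is an
  # exact identity; the tolerance only guards non-integer HQ inputs
  stopifnot(isTRUE(all.equal(obj, best_e, tolerance = 1e-9)))
  res <- list(status = "feasible", schedule = best, profile = profile,
              objective = obj, solver_objective = obj, gap = NA_real_,
              harvest_week = profile$harvest_week, offending = NULL)
  if (cfg$objective == "case2_stoch") res$capacity <- max(profile$A_max)
  list(result = structure(res, class = "gdu_solve_result"), trace = trace)
}
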