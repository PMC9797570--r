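# ---- solver backend (HiGHS via SciPy) ---------------------------------

.python_bin <- function() {
  p <- Sys.getenv("GDUPLAN_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("no MILP backend: `python` with SciPy >= 1.9 is required on PATH ",
         "(set GDUPLAN_PYTHON to override)")
  p
}

.model_payload <- function(model, time_limit, rel_gap) {
  list(nvar = nrow(model$vars),
       obj = model$obj,
       integrality = as.integer(model$vars$kind == "binary"),
       lb = ifelse(is.finite(model$vars$lb), model$vars$lb, NA),
       ub = ifelse(is.finite(model$vars$ub), model$vars$ub, NA),
       ai = model$A$i, aj = model$A$j, ax = model$A$x,
       cl = ifelse(is.finite(model$cl), model$cl, NA),
       cu = ifelse(is.finite(model$cu), model$cu, NA),
       time_limit = time_limit, rel_gap = rel_gap)
}

#' Solve a batch of MILP models in one backend call
#'
#' Ships the models to the HiGHS solver (SciPy's \code{milp}) through a JSON
#' round-trip and one Python subprocess, amortizing interpreter start-up
#' over the batch. Raw solutions only; use [solve_model()] (or the
#' \code{solve_*} wrappers) for schedule extraction and re-validation.
#'
#' @param models list of \code{milp_model} objects
#' @param time_limit per-model wall-clock limit, seconds
#' @param rel_gap relative MIP optimality gap
#' @return list of raw solutions (status, x, fun, gap)
#' @export
solve_milp_batch <- function(models, time_limit = 600, rel_gap = 1e-6) {
  stopifnot(all(vapply(models, inherits, logical(1), "milp_model")))
  script <- system.file("python", "milp_solve.py", package = "gduplan")
  if (!nzchar(script)) stop("milp_solve.py not found in installed package")
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  payload <- lapply(models, .model_payload, time_limit = time_limit,
                    rel_gap = rel_gap)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  st <- system2(.python_bin(), c(script, fin, fout),
                stdout = TRUE, stderr = TRUE)
  code <- attr(st, "status")
  if (!is.null(code) && code != 0)
    stop("MILP backend failed (exit ", code, "):\n",
         paste(st, collapse = "\n"))
  jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Solve one MILP model and extract a validated result
#'
#' Solves the model, rounds the binaries at 0.5, asserts that exactly one
#' planting week is selected per population, and re-derives harvest weeks,
#' profile and objective independently through the GDU engine — the solver's
#' numbers are cross-checked, never trusted.
#'
#' @param model a model built by [build_case1()], [build_case2()] or
#'   [build_stochastic_case1()]
#' @param instance the [gdu_instance()] the model was built from
#' @param time_limit seconds (default 600)
#' @param rel_gap relative optimality gap (the capacity-sizing runs in the
#'   source study used 0.001)
#' @param raw optionally a pre-computed raw solution from
#'   [solve_milp_batch()]
#' @return a \code{gdu_solve_result}: list with \code{status},
#'   \code{schedule}, \code{profile}, \code{objective} (engine-recomputed),
#'   \code{solver_objective}, \code{gap}, and for case 2 \code{capacity}
#'   (= peak of the weekly harvest)
#' @export
solve_model <- function(model, instance, time_limit = 600, rel_gap = 1e-6,
                        raw = NULL) {
  if (is.null(raw))
    raw <- solve_milp_batch(list(model), time_limit, rel_gap)[[1]]
  if (raw$status %in% c("infeasible", "unbounded", "failed") ||
      is.null(raw$x)) {
    return(structure(list(status = raw$status, schedule = NULL,
                          profile = NULL, objective = NA_real_,
                          solver_objective = NA_real_, gap = NA_real_,
                          offending = NULL),
                     class = "gdu_solve_result"))
  }
  x <- as.numeric(unlist(raw$x))
  s <- integer(instance$N)
  for (i in seq_len(instance$N)) {
    tpi <- model$meta$tp[[i]]
    on <- x[tpi] > 0.5
    if (sum(on) != 1L)
      stop("extraction: population ", instance$populations$id[i],
           " has ", sum(on), " planting weeks selected")
    s[i] <- as.integer(names(tpi)[on])
  }
  schedule <- validate_schedule(s, instance)
  profile <- evaluate_profile(schedule, instance)
  obj <- switch(model$meta$objective,
                case1_det = objective_case1_det(
                  structure(list(A = profile$A[, model$meta$scenario,
                                               drop = FALSE],
                                 A_max = profile$A[, model$meta$scenario]),
                            class = "harvest_profile"),
                  instance$capacity),
                case2_det = objective_case2_det(
                  structure(list(A = profile$A[, model$meta$scenario,
                                               drop = FALSE],
                                 A_max = profile$A[, model$meta$scenario]),
                            class = "harvest_profile"),
                  instance$theta_w),
                case1_stoch = objective_case1_stoch(
                  profile, instance$capacity,
                  all_weeks = isTRUE(model$meta$all_weeks)))
  solver_obj <- raw$fun
  if (!isTRUE(all.equal(obj, solver_obj, tolerance = max(rel_gap, 1e-6),
                        scale = max(1, abs(obj)))))
    warning(sprintf(
      "solver objective %.8g differs from engine re-evaluation %.8g",
      solver_obj, obj))
  status <- raw$status
  gap <- if (is.null(raw$gap)) NA_real_ else raw$gap
  res <- list(status = status, schedule = schedule, profile = profile,
              objective = obj, solver_objective = solver_obj, gap = gap,
              harvest_week = profile$harvest_week, offending = NULL)
  if (model$meta$objective == "case2_det")
    res$capacity <- max(profile$A[, model$meta$scenario])
  structure(res, class = "gdu_solve_result")
}

#' @export
print.gdu_solve_result <- function(x, ...) {
  cat(sprintf("<gdu_solve_result: status=%s", x$status))
  if (!is.null(x$schedule))
    cat(sprintf(", objective=%.6g (solver %.6g, gap %s)",
                x$objective, x$solver_objective,
                ifelse(is.na(x$gap), "NA", sprintf("%.2g", x$gap))))
  if (!is.null(x$offending) && length(x$offending))
    cat(", offending populations: ", paste(x$offending, collapse = ", "))
  cat(">\n")
  invisible(x)
}

# Wrap a builder so maturity infeasibility becomes an infeasible result
# instead of an error.
.solve_with <- function(builder, instance, ...,
                        time_limit = 600, rel_gap = 1e-6) {
  model <- tryCatch(builder(), gduplan_infeasible = function(c) c)
  if (inherits(model, "gduplan_infeasible")) {
    return(structure(list(status = "infeasible", schedule = NULL,
                          profile = NULL, objective = NA_real_,
                          solver_objective = NA_real_, gap = NA_real_,
                          offending = model$offending,
                          pairs = model$pairs,
                          message = conditionMessage(model)),
                     class = "gdu_solve_result"))
  }
  solve_model(model, instance, time_limit = time_limit, rel_gap = rel_gap)
}

#' Solve the deterministic case 1 problem end to end
#'
#' @inheritParams build_case1
#' @inheritParams solve_model
#' @export
solve_case1 <- function(instance, scenario = 1, time_limit = 600,
                        rel_gap = 1e-6, sparsify_harvest = FALSE) {
  .solve_with(function() build_case1(instance, scenario, sparsify_harvest),
              instance, time_limit = time_limit, rel_gap = rel_gap)
}

#' Solve the deterministic case 2 (capacity sizing) problem end to end
#'
#' Uses the 0.1 % optimality-gap stopping convention of the capacity-sizing
#' runs by default.
#'
#' @inheritParams build_case2
#' @inheritParams solve_model
#' @export
solve_case2 <- function(instance, scenario = 1, time_limit = 600,
                        rel_gap = 0.001, sparsify_harvest = FALSE) {
  .solve_with(function() build_case2(instance, scenario, sparsify_harvest),
              instance, time_limit = time_limit, rel_gap = rel_gap)
}

#' Solve the stochastic case 1 MILP end to end
#'
#' @inheritParams build_stochastic_case1
#' @inheritParams solve_model
#' @export
solve_stochastic_case1 <- function(instance, all_weeks = FALSE,
                                   time_limit = 600, rel_gap = 1e-6,
                                   audit_dense = FALSE) {
  .solve_with(function() build_stochastic_case1(instance, all_weeks,
                                                audit_dense),
              instance, time_limit = time_limit, rel_gap = rel_gap)
}
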