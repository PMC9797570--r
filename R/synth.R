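#' Configuration for the synthetic instance generator
#'
#' Defaults describe a plausible temperate corn site: planting windows a few
#' weeks wide opening between early spring and midsummer, corn-typical
#' required heat (1200-1600 C-based GDU), right-skewed (log-normal) harvest
#' quantities with the capacity-sizing case uniformly larger, and a
#' sinusoidal seasonal weekly GDU curve peaking midsummer with additive
#' year-to-year noise and an optional site-level offset.
#'
#' @param n_populations number of seed populations N
#' @param horizon horizon T in weeks (70, the challenge convention)
#' @param n_scenarios number of GDU scenario years K
#' @param seed RNG seed for full determinism
#' @param window_start_range weeks between which the earliest planting week
#'   is drawn (uniform integer)
#' @param window_width_range window width (late - early) range, weeks
#' @param required_gdu_range required GDU range, heat units
#' @param hq_log_mean,hq_log_sd log-normal parameters of the case 1 harvest
#'   quantity, log-ears
#' @param case2_multiplier_range case 2 quantity = case 1 x multiplier,
#'   drawn uniformly from this range (> 1, matching the observation that
#'   the unconstrained-capacity case stores more ears)
#' @param climate_mean mean weekly GDU over the year, heat units/week
#' @param climate_amplitude seasonal amplitude of the weekly GDU sinusoid
#' @param climate_noise_sd sd of independent weekly noise, heat units/week
#' @param site_offset additive shift of the weekly mean (negative for a
#'   colder site), heat units/week
#' @return a list of class \code{generator_config}
#' @export
generator_config <- function(n_populations = 200, horizon = 70,
                             n_scenarios = 10, seed = 1,
                             window_start_range = c(2, 30),
                             window_width_range = c(3, 10),
                             required_gdu_range = c(1200, 1600),
                             hq_log_mean = log(150), hq_log_sd = 0.6,
                             case2_multiplier_range = c(1.2, 2.0),
                             climate_mean = 55, climate_amplitude = 50,
                             climate_noise_sd = 8, site_offset = 0) {
  cfg <- list(n_populations = as.integer(n_populations),
              horizon = as.integer(horizon),
              n_scenarios = as.integer(n_scenarios),
              seed = as.integer(seed),
              window_start_range = as.integer(window_start_range),
              window_width_range = as.integer(window_width_range),
              required_gdu_range = as.numeric(required_gdu_range),
              hq_log_mean = hq_log_mean, hq_log_sd = hq_log_sd,
              case2_multiplier_range = as.numeric(case2_multiplier_range),
              climate_mean = climate_mean,
              climate_amplitude = climate_amplitude,
              climate_noise_sd = climate_noise_sd,
              site_offset = site_offset)
  stopifnot(cfg$n_populations >= 0, cfg$horizon >= 1, cfg$n_scenarios >= 1,
            cfg$hq_log_sd >= 0, cfg$climate_noise_sd >= 0)
  rng <- function(r, what) if (r[1] > r[2]) stop("generator_config: empty ", what)
  rng(cfg$window_start_range, "window_start_range")
  rng(cfg$window_width_range, "window_width_range")
  rng(cfg$required_gdu_range, "required_gdu_range")
  rng(cfg$case2_multiplier_range, "case2_multiplier_range")
  if (cfg$window_width_range[1] < 0)
    stop("generator_config: negative window width")
  if (cfg$case2_multiplier_range[1] < 1)
    stop("generator_config: case 2 multiplier must be >= 1")
  class(cfg) <- "generator_config"
  cfg
}

#' Draw a synthetic population table
#'
#' Windows are uniform-integer draws clipped into \code{[1, T]}; required
#' GDUs uniform; harvest quantities log-normal with case 2 = case 1 times a
#' multiplier > 1, so \code{hq_case2 >= hq_case1} holds row by row.
#' Fully deterministic under \code{cfg$seed}.
#'
#' @param cfg a [generator_config()]
#' @return a population table passing [validate_populations()]
#' @export
generate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_populations
  if (n == 0L)
    return(data.frame(id = integer(), early_week = integer(),
                      late_week = integer(), required_gdu = numeric(),
                      hq_case1 = numeric(), hq_case2 = numeric()))
  withr_seed(cfg$seed, {
    early <- sample(cfg$window_start_range[1]:cfg$window_start_range[2],
                    n, replace = TRUE)
    early <- pmin(early, cfg$horizon)  # short horizons clip the start range
    width <- sample(cfg$window_width_range[1]:cfg$window_width_range[2],
                    n, replace = TRUE)
    late <- pmin(early + width, cfg$horizon)
    gmin <- stats::runif(n, cfg$required_gdu_range[1], cfg$required_gdu_range[2])
    hq1 <- round(stats::rlnorm(n, cfg$hq_log_mean, cfg$hq_log_sd))
    mult <- stats::runif(n, cfg$case2_multiplier_range[1],
                         cfg$case2_multiplier_range[2])
    data.frame(id = seq_len(n), early_week = as.integer(early),
               late_week = as.integer(late), required_gdu = gmin,
               hq_case1 = hq1, hq_case2 = round(hq1 * mult))
  })
}

#' Draw synthetic weekly GDU scenarios
#'
#' Each scenario (year) follows the same seasonal sinusoid
#' \eqn{\mu_j = m + a \cos(2\pi (j - 26)/52) + offset} (peak near week 26,
#' midsummer) plus independent Gaussian weekly noise, clipped at 0 and
#' wrapped past week 52 so the horizon's tail re-enters the next spring of
#' the same synthetic year.
#'
#' @param cfg a [generator_config()]
#' @return list of K [gdu_scenario()] objects of length T
#' @export
generate_scenarios <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  T_ <- cfg$horizon
  j52 <- ((seq_len(T_) - 1L) %% 52L) + 1L  # wrap week index into the year
  mu <- cfg$climate_mean + cfg$site_offset +
    cfg$climate_amplitude * cos(2 * pi * (j52 - 26) / 52)
  withr_seed(cfg$seed + 1L, {
    lapply(seq_len(cfg$n_scenarios), function(k) {
      noise <- stats::rnorm(T_, 0, cfg$climate_noise_sd)
      gdu_scenario(pmax(mu + noise, 0), label = sprintf("year%02d", k))
    })
  })
}

#' Generate a complete synthetic instance
#'
#' Assembles populations and scenarios, then sets the capacity and repairs
#' maturity feasibility. With \code{capacity_rule = "quantile"} (default)
#' the capacity is the stated quantile of the positive weekly envelope
#' demand under midpoint-of-window planting; \code{"explicit"} uses
#' \code{capacity} as given. Unless \code{allow_infeasible} is set, any
#' population whose required GDU is unreachable from every window week
#' under some scenario has its requirement redrawn below the reachable
#' maximum (the repair is recorded in the \code{resampled} attribute), so
#' generated instances are feasible by construction.
#'
#' @param cfg a [generator_config()]
#' @param capacity_rule \code{"quantile"} or \code{"explicit"}
#' @param capacity explicit capacity in ears (required for
#'   \code{"explicit"}; ignored otherwise)
#' @param quantile probability used by the quantile rule (default 0.75)
#' @param hq_case active harvest-quantity case, 1 or 2
#' @param theta_w case 2 week penalty
#' @param allow_infeasible skip the feasibility repair (to reproduce
#'   cold-site infeasibility)
#' @return a [gdu_instance()]; attribute \code{resampled} lists repaired
#'   population ids
#' @export
generate_instance <- function(cfg, capacity_rule = c("quantile", "explicit"),
                              capacity = NULL, quantile = 0.75,
                              hq_case = 1, theta_w = 1,
                              allow_infeasible = FALSE) {
  capacity_rule <- match.arg(capacity_rule)
  pops <- generate_populations(cfg)
  scen <- generate_scenarios(cfg)
  cum <- vapply(scen, function(s) cumulative_gdu(s), numeric(cfg$horizon + 1))

  resampled <- integer()
  if (!allow_infeasible && nrow(pops)) {
    withr_seed(cfg$seed + 2L, {
      for (i in seq_len(nrow(pops))) {
        win <- pops$early_week[i]:pops$late_week[i]
        # heat available from the most favorable window week, per scenario;
        # the earliest window week maximizes remaining accumulation
        reach <- min(vapply(seq_along(scen), function(k)
          cum[cfg$horizon + 1, k] - cum[pops$early_week[i] + 1, k],
          numeric(1)))
        if (pops$required_gdu[i] > reach) {
          if (reach <= 0)
            stop("generate_instance: population ", pops$id[i],
                 " has no accumulable heat; widen the climate config")
          pops$required_gdu[i] <- stats::runif(1, 0.5 * reach, 0.95 * reach)
          resampled <- c(resampled, pops$id[i])
        }
      }
    })
  }

  if (capacity_rule == "explicit") {
    if (is.null(capacity)) stop("generate_instance: explicit capacity missing")
    C <- capacity
  } else {
    # midpoint-of-window planting demand, envelope across scenarios
    inst0 <- gdu_instance(pops, scen, capacity = NA, theta_w = theta_w,
                          hq_case = hq_case)
    mid <- as.integer(floor((pops$early_week + pops$late_week) / 2))
    prof <- evaluate_profile(mid, inst0)
    pos <- prof$A_max[prof$A_max > 0]
    C <- if (length(pos)) as.numeric(stats::quantile(pos, quantile)) else 1
  }
  inst <- gdu_instance(pops, scen, capacity = C, theta_w = theta_w,
                       hq_case = hq_case)
  attr(inst, "resampled") <- resampled
  inst
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
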