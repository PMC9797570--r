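Package: gduplan
Title: Corn Planting and Harvest Scheduling Under Growing Degree Unit
    Uncertainty
Version: 0.1.0
Authors@R:
    person("Sam", "Field", email = "sam.field@example.org",
           role = c("aut", "cre"))
Description: Optimization toolkit for scheduling planting and harvest weeks
    of corn seed populations from heat-unit (growing degree unit, GDU)
    phenology. Provides the weekly GDU accumulation engine with the
    earliest-harvest rule, deterministic mixed-integer linear programs for a
    fixed storage capacity (absolute-deviation objective) and for capacity
    sizing (minimax objective), an exact multi-scenario stochastic MILP with
    a linearized max envelope over historical GDU scenarios, and a simulated
    annealing heuristic with a problem-specific neighborhood for the
    stochastic problem. Includes a synthetic instance generator, a lagged
    climatology forecasting baseline, CSV readers and writers, and a command
    line interface. Mixed-integer programs are solved through the HiGHS
    solver bundled with SciPy, called via the system Python.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.9) with SciPy (>= 1.9) on the PATH for the
    MILP solver backend.
Config/testthat/edition: 3
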