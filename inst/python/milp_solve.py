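"""Batch MILP solve via scipy.optimize.milp (HiGHS).

Reads a JSON file holding a list of models, solves each, writes a JSON list
of solutions. Model schema (indices 1-based, converted here):
  {"nvar": int, "obj": [...], "integrality": [0/1,...],
   "lb": [...], "ub": [...],
   "ai": [...], "aj": [...], "ax": [...], "cl": [...], "cu": [...],
   "time_limit": seconds, "rel_gap": fraction}
Solution: {"status": "optimal|time_limit|infeasible|unbounded|failed",
           "x": [...], "fun": float, "gap": float}
"""
import json
import math
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

STATUS = {0: "optimal", 1: "time_limit", 2: "infeasible", 3: "unbounded",
          4: "failed"}


def num(v, default):
    if v is None:
        return default
    return float(v)


def solve_one(mod):
    nvar = int(mod["nvar"])
    c = np.asarray(mod["obj"], dtype=float)
    integrality = np.asarray(mod["integrality"], dtype=int)
    lb = np.array([num(v, -math.inf) for v in mod["lb"]])
    ub = np.array([num(v, math.inf) for v in mod["ub"]])
    ai = np.asarray(mod["ai"], dtype=int) - 1
    aj = np.asarray(mod["aj"], dtype=int) - 1
    ax = np.asarray(mod["ax"], dtype=float)
    ncon = len(mod["cl"])
    cl = np.array([num(v, -math.inf) for v in mod["cl"]])
    cu = np.array([num(v, math.inf) for v in mod["cu"]])
    A = sparse.csc_matrix((ax, (ai, aj)), shape=(ncon, nvar))
    options = {"presolve": True}
    if mod.get("time_limit") is not None:
        options["time_limit"] = float(mod["time_limit"])
    if mod.get("rel_gap") is not None:
        options["mip_rel_gap"] = float(mod["rel_gap"])
    res = milp(c=c, constraints=LinearConstraint(A, cl, cu),
               integrality=integrality, bounds=Bounds(lb, ub),
               options=options)
    out = {"status": STATUS.get(res.status, "failed")}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["fun"] = float(res.fun)
        gap = getattr(res, "mip_gap", None)
        out["gap"] = None if gap is None else float(gap)
    return out


def main(argv):
    inp, outp = argv[1], argv[2]
    with open(inp) as fh:
        models = json.load(fh)
    if isinstance(models, dict):
        models = [models]
    sols = [solve_one(m) for m in models]
    with open(outp, "w") as fh:
        json.dump(sols, fh)


if __name__ == "__main__":
    main(sys.argv)
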