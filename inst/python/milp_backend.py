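"""Batched LP/MILP solves via scipy's HiGHS interface.

Protocol: argv[1] is a JSON file {"groups": [...], "problems": [...]},
argv[2] the output path. Each problem is
  {"c": [...], "maximize": bool, "lb": [...], "ub": [...],
   "int": [...0/1...],                      # optional, default all 0
   "Aeq": [[...]], "beq": [...],            # optional
   "Aub": [[...]], "bub": [...],            # optional
   "group": i}                              # optional, 1-based index into
                                            # groups for shared Aeq/Aub
Groups hold {"Aeq": ..., "beq": ..., "Aub": ..., "bub": ...}.
Bounds with |x| >= 1e29 are treated as infinite.
Output: [{"status": "optimal"|"infeasible"|"unbounded"|"error",
          "objective": num|null, "x": [...]|null}, ...]
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp

BIG = 1e29


def _inf(v):
    v = np.atleast_1d(np.asarray(v, dtype=float))
    v = np.where(v >= BIG, np.inf, v)
    v = np.where(v <= -BIG, -np.inf, v)
    return v


def solve_one(prob, groups):
    src = groups[prob["group"] - 1] if prob.get("group") else prob
    cons = []
    if src.get("Aeq") is not None and len(src["Aeq"]):
        beq = np.atleast_1d(np.asarray(src["beq"], dtype=float))
        cons.append(LinearConstraint(
            np.atleast_2d(np.asarray(src["Aeq"], dtype=float)), beq, beq))
    if src.get("Aub") is not None and len(src["Aub"]):
        bub = _inf(src["bub"])
        cons.append(LinearConstraint(
            np.atleast_2d(np.asarray(src["Aub"], dtype=float)), -np.inf, bub))
    c = np.atleast_1d(np.asarray(prob["c"], dtype=float))
    sign = -1.0 if prob.get("maximize") else 1.0
    integrality = np.atleast_1d(
        np.asarray(prob.get("int", np.zeros_like(c)), dtype=int))
    bounds = Bounds(_inf(prob["lb"]), _inf(prob["ub"]))
    res = milp(c=sign * c, constraints=cons, bounds=bounds,
               integrality=integrality)
    if res.status == 0:
        return {"status": "optimal", "objective": float(sign * res.fun),
                "x": [float(v) for v in res.x]}
    if res.status == 2:
        return {"status": "infeasible", "objective": None, "x": None}
    if res.status == 3:
        return {"status": "unbounded", "objective": None, "x": None}
    return {"status": "error", "objective": None, "x": None}


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    groups = payload.get("groups") or []
    out = [solve_one(p, groups) for p in payload.get("problems", [])]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
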