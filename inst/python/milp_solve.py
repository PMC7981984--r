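"""Batch LP/MILP solving over a shared constraint set (HiGHS via scipy).

Reads a JSON problem description, solves one LP/MILP per objective, writes a
JSON results file.  Matrices arrive as 1-based sparse triplets.

Usage: python milp_solve.py <in.json> <out.json>
"""
import json
import sys
import warnings

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import csr_matrix

# constraint couplings at the 1e-6 scale (basal fluxes) must not drown in
# the solver's default 1e-6 MIP feasibility tolerance
DEFAULT_OPTIONS = {
    "mip_feasibility_tolerance": 1e-9,
    "primal_feasibility_tolerance": 1e-8,
    "dual_feasibility_tolerance": 1e-8,
    "mip_rel_gap": 0.0,
    "mip_abs_gap": 0.0,
}


def _mat(d, ncol):
    if d is None or d["nrow"] == 0:
        return None
    i = np.asarray(d["i"], dtype=int) - 1
    j = np.asarray(d["j"], dtype=int) - 1
    x = np.asarray(d["x"], dtype=float)
    return csr_matrix((x, (i, j)), shape=(d["nrow"], ncol))


def main(path_in, path_out):
    with open(path_in) as fh:
        prob = json.load(fh)

    ncol = int(prob["ncol"])
    lb = np.asarray(prob["lb"], dtype=float)
    ub = np.asarray(prob["ub"], dtype=float)
    integrality = np.asarray(prob.get("integrality", [0] * ncol), dtype=int)
    options = dict(DEFAULT_OPTIONS, **(prob.get("options", {}) or {}))
    warnings.filterwarnings("ignore", message="Unrecognized options")

    constraints = []
    a_eq = _mat(prob.get("A_eq"), ncol)
    if a_eq is not None:
        beq = np.asarray(prob["b_eq"], dtype=float)
        constraints.append(LinearConstraint(a_eq, beq, beq))
    a_ub = _mat(prob.get("A_ub"), ncol)
    if a_ub is not None:
        bub = np.asarray(prob["b_ub"], dtype=float)
        constraints.append(LinearConstraint(a_ub, -np.inf, bub))

    results = []
    for obj in prob["objectives"]:
        c = np.zeros(ncol)
        if obj.get("i"):
            c[np.asarray(obj["i"], dtype=int) - 1] = np.asarray(
                obj["x"], dtype=float
            )
        sense = obj.get("sense", "min")
        if sense == "max":
            c = -c
        lbk, ubk = lb, ub
        if obj.get("lb_i") or obj.get("ub_i"):
            lbk, ubk = lb.copy(), ub.copy()
            if obj.get("lb_i"):
                lbk[np.asarray(obj["lb_i"], dtype=int) - 1] = np.asarray(
                    obj["lb_x"], dtype=float
                )
            if obj.get("ub_i"):
                ubk[np.asarray(obj["ub_i"], dtype=int) - 1] = np.asarray(
                    obj["ub_x"], dtype=float
                )
        res = milp(
            c=c,
            constraints=constraints,
            bounds=Bounds(lbk, ubk),
            integrality=integrality,
            options=options,
        )
        out = {
            "status": int(res.status),
            "success": bool(res.success),
            "objective": None,
            "x": None,
        }
        if res.x is not None:
            val = float(res.fun)
            out["objective"] = -val if sense == "max" else val
            out["x"] = [float(v) for v in res.x]
        results.append(out)

    with open(path_out, "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
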