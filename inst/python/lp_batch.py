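#!/usr/bin/env python
"""Batch LP helper for the fluxforce R package.

Reads a JSON problem file: one sparse constraint matrix (steady-state
stoichiometry), global bounds, and a list of jobs (objective + optional
bound overrides). Solves each job with scipy's HiGHS interface and writes
a JSON list of results. Keeping the matrix shared across jobs makes flux
variability analysis a single process invocation.

Usage: python lp_batch.py <in.json> <out.json>
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import linprog

STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
          3: "unbounded", 4: "error"}


def aslist(x):
    """R's JSON writer unboxes length-1 vectors; normalize back to lists."""
    if x is None:
        return []
    return x if isinstance(x, list) else [x]


def main(in_path, out_path):
    with open(in_path) as fh:
        prob = json.load(fh)
    m, n = prob["m"], prob["n"]
    A = sparse.csc_matrix(
        (aslist(prob["Ax"]),
         (np.array(aslist(prob["Ai"])) - 1, np.array(aslist(prob["Aj"])) - 1)),
        shape=(m, n))
    b = (np.zeros(m) if "b" not in prob
         else np.asarray(aslist(prob["b"]), dtype=float))
    lb0 = np.asarray(aslist(prob["lb"]), dtype=float)
    ub0 = np.asarray(aslist(prob["ub"]), dtype=float)
    big = prob.get("inf", 1e30)
    results = []
    for job in prob["jobs"]:
        lb, ub = lb0.copy(), ub0.copy()
        for k, v in zip(aslist(job.get("lb_idx")), aslist(job.get("lb_val"))):
            lb[k - 1] = v
        for k, v in zip(aslist(job.get("ub_idx")), aslist(job.get("ub_val"))):
            ub[k - 1] = v
        c = np.zeros(n)
        for k, v in zip(aslist(job["c_idx"]), aslist(job["c_val"])):
            c[k - 1] = v
        sign = -1.0 if job.get("sense", "max") == "max" else 1.0
        lb_ = np.where(lb <= -big, -np.inf, lb)
        ub_ = np.where(ub >= big, np.inf, ub)
        res = linprog(sign * c, A_eq=A, b_eq=b,
                      bounds=np.column_stack([lb_, ub_]), method="highs")
        out = {"status": STATUS.get(res.status, "error")}
        if res.status == 0:
            out["objective"] = float(sign * res.fun)
            if job.get("want_fluxes", False):
                out["fluxes"] = [float(x) for x in res.x]
        results.append(out)
    with open(out_path, "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
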