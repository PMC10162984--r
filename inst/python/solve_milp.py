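"""Generic MILP solve via scipy/HiGHS for the enzopt R package.

Reads a model as JSON (sparse triplet constraint matrix, row bounds,
variable bounds, integrality), solves with scipy.optimize.milp and writes
the result as JSON.  Usage: python solve_milp.py model.json result.json
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def main(model_path, result_path):
    with open(model_path) as fh:
        m = json.load(fh)

    ncol = int(m["ncol"])
    obj = np.asarray(m["obj"], dtype=float)
    sign = -1.0 if m.get("maximize", False) else 1.0

    inf = np.inf
    lb = np.asarray(m["lb"], dtype=float)
    ub = np.asarray(m["ub"], dtype=float)
    lb[lb <= -1e29] = -inf
    ub[ub >= 1e29] = inf

    A = sparse.csc_matrix(
        (np.asarray(m["A"]["x"], dtype=float),
         (np.asarray(m["A"]["i"], dtype=int) - 1,
          np.asarray(m["A"]["j"], dtype=int) - 1)),
        shape=(int(m["nrow"]), ncol))
    rlb = np.asarray(m["rlb"], dtype=float)
    rub = np.asarray(m["rub"], dtype=float)
    rlb[rlb <= -1e29] = -inf
    rub[rub >= 1e29] = inf

    integrality = np.asarray(m["integrality"], dtype=int)
    opts = m.get("options", {}) or {}
    milp_opts = {}
    for key in ("mip_rel_gap", "time_limit", "presolve", "node_limit", "disp"):
        if key in opts and opts[key] is not None:
            milp_opts[key] = opts[key]

    res = milp(c=sign * obj,
               constraints=LinearConstraint(A, rlb, rub),
               bounds=Bounds(lb, ub),
               integrality=integrality,
               options=milp_opts)

    out = {
        "success": bool(res.success),
        "status": int(res.status),
        "message": str(res.message),
        "objective": (sign * float(res.fun)) if res.fun is not None else None,
        "x": [float(v) for v in res.x] if res.x is not None else None,
        "mip_gap": float(res.mip_gap) if getattr(res, "mip_gap", None) is not None else None,
    }
    with open(result_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
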