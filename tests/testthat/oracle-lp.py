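"""Independent LP oracle for the test suite.

Reads a JSON file with a list of problems and writes a JSON list of
optima (null where infeasible). Each problem:
  S      : equality matrix (rows) with S v = 0
  lb, ub : variable bounds
  obj    : objective coefficients
  sense  : "max" or "min"
  ineq   : optional {"coef": [...], "rhs": x} meaning coef' v >= rhs
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog

problems = json.load(open(sys.argv[1]))
out = []
for p in problems:
    S = np.asarray(p["S"], dtype=float)
    if S.ndim == 1:
        S = S.reshape(1, -1)
    n = len(p["obj"])
    c = np.asarray(p["obj"], dtype=float)
    sign = -1.0 if p["sense"] == "max" else 1.0
    A_ub = b_ub = None
    if p.get("ineq"):
        A_ub = -np.asarray(p["ineq"]["coef"], dtype=float).reshape(1, -1)
        b_ub = [-float(p["ineq"]["rhs"])]
    res = linprog(sign * c, A_ub=A_ub, b_ub=b_ub, A_eq=S,
                  b_eq=np.zeros(S.shape[0]),
                  bounds=list(zip(p["lb"], p["ub"])), method="highs")
    out.append(sign * res.fun if res.status == 0 else None)
json.dump(out, open(sys.argv[2], "w"))
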