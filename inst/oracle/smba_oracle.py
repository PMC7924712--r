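"""Independent solver for the affine-constrained row-sparse
self-representation problem, used only as a test oracle.

Reads a JSON problem list from argv[1]:
  [{"X": [[...]], "lam": float, "q": 2}, ...]
and writes to argv[2] a JSON list of objective minima obtained with
scipy SLSQP on a smoothed row-norm (sqrt(||row||^2 + eps^2) - eps),
subject to the exact affine constraint (every column of C sums to 1).
"""
import json
import sys

import numpy as np
from scipy.optimize import minimize

EPS = 1e-9


def solve_one(X, lam):
    X = np.asarray(X, dtype=float)
    n = X.shape[1]

    def unpack(v):
        return v.reshape(n, n)

    def obj(v):
        C = unpack(v)
        R = X - X @ C
        rows = np.sqrt(np.sum(C * C, axis=1) + EPS * EPS) - EPS
        return 0.5 * np.sum(R * R) + lam * np.sum(rows)

    def grad(v):
        C = unpack(v)
        R = X - X @ C
        g = -X.T @ R
        rn = np.sqrt(np.sum(C * C, axis=1) + EPS * EPS)
        g += lam * C / rn[:, None]
        return g.ravel()

    cons = [{"type": "eq",
             "fun": (lambda v, j=j: unpack(v)[:, j].sum() - 1.0),
             "jac": (lambda v, j=j: np.eye(n)[:, j][None, :].repeat(n, 0)
                     .T.ravel() * 0 + col_jac(n, j))}
            for j in range(n)]
    # start from the feasible uniform matrix
    v0 = np.full(n * n, 1.0 / n)
    best = None
    for x0 in (v0, np.eye(n).ravel()):
        res = minimize(obj, x0, jac=grad, constraints=cons, method="SLSQP",
                       options={"maxiter": 2000, "ftol": 1e-12})
        val = obj(res.x)
        if best is None or val < best:
            best = val
    return best


def col_jac(n, j):
    J = np.zeros((n, n))
    J[:, j] = 1.0
    return J.ravel()


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    out = [solve_one(p["X"], p["lam"]) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
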