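"""Generic convex reference solver for penalized multi-task regression.

Solves  min_B  0.5 * ||Y - X B||_F^2  +  sum_i w_i * ||S_i vec(B)||_{p_i}
with atoms of two kinds:
  abs: {"w": w, "idx": [...], "coef": [...]}        -> w * |sum coef*x[idx]|
  l2 : {"w": w, "idx": [...]}                        -> w * ||x[idx]||_2
vec(B) is column-major, 0-based indices.  Input/output JSON:
  {"problems": [{"X": [[..]], "Y": [[..]], "atoms": [...]}, ...]}
  -> {"solutions": [{"obj": f, "B": [[..]]}, ...]}
Uses scipy SLSQP on the epigraph form with smooth (squared) cone constraints.
"""
import json, sys
import numpy as np
from scipy.optimize import minimize


def solve_one(prob):
    X = np.asarray(prob["X"], dtype=float)
    Y = np.asarray(prob["Y"], dtype=float)
    if Y.ndim == 1:
        Y = Y[:, None]
    n, J = X.shape
    K = Y.shape[1]
    nb = J * K
    atoms = prob.get("atoms", [])
    na = len(atoms)
    XtX = X.T @ X
    XtY = X.T @ Y
    yty = float(np.sum(Y * Y))
    w = np.array([a["w"] for a in atoms], dtype=float)

    def unpack(z):
        return z[:nb].reshape((J, K), order="F"), z[nb:]

    def f(z):
        B, t = unpack(z)
        return 0.5 * (yty - 2.0 * np.sum(XtY * B) + np.sum(B * (XtX @ B))) + float(w @ t)

    def grad(z):
        B, t = unpack(z)
        g = np.empty(nb + na)
        g[:nb] = (XtX @ B - XtY).reshape(-1, order="F")
        g[nb:] = w
        return g

    cons = []
    for i, a in enumerate(atoms):
        idx = np.atleast_1d(np.asarray(a["idx"], dtype=int))
        if a.get("kind", "l2") == "abs":
            coef = np.atleast_1d(np.asarray(a["coef"], dtype=float))

            def make(idx=idx, coef=coef, i=i, sgn=1.0):
                def c(z):
                    return z[nb + i] + sgn * float(coef @ z[idx])

                def jac(z):
                    g = np.zeros(nb + na)
                    g[idx] = sgn * coef
                    g[nb + i] = 1.0
                    return g

                return {"type": "ineq", "fun": c, "jac": jac}

            cons.append(make(sgn=1.0))
            cons.append(make(sgn=-1.0))
        else:

            def make(idx=idx, i=i):
                def c(z):
                    return z[nb + i] ** 2 - float(z[idx] @ z[idx])

                def jac(z):
                    g = np.zeros(nb + na)
                    g[idx] = -2.0 * z[idx]
                    g[nb + i] = 2.0 * z[nb + i]
                    return g

                return {"type": "ineq", "fun": c, "jac": jac}

            cons.append(make())

    bounds = [(None, None)] * nb + [(0.0, None)] * na

    def true_obj(B):
        o = 0.5 * (yty - 2.0 * np.sum(XtY * B) + np.sum(B * (XtX @ B)))
        v = B.reshape(-1, order="F")
        for a in atoms:
            idx = np.atleast_1d(np.asarray(a["idx"], dtype=int))
            if a.get("kind", "l2") == "abs":
                o += a["w"] * abs(float(np.atleast_1d(np.asarray(a["coef"])) @ v[idx]))
            else:
                o += a["w"] * float(np.linalg.norm(v[idx]))
        return float(o)

    def start_from(B):
        # feasible epigraph point with strictly slack cone constraints (the
        # squared-cone constraint is degenerate at t = ||x|| = 0, where SLSQP
        # has a vanishing constraint gradient and cannot move)
        z = np.empty(nb + na)
        z[:nb] = B.reshape(-1, order="F")
        for i, a in enumerate(atoms):
            idx = np.atleast_1d(np.asarray(a["idx"], dtype=int))
            if a.get("kind", "l2") == "abs":
                z[nb + i] = abs(float(np.atleast_1d(np.asarray(a["coef"])) @ z[idx])) + 1e-6
            else:
                z[nb + i] = float(np.linalg.norm(z[idx])) + 1e-6
        return z

    B_ridge = np.linalg.solve(XtX + 0.1 * np.eye(J), XtY)
    best_B, best_o = None, np.inf
    for start in (start_from(np.zeros((J, K))), start_from(B_ridge)):
        res = minimize(f, start, jac=grad, bounds=bounds, constraints=cons,
                       method="SLSQP", options={"maxiter": 3000, "ftol": 1e-14})
        B, t = unpack(res.x)
        o = true_obj(B)
        if o < best_o:
            best_B, best_o = B, o

    # second, independent route: smooth every norm as sqrt(.^2 + eps^2) and
    # drive eps down by continuation under L-BFGS-B (no epigraph variables)
    pre = []
    for a in atoms:
        idx = np.atleast_1d(np.asarray(a["idx"], dtype=int))
        kind = a.get("kind", "l2")
        coef = (np.atleast_1d(np.asarray(a["coef"], dtype=float))
                if kind == "abs" else None)
        pre.append((kind, idx, coef, float(a["w"])))

    def smooth_obj_grad(x, eps):
        B = x.reshape((J, K), order="F")
        Gq = XtX @ B - XtY
        o = 0.5 * (yty - 2.0 * np.sum(XtY * B) + np.sum(B * (XtX @ B)))
        g = Gq.reshape(-1, order="F").copy()
        for kind, idx, coef, wgt in pre:
            if kind == "abs":
                u = float(coef @ x[idx])
                r = np.sqrt(u * u + eps * eps)
                o += wgt * r
                g[idx] += wgt * u / r * coef
            else:
                v = x[idx]
                r = np.sqrt(float(v @ v) + eps * eps)
                o += wgt * r
                g[idx] += wgt * v / r
        return o, g

    x = B_ridge.reshape(-1, order="F").copy()
    for eps in (1e-2, 1e-4, 1e-6, 1e-8, 1e-10):
        res = minimize(smooth_obj_grad, x, args=(eps,), jac=True,
                       method="L-BFGS-B",
                       options={"maxiter": 20000, "ftol": 1e-16, "gtol": 1e-12})
        x = res.x
    B2 = x.reshape((J, K), order="F")
    o2 = true_obj(B2)
    if o2 < best_o:
        best_B, best_o = B2, o2
    return {"obj": best_o, "B": best_B.tolist()}


def main():
    data = json.load(open(sys.argv[1]))
    out = {"solutions": [solve_one(p) for p in data["problems"]]}
    json.dump(out, open(sys.argv[2], "w"))


if __name__ == "__main__":
    main()
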