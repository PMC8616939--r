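"""Arbitrary-precision backend for the odnptraj memory-kernel recursions.

Implements, in decimal arithmetic at a caller-chosen number of digits, the
same discretization as the package's C++ double-precision path:

  -g''(t) - a g'(t) = K(t) g(0) + h * sum_j w_j K(t_j) g'(t - t_j)

with delta mass a = -g'(0)/g(0), finite-difference derivatives of order 2
or 4 and Gregory-corrected trapezoid quadrature.  Called by R as

    python hpvolterra.py input.json output.json

The input JSON selects an op: "solve", "reconstruct2" or "acf_sums".
Binary doubles are converted to Decimal exactly (Decimal(float)), so the
two backends start from identical inputs.
"""

import json
import sys
from decimal import Decimal, getcontext

D = Decimal


def greg_weights(n, order):
    one = D(1)
    w = [one] * (n + 1)
    half = D(1) / D(2)
    if order <= 1 or n == 1:
        w[0] = w[n] = half
        return w
    if n == 2:
        w[0] = w[2] = D(5) / D(12)
        w[1] = D(7) / D(6)
        return w
    if order >= 3 and n >= 5:
        w[0] = w[n] = D(3) / D(8)
        w[1] = w[n - 1] = D(7) / D(6)
        w[2] = w[n - 2] = D(23) / D(24)
        return w
    w[0] = w[n] = D(5) / D(12)
    w[1] = w[n - 1] = D(13) / D(12)
    return w


def deriv_arrays(g, h, ord_, mmax):
    d1 = [D(0)] * (mmax + 1)
    d2 = [D(0)] * (mmax + 1)
    h2 = h * h
    tw = 2 * h
    if ord_ == 2:
        d1[0] = (-3 * g[0] + 4 * g[1] - g[2]) / tw
        d2[0] = (2 * g[0] - 5 * g[1] + 4 * g[2] - g[3]) / h2
        for m in range(1, mmax + 1):
            d1[m] = (g[m + 1] - g[m - 1]) / tw
            d2[m] = (g[m + 1] - 2 * g[m] + g[m - 1]) / h2
    else:
        tw12 = 12 * h
        h212 = 12 * h2
        d1[0] = (-25 * g[0] + 48 * g[1] - 36 * g[2] + 16 * g[3] - 3 * g[4]) / tw12
        d2[0] = (45 * g[0] - 154 * g[1] + 214 * g[2] - 156 * g[3] +
                 61 * g[4] - 10 * g[5]) / h212
        if mmax >= 1:
            d1[1] = (-3 * g[0] - 10 * g[1] + 18 * g[2] - 6 * g[3] + g[4]) / tw12
            d2[1] = (10 * g[0] - 15 * g[1] - 4 * g[2] + 14 * g[3] -
                     6 * g[4] + g[5]) / h212
        for m in range(2, mmax + 1):
            d1[m] = (g[m - 2] - 8 * g[m - 1] + 8 * g[m + 1] - g[m + 2]) / tw12
            d2[m] = (-g[m - 2] + 16 * g[m - 1] - 30 * g[m] +
                     16 * g[m + 1] - g[m + 2]) / h212
    return d1, d2


def solve(g, h, greg, ord_, pivot_tol):
    N = len(g) - 1
    M = N - 1 if ord_ == 2 else N - 2
    d1, d2 = deriv_arrays(g, h, ord_, M)
    g0 = g[0]
    a = -d1[0] / g0
    K = [D(0)] * (M + 1)
    K[0] = (-d2[0] - a * d1[0]) / g0
    for n in range(1, M + 1):
        w = greg_weights(n, greg)
        s = D(0)
        for j in range(n):
            s += w[j] * K[j] * d1[n - j]
        piv = g0 + h * w[n] * d1[0]
        if abs(piv) < pivot_tol:
            raise ValueError("singular pivot %s at lag index %d" % (piv, n))
        K[n] = (-d2[n] - a * d1[n] - h * s) / piv
    return a, K


def reconstruct2(a, K, h, greg, g0):
    M = len(K) - 1
    N = M + 1
    g = [D(0)] * (N + 1)
    g[0] = g0
    d1 = [D(0)] * N
    d1[0] = -a * g0
    h2 = h * h
    tw = 2 * h
    # 2x2 block {a-def, eq1} for (g1, g2)
    w = greg_weights(1, greg)
    A11 = D(4) / tw
    A12 = D(-1) / tw
    b1 = -(-3 * g0 / tw + a * g0)
    A21 = D(2) / h2
    A22 = -1 / h2 - a / tw - w[0] * K[0] / 2
    b2 = -(-g0 / h2 + a * g0 / tw - K[1] * g0 +
           w[0] * K[0] * g0 / 2 + h * w[1] * K[1] * a * g0)
    det = A11 * A22 - A12 * A21
    g[1] = (b1 * A22 - A12 * b2) / det
    g[2] = (A11 * b2 - b1 * A21) / det
    d1[1] = (g[2] - g0) / tw
    for n in range(2, N):
        w = greg_weights(n, greg)
        s = w[n] * K[n] * d1[0]
        for j in range(1, n):
            s += w[j] * K[j] * d1[n - j]
        d2_part = (-2 * g[n] + g[n - 1]) / h2
        d1_part = -g[n - 1] / tw
        r0 = -d2_part - a * d1_part - K[n] * g[0] - h * (s + w[0] * K[0] * d1_part)
        coef = -(1 / h2 + a / tw + w[0] * K[0] / 2)
        g[n + 1] = -r0 / coef
        d1[n] = (g[n + 1] - g[n - 1]) / tw
    return g


# ---- generic order-4 residual machinery (used for the prefix round trip) ----

def d1_stencil(m):
    if m == 0:
        return (0, [D(-25), D(48), D(-36), D(16), D(-3)])
    if m == 1:
        return (0, [D(-3), D(-10), D(18), D(-6), D(1)])
    return (m - 2, [D(1), D(-8), D(0), D(8), D(-1)])


def d2_stencil(m):
    if m == 0:
        return (0, [D(45), D(-154), D(214), D(-156), D(61), D(-10)])
    if m == 1:
        return (0, [D(10), D(-15), D(-4), D(14), D(-6), D(1)])
    return (m - 2, [D(-1), D(16), D(-30), D(16), D(-1)])


def sten(stencil, g, h, p):
    i0, c = stencil
    s = D(0)
    for k, ck in enumerate(c):
        s += ck * g[i0 + k]
    return s / (12 * h ** p)


def resid4(n, g, a, K, h, greg):
    def d1v(m):
        return sten(d1_stencil(m), g, h, 1)
    if n == -1:  # a-definition
        return d1v(0) + a * g[0]
    if n == 0:
        return -sten(d2_stencil(0), g, h, 2) - a * d1v(0) - K[0] * g[0]
    w = greg_weights(n, greg)
    s = D(0)
    for j in range(n + 1):
        s += w[j] * K[j] * d1v(n - j)
    return (-sten(d2_stencil(n), g, h, 2) - a * d1v(n) - K[n] * g[0] - h * s)


def gauss_solve(A, b):
    n = len(b)
    M = [row[:] + [b[i]] for i, row in enumerate(A)]
    for c in range(n):
        piv = max(range(c, n), key=lambda r: abs(M[r][c]))
        M[c], M[piv] = M[piv], M[c]
        for r in range(c + 1, n):
            f = M[r][c] / M[c][c]
            for k in range(c, n + 1):
                M[r][k] -= f * M[c][k]
    x = [D(0)] * n
    for r in range(n - 1, -1, -1):
        s = M[r][n]
        for k in range(r + 1, n):
            s -= M[r][k] * x[k]
        x[r] = s / M[r][r]
    return x


def reconstruct4_prefix(a, K, h, greg, n_out):
    # reconstruct g_0..g_{n_out} (n_out <= len(K)); unstable marching, so
    # n_out must be kept within the precision budget by the caller
    g = [D(0)] * (n_out + 1)
    g[0] = D(1)
    eqs = [-1, 0, 1, 2, 3]
    r0 = [resid4(n, g, a, K, h, greg) for n in eqs]
    A = [[D(0)] * 5 for _ in range(5)]
    for k in range(5):
        gk = g[:]
        gk[1 + k] = D(1)
        rk = [resid4(n, gk, a, K, h, greg) for n in eqs]
        for i in range(5):
            A[i][k] = rk[i] - r0[i]
    sol = gauss_solve(A, [-v for v in r0])
    g[1:6] = sol
    for n in range(4, n_out - 1):
        u = n + 2
        g[u] = D(0)
        rA = resid4(n, g, a, K, h, greg)
        g[u] = D(1)
        rB = resid4(n, g, a, K, h, greg)
        g[u] = -rA / (rB - rA)
    return g


def acf_sums(x, n_lag, center):
    n = len(x)
    if center:
        mu = sum(x, D(0)) / n
        x = [v - mu for v in x]
    v0 = sum((v * v for v in x), D(0)) / n
    sums = []
    for k in range(n_lag):
        s = D(0)
        for i in range(n - k):
            s += x[i] * x[i + k]
        sums.append(s)
    return sums, v0


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    digits = int(req.get("digits", 100))
    getcontext().prec = digits + 10
    op = req["op"]
    out = {}
    if op == "acf_sums":
        x = [D(v) for v in req["x"]]
        sums, v0 = acf_sums(x, int(req["n_lag"]), bool(req["center"]))
        out = {"sums": [float(s) for s in sums], "v0": float(v0)}
    elif op == "solve":
        g = [D(v) for v in req["g"]]
        h = D(req["h"])
        greg = int(req["greg"])
        ord_ = int(req["ord"])
        pivot_tol = D(10) ** (-(digits // 2))
        a, K = solve(g, h, greg, ord_, pivot_tol)
        out = {"a": float(a), "K": [float(v) for v in K]}
        if req.get("roundtrip", True):
            if ord_ == 2:
                grec = reconstruct2(a, K, h, greg, g[0])
            else:
                nrt = int(req.get("rt_prefix", 40))
                nrt = min(nrt, len(K))
                grec = reconstruct4_prefix(a, K, h, greg, nrt)
            err = [abs(grec[i] - g[i]) for i in range(len(grec))]
            out["rt_err"] = [float(e) for e in err]
    elif op == "reconstruct2":
        K = [D(v) for v in req["K"]]
        a = D(req["a"])
        h = D(req["h"])
        g = reconstruct2(a, K, h, int(req["greg"]), D(1))
        out = {"g": [float(v) for v in g]}
    elif op == "reconstruct4":
        K = [D(v) for v in req["K"]]
        a = D(req["a"])
        h = D(req["h"])
        g = reconstruct4_prefix(a, K, h, int(req["greg"]), int(req["n_out"]))
        out = {"g": [float(v) for v in g]}
    else:
        raise ValueError("unknown op: %s" % op)
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
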