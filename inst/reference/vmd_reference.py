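"""Independent NumPy reference implementation of variational mode
decomposition, used only as a cross-check oracle in the test suite.

Reads a JSON object {"signal": [...], "rate_hz": r, "K": k, "alpha": a}
on stdin and writes {"center_freqs_hz": [...]} on stdout. Kept deliberately
separate from the package's compiled solver: plain dense full-spectrum
updates, no half-spectrum storage, no shared code.
"""
import json
import sys

import numpy as np


def vmd_center_freqs(x, rate_hz, K, alpha, tau=0.0, tol=1e-7, max_iter=500):
    x = np.asarray(x, dtype=float)
    N = x.size
    h = N // 2
    f = np.concatenate([x[:h][::-1], x, x[N - (N - h):][::-1]])
    T = f.size
    freqs = np.fft.fftfreq(T)           # cycles/sample, unshifted order
    f_hat = np.fft.fft(f)
    f_hat_plus = f_hat.copy()
    f_hat_plus[freqs < 0] = 0.0

    omega = np.array([(0.5 / K) * k for k in range(K)])
    u_hat = np.zeros((K, T), dtype=complex)
    lam = np.zeros(T, dtype=complex)

    for _ in range(max_iter):
        u_prev = u_hat.copy()
        for k in range(K):
            others = u_hat.sum(axis=0) - u_hat[k]
            u_hat[k] = (f_hat_plus - others - lam / 2.0) / (
                1.0 + 2.0 * alpha * (freqs - omega[k]) ** 2)
            u_hat[k][freqs < 0] = 0.0
            p = np.abs(u_hat[k]) ** 2
            if p.sum() > 0:
                omega[k] = np.sum(freqs * p) / p.sum()
        if tau > 0:
            lam = lam + tau * (u_hat.sum(axis=0) - f_hat_plus)
        num = np.sum(np.abs(u_hat - u_prev) ** 2)
        den = np.sum(np.abs(u_prev) ** 2) + 1e-300
        if num / den < tol:
            break
    return np.sort(omega) * rate_hz


def main():
    req = json.load(sys.stdin)
    cf = vmd_center_freqs(req["signal"], req["rate_hz"], int(req["K"]),
                          float(req["alpha"]))
    json.dump({"center_freqs_hz": list(map(float, cf))}, sys.stdout)


if __name__ == "__main__":
    main()
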