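"""Arbitrary-precision evaluation of the difference-of-proportions Z score.

Reads a whitespace-separated table (x_t n_t x_n n_n, no header) from
argv[1] and writes, for each row, `z<TAB>p` evaluated with mpmath at 50
significant digits:

    P_T = X_T/N_T, P_N = X_N/N_N, P_avg = (X_T+X_N)/(N_T+N_N)
    Z = (|P_T - P_N| - (1/N_T + 1/N_N)/2)
        / (P_avg * (1 - P_avg) * sqrt(1/N_T + 1/N_N))
    p = upper-tail standard-normal probability of Z

Rows where the test would be skipped (no coverage or P_T <= P_N) emit NA.
"""
import sys
import mpmath as mp

mp.mp.dps = 50


def main(path):
    for line in open(path):
        if not line.strip():
            continue
        x_t, n_t, x_n, n_n = (mp.mpf(v) for v in line.split())
        if n_t == 0 or n_n == 0:
            print("NA\tNA")
            continue
        p_t, p_n = x_t / n_t, x_n / n_n
        if p_t <= p_n:
            print("NA\tNA")
            continue
        p_avg = (x_t + x_n) / (n_t + n_n)
        inv = 1 / n_t + 1 / n_n
        z = (abs(p_t - p_n) - inv / 2) / (p_avg * (1 - p_avg) * mp.sqrt(inv))
        p = mp.erfc(z / mp.sqrt(2)) / 2  # upper tail of the standard normal
        print(f"{mp.nstr(z, 25)}\t{mp.nstr(p, 25)}")


if __name__ == "__main__":
    main(sys.argv[1])
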