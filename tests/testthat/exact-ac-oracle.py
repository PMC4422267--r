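"""Exact-rational oracle for the two-library tag-count probability.

p(y|x) = C(x+y, y) * N2^y * N1^(x+1) / (N1+N2)^(x+y+1)

evaluated with stdlib integer/Fraction arithmetic (no rounding until the final
conversion to the nearest double). Usage:

    python exact-ac-oracle.py "N1,N2;N1,N2;..." XMAX YMAX > table.tsv

emits columns N1, N2, x, y, p for the full grid x in 0..XMAX, y in 0..YMAX.
"""
import sys
from fractions import Fraction
from math import comb


def main():
    pairs = [tuple(int(v) for v in p.split(",")) for p in sys.argv[1].split(";")]
    xmax, ymax = int(sys.argv[2]), int(sys.argv[3])
    out = sys.stdout
    out.write("N1\tN2\tx\ty\tp\n")
    for N1, N2 in pairs:
        pow_n2 = [N2**y for y in range(ymax + 1)]
        pow_n1 = [N1**k for k in range(xmax + 2)]
        pow_s = [(N1 + N2)**k for k in range(xmax + ymax + 2)]
        for x in range(xmax + 1):
            for y in range(ymax + 1):
                num = comb(x + y, y) * pow_n2[y] * pow_n1[x + 1]
                p = float(Fraction(num, pow_s[x + y + 1]))
                out.write(f"{N1}\t{N2}\t{x}\t{y}\t{p:.17e}\n")


if __name__ == "__main__":
    main()
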