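"""Extended-precision oracle for indicator probabilities.

Reads long-format CSV rows (case, k, weight, rate, t) on stdin-free file
arguments and writes (case, k, p) where p is the normalized value of
weight_k * rate_k * exp(-rate_k * t), computed with 60 significant digits.
"""
import csv
import sys

from mpmath import mp, mpf, exp

mp.dps = 60

cases = {}
with open(sys.argv[1], newline="") as fh:
    for row in csv.DictReader(fh):
        cases.setdefault(row["case"], []).append(row)

with open(sys.argv[2], "w", newline="") as out:
    writer = csv.writer(out)
    writer.writerow(["case", "k", "p"])
    for case, rows in cases.items():
        rows.sort(key=lambda r: int(r["k"]))
        t = mpf(rows[0]["t"])
        terms = [mpf(r["weight"]) * mpf(r["rate"]) * exp(-mpf(r["rate"]) * t)
                 for r in rows]
        total = sum(terms)
        for r, term in zip(rows, terms):
            writer.writerow([case, r["k"], mp.nstr(term / total, 25)])
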