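#!/usr/bin/env python
"""Independent coalescent oracle (msprime) for cross-simulator agreement
tests. Reads a JSON job description, simulates the Mesoamerican-origin
model with founder bottlenecks, ascertains SNPs (pooled MAF filter, fixed
site count per replicate), and reports per-deme nucleotide diversity and
pairwise Weir-Cockerham Fst means with Monte-Carlo standard errors.

Usage: python msprime_oracle.py job.json out.json
"""
import json
import sys

import msprime
import numpy as np

POPS = ["MW", "AW", "PhI"]
PAIRS = [("MW", "AW"), ("MW", "PhI"), ("AW", "PhI")]


def demography(p):
    dem = msprime.Demography()
    dem.add_population(name="MW", initial_size=p["N_MW"])
    dem.add_population(name="AW", initial_size=p["N_AW"])
    dem.add_population(name="PhI", initial_size=p["N_PhI"])
    dur = p["bottleneck_dur"]
    for deme, nf, t in (("AW", p["NF_AW"], p["T1"]),
                        ("PhI", p["NF_PhI"], p["T2"])):
        t0 = max(t - dur, 0)
        if t0 > 0:
            dem.add_population_parameters_change(
                time=t0, initial_size=nf, population=deme)
        else:
            dem.populations[[q.name for q in dem.populations].index(deme)] \
                .initial_size = nf
    # derived demes merge into the constant MW deme
    for deme, t in (("AW", p["T1"]), ("PhI", p["T2"])):
        dem.add_mass_migration(time=t, source=deme, dest="MW", proportion=1.0)
    dem.sort_events()
    return dem


def ascertained_genotypes(ts, n_snps, maf_min, rng):
    """Dosage matrix (sites x diploids) of the first n_snps MAF-passing
    biallelic sites; mutation rate is raised until enough sites pass."""
    L = sum(tree.total_branch_length * tree.span for tree in ts.trees())
    rate = 4.0 * n_snps / L
    for _ in range(12):
        mts = msprime.sim_mutations(ts, rate=rate, discrete_genome=False,
                                    random_seed=int(rng.integers(1, 2**31)))
        rows = []
        n_hap = mts.num_samples
        for var in mts.variants():
            g = var.genotypes
            if len(var.alleles) != 2:
                continue
            c = int(g.sum())
            if min(c, n_hap - c) / n_hap < maf_min - 1e-12:
                continue
            rows.append(g.copy())
            if len(rows) == n_snps:
                break
        if len(rows) == n_snps:
            hap = np.array(rows)
            return hap[:, 0::2] + hap[:, 1::2]
        rate *= 2.0
    raise RuntimeError("could not ascertain enough SNPs")


def pi_per_site(dos):
    n = 2 * dos.shape[1]
    p = dos.sum(axis=1) / n
    return float(np.mean(2 * p * (1 - p) * n / (n - 1)))


def wc_fst(dA, dB):
    n1 = dA.shape[1]
    n2 = dB.shape[1]
    p1 = dA.sum(axis=1) / (2 * n1)
    p2 = dB.sum(axis=1) / (2 * n2)
    h1 = (dA == 1).sum(axis=1) / n1
    h2 = (dB == 1).sum(axis=1) / n2
    nbar = (n1 + n2) / 2
    nc = 2 * nbar - (n1**2 + n2**2) / (2 * nbar)
    pbar = (n1 * p1 + n2 * p2) / (2 * nbar)
    s2 = (n1 * (p1 - pbar) ** 2 + n2 * (p2 - pbar) ** 2) / nbar
    hbar = (n1 * h1 + n2 * h2) / (2 * nbar)
    a = nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b = nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2
                             - (2 * nbar - 1) / (4 * nbar) * hbar)
    c = hbar / 2
    poly = (pbar > 0) & (pbar < 1)
    den = float((a + b + c)[poly].sum())
    return float(a[poly].sum()) / den if den > 0 else np.nan


def main(job_path, out_path):
    with open(job_path) as fh:
        job = json.load(fh)
    p = job["params"]
    sizes = job["sample_sizes"]
    rng = np.random.default_rng(job["seed"])
    dem = demography(p)
    stats = {f"pi_{q}": [] for q in POPS}
    stats.update({f"fst_{a}_{b}": [] for a, b in PAIRS})
    cols = {}
    off = 0
    for q in POPS:
        cols[q] = slice(off, off + sizes[q])
        off += sizes[q]
    for _ in range(job["reps"]):
        ts = msprime.sim_ancestry(
            samples={q: sizes[q] for q in POPS}, demography=dem, ploidy=2,
            sequence_length=1.0, discrete_genome=False,
            random_seed=int(rng.integers(1, 2**31)))
        dos = ascertained_genotypes(ts, job["n_snps"], job["maf_min"], rng)
        for q in POPS:
            stats[f"pi_{q}"].append(pi_per_site(dos[:, cols[q]]))
        for a, b in PAIRS:
            stats[f"fst_{a}_{b}"].append(wc_fst(dos[:, cols[a]],
                                                dos[:, cols[b]]))
    out = {}
    for k, v in stats.items():
        v = np.array(v, dtype=float)
        v = v[~np.isnan(v)]
        out[k] = {"mean": float(v.mean()),
                  "se": float(v.std(ddof=1) / np.sqrt(len(v))),
                  "n": int(len(v))}
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
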