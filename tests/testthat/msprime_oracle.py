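#!/usr/bin/env python
"""Reference distributions of segregating sites and mean pairwise
differences from msprime, used as an independent oracle for the package's
coalescent engine. Writes per-replicate S and pi (pairwise differences per
window, not per site) for three parameter sets."""
import json
import sys

import msprime

REPS = 300
L = 5000
MU = 2e-8
RHO_PER_BP = 0.01  # 4 Ne r


def summarize(ts_iter):
    S, pi = [], []
    for ts in ts_iter:
        mts = msprime.sim_mutations(ts, rate=MU, discrete_genome=False,
                                    model=msprime.BinaryMutationModel())
        S.append(mts.num_sites)
        pi.append(float(mts.diversity(span_normalise=False)))
    return {"S": S, "pi": pi}


def constant():
    ne = 1e5
    return msprime.sim_ancestry(
        samples=5, ploidy=2, population_size=ne,
        sequence_length=L, recombination_rate=RHO_PER_BP / (4 * ne),
        num_replicates=REPS, random_seed=101)


def expansion():
    # size Ne until t = 1e5 generations ago, 10x larger since then
    ne = 1e5
    dem = msprime.Demography()
    dem.add_population(initial_size=10 * ne)
    dem.add_population_parameters_change(time=1e5, initial_size=ne)
    return msprime.sim_ancestry(
        samples=5, ploidy=2, demography=dem,
        sequence_length=L, recombination_rate=RHO_PER_BP / (4 * ne),
        num_replicates=REPS, random_seed=102)


def split():
    ne = 1e5
    dem = msprime.Demography()
    dem.add_population(name="p1", initial_size=ne)
    dem.add_population(name="p2", initial_size=ne)
    dem.add_population(name="anc", initial_size=ne)
    dem.set_symmetric_migration_rate(["p1", "p2"], 1e-6)
    dem.add_population_split(time=2e5, derived=["p1", "p2"], ancestral="anc")
    return msprime.sim_ancestry(
        samples={"p1": 5, "p2": 5}, ploidy=2, demography=dem,
        sequence_length=L, recombination_rate=RHO_PER_BP / (4 * ne),
        num_replicates=REPS, random_seed=103)


def main(out_path):
    out = {"constant": summarize(constant()),
           "expansion": summarize(expansion()),
           "split": summarize(split())}
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1])
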