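"""Coalescent replicate generator emitting ms-format text.

Reads a JSON job description and writes one ms-style block per replicate.
Sizes in the job are DIPLOID deme sizes; because samples are haploid
sequences (ploidy=1), every size is doubled before being handed to msprime
so that the coalescent time scale matches ms's 4*N0 convention.

Job schema:
  N0, theta, rho, length        scalars (theta/rho are 4*N0*mu*l / 4*N0*r*l)
  deme_sizes                    list of diploid sizes
  migration_matrix              square, entries in 4*N0*m units, zero diagonal
  events                        list of {time (4*N0 units), kind, ...}:
                                  kind=="split": source, dest (1-based demes)
                                  kind=="size_change": pop (1-based), size (diploid)
  sample_sizes                  haploid sample count per deme
  seeds                         one RNG seed per replicate

Usage: python simulate_ms.py job.json out.txt
"""

import json
import sys

import msprime


def build_demography(job):
    n0 = job["N0"]
    dem = msprime.Demography()
    for i, size in enumerate(job["deme_sizes"]):
        dem.add_population(name="pop%d" % i, initial_size=2 * size)
    mig = job["migration_matrix"]
    for i in range(len(mig)):
        for j in range(len(mig)):
            if i != j and mig[i][j] > 0:
                # migration_matrix entry is 4*N0*m; msprime wants m per generation
                dem.set_migration_rate(source="pop%d" % i, dest="pop%d" % j,
                                       rate=mig[i][j] / (4.0 * n0))
    for ev in job.get("events", []):
        t_gen = ev["time"] * 4.0 * n0
        if ev["kind"] == "size_change":
            dem.add_population_parameters_change(
                time=t_gen, population="pop%d" % (ev["pop"] - 1),
                initial_size=2 * ev["size"])
        elif ev["kind"] == "split":
            dem.add_mass_migration(
                time=t_gen, source="pop%d" % (ev["source"] - 1),
                dest="pop%d" % (ev["dest"] - 1), proportion=1.0)
        else:
            raise ValueError("unknown event kind: %r" % ev["kind"])
    dem.sort_events()
    return dem


def main(job_path, out_path):
    with open(job_path) as fh:
        job = json.load(fh)
    n0 = float(job["N0"])
    length = float(job["length"])
    mu = job["theta"] / (4.0 * n0 * length)
    rec = job["rho"] / (4.0 * n0 * length)
    dem = build_demography(job)
    samples = {"pop%d" % i: n for i, n in enumerate(job["sample_sizes"])}
    total = sum(job["sample_sizes"])
    seeds = job["seeds"]

    with open(out_path, "w") as out:
        out.write("ascbias-msprime %d %d\n" % (total, len(seeds)))
        out.write("%d\n" % seeds[0])
        for seed in seeds:
            ts = msprime.sim_ancestry(
                samples=samples, demography=dem, ploidy=1,
                sequence_length=length, recombination_rate=rec,
                random_seed=seed)
            mts = msprime.sim_mutations(
                ts, rate=mu, random_seed=seed,
                model=msprime.BinaryMutationModel(), discrete_genome=False)
            positions = [site.position / length for site in mts.sites()]
            nsites = len(positions)
            out.write("\n// seed=%d\nsegsites: %d\n" % (seed, nsites))
            if nsites == 0:
                continue
            out.write("positions: %s\n"
                      % " ".join("%.10f" % p for p in positions))
            geno = mts.genotype_matrix()  # sites x samples, 0/1
            for i in range(total):
                out.write("".join("1" if g else "0" for g in geno[:, i]))
                out.write("\n")


if __name__ == "__main__":
    if len(sys.argv) != 3:
        sys.exit("usage: simulate_ms.py job.json out.txt")
    main(sys.argv[1], sys.argv[2])
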