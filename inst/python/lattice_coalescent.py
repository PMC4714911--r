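"""Stepping-stone lattice coalescent backend.

Reads a JSON scenario config, simulates one genealogy per locus with msprime
under the structured coalescent on the lattice, conditions each locus on a
single segregating site by placing one mutation uniformly on the genealogy's
total branch length, and writes the counted-allele matrix (sampled
populations x loci) as TSV.

Config keys:
  n_row, n_col            full-lattice dimensions (rows = south->north)
  deme_size               per-deme size (coalescent scale)
  m                       nearest-neighbor backward migration rate
  m_diag                  diagonal migration rate
  barrier_row             if > 0, edges connecting rows <= barrier_row to
                          rows > barrier_row have rates divided by
                          barrier_divisor
  barrier_divisor
  events                  list of {type: "mass_migration"|"merge",
                          time, source_deme, dest_deme, proportion}
                          (deme ids are 0-based full-lattice row-major
                          indices from the SW corner; backward-time
                          semantics: lineages in source move to dest)
  sampled_demes           0-based full-lattice indices
  haploids_per_deme
  n_loci
  seed
Usage: python lattice_coalescent.py config.json out_counts.tsv
"""
import json
import sys

import numpy as np
import msprime


def build_demography(cfg):
    R, C = cfg["n_row"], cfg["n_col"]
    demog = msprime.Demography()
    for i in range(R * C):
        demog.add_population(name=f"d{i}", initial_size=cfg["deme_size"])

    def idx(r, c):
        return r * C + c

    brow = cfg.get("barrier_row", 0)
    bdiv = cfg.get("barrier_divisor", 5.0)
    for r in range(R):
        for c in range(C):
            for dr, dc in ((0, 1), (1, 0), (1, 1), (1, -1)):
                r2, c2 = r + dr, c + dc
                if not (0 <= r2 < R and 0 <= c2 < C):
                    continue
                rate = cfg["m"] if (dr == 0 or dc == 0) else cfg["m_diag"]
                if brow > 0 and min(r, r2) + 1 <= brow < max(r, r2) + 1:
                    rate /= bdiv
                if rate > 0:
                    demog.set_migration_rate(f"d{idx(r, c)}", f"d{idx(r2, c2)}", rate)
                    demog.set_migration_rate(f"d{idx(r2, c2)}", f"d{idx(r, c)}", rate)

    for ev in sorted(cfg.get("events", []), key=lambda e: e["time"]):
        prop = 1.0 if ev["type"] == "merge" else ev["proportion"]
        demog.add_mass_migration(time=ev["time"], source=f"d{ev['source_deme']}",
                                 dest=f"d{ev['dest_deme']}", proportion=prop)
    demog.sort_events()
    return demog


def check_connected(cfg):
    """Sampled demes must share one migration-connected component."""
    R, C = cfg["n_row"], cfg["n_col"]
    if cfg["m"] <= 0 and cfg["m_diag"] <= 0:
        comp = {d: {d} for d in cfg["sampled_demes"]}
        if len(comp) > 1:
            raise SystemExit(
                "disconnected lattice: migration rates are zero, sampled demes "
                "cannot share a common ancestor")


def main(cfg_path, out_path):
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    check_connected(cfg)
    demog = build_demography(cfg)
    sampled = cfg["sampled_demes"]
    nh = cfg["haploids_per_deme"]
    samples = {f"d{d}": nh for d in sampled}
    popmap = -np.ones(cfg["n_row"] * cfg["n_col"], dtype=np.int64)
    for i, d in enumerate(sampled):
        popmap[d] = i
    K = len(sampled)
    L = cfg["n_loci"]
    counts = np.zeros((K, L), dtype=np.int64)

    rng = np.random.default_rng(cfg["seed"])
    reps = msprime.sim_ancestry(samples=samples, demography=demog,
                                num_replicates=L, ploidy=1,
                                random_seed=cfg["seed"])
    for li, ts in enumerate(reps):
        tables = ts.tables
        node_time = tables.nodes.time
        child = tables.edges.child
        parent = tables.edges.parent
        bl = node_time[parent] - node_time[child]
        j = rng.choice(len(bl), p=bl / bl.sum())
        tree = ts.first()
        carriers = np.fromiter(tree.samples(child[j]), dtype=np.int64)
        np.add.at(counts[:, li], popmap[tables.nodes.population[carriers]], 1)

    with open(out_path, "w") as fh:
        for i in range(K):
            fh.write("\t".join(map(str, counts[i])) + "\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
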