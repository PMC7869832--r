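"""Two-population out-of-Africa coalescent simulation bridge.

Reads a JSON config, simulates AFR + EUR samples with msprime, and writes
plain binary arrays (int32 positions, uint8 haplotypes or int32 allele
counts) plus a meta.json manifest for the R side to read.

Modes:
  panel  - export phased haplotypes for every sample (site-major uint8)
  counts - export per-site derived-allele counts per population only
           (no genotype matrix; scales to hundreds of thousands of samples)

Only biallelic sites are kept: sites carrying more than one mutation
(multi-allelic or recurrent) are dropped and their count reported.
"""

import json
import sys

import msprime
import numpy as np
import tskit


def build_demography(p):
    d = msprime.Demography()
    d.add_population(name="AFR", initial_size=p["N_afr_modern"])
    eur_now = p["N_eur_initial"] * np.exp(p["eur_growth_rate"] * p["T_eur_growth_gen"])
    d.add_population(name="EUR", initial_size=eur_now, growth_rate=p["eur_growth_rate"])
    d.add_population(name="ANC", initial_size=p["N_afr_modern"])
    d.set_symmetric_migration_rate(["AFR", "EUR"], p["m_afr_eur_recent"])
    d.add_population_parameters_change(
        time=p["T_eur_growth_gen"], population="EUR",
        initial_size=p["N_ooa_bottleneck"], growth_rate=0)
    d.add_symmetric_migration_rate_change(
        time=p["T_eur_growth_gen"], populations=["AFR", "EUR"],
        rate=p["m_afr_ooa"])
    d.add_population_split(
        time=p["T_ooa_split_gen"], derived=["AFR", "EUR"], ancestral="ANC")
    d.add_population_parameters_change(
        time=p["T_afr_expand_gen"], population="ANC",
        initial_size=p["N_ancestral"])
    d.sort_events()
    return d


def recomb_arg(cfg):
    rmap = cfg.get("recombination_map")
    if rmap is None:
        return cfg["recombination_rate"]
    left = list(map(float, rmap["left"])) + [float(cfg["region_length_bp"])]
    return msprime.RateMap(position=left, rate=list(map(float, rmap["rate"])))


def main(cfg_path, out_dir):
    with open(cfg_path) as fh:
        cfg = json.load(fh)

    n_afr = int(cfg["n_afr"]) + int(cfg["n_founders_per_pop"])
    n_eur = int(cfg["n_eur"]) + int(cfg["n_founders_per_pop"])
    seed = int(cfg["seed"])

    ts = msprime.sim_ancestry(
        samples={"AFR": n_afr, "EUR": n_eur},
        demography=build_demography(cfg["demographic_params"]),
        sequence_length=float(cfg["region_length_bp"]),
        recombination_rate=recomb_arg(cfg),
        random_seed=seed,
    )
    ts = msprime.sim_mutations(ts, rate=float(cfg["mutation_rate"]),
                               random_seed=seed + 1)

    muts_per_site = np.bincount(ts.tables.mutations.site,
                                minlength=ts.num_sites)
    keep = np.flatnonzero(muts_per_site == 1)
    n_dropped = int(ts.num_sites - keep.size)
    if keep.size == 0:
        sys.stderr.write(
            "no biallelic segregating site in region of length "
            f"{int(cfg['region_length_bp'])} bp\n")
        sys.exit(3)

    positions = ts.tables.sites.position[keep].astype(np.int32)
    afr_samples = ts.samples(population=0)
    eur_samples = ts.samples(population=1)
    # sample ids are contiguous per population block; R relies on this
    assert np.array_equal(afr_samples, np.arange(2 * n_afr))
    assert np.array_equal(eur_samples, 2 * n_afr + np.arange(2 * n_eur))

    if cfg["mode"] == "panel":
        var = tskit.Variant(ts)
        with open(f"{out_dir}/haplotypes.bin", "wb") as fh:
            buf = []
            for j, site in enumerate(keep):
                var.decode(int(site))
                buf.append(var.genotypes.astype(np.uint8))
                if len(buf) == 512 or j == keep.size - 1:
                    fh.write(np.concatenate(buf).tobytes())
                    buf = []
    else:  # counts
        site_of_mut = ts.tables.mutations.site
        node_of_mut = ts.tables.mutations.node
        keep_mask = np.zeros(ts.num_sites, dtype=bool)
        keep_mask[keep] = True
        ac_total = np.zeros(keep.size, dtype=np.int32)
        ac_afr = np.zeros(keep.size, dtype=np.int32)
        row = {s: i for i, s in enumerate(keep)}
        for tree in ts.trees(tracked_samples=afr_samples):
            for site in tree.sites():
                sid = site.id
                if not keep_mask[sid]:
                    continue
                node = site.mutations[0].node
                i = row[sid]
                ac_total[i] = tree.num_samples(node)
                ac_afr[i] = tree.num_tracked_samples(node)
        ac_eur = ac_total - ac_afr
        ac_afr.tofile(f"{out_dir}/counts_afr.bin")
        ac_eur.tofile(f"{out_dir}/counts_eur.bin")

    positions.tofile(f"{out_dir}/positions.bin")
    meta = {
        "mode": cfg["mode"],
        "n_sites": int(keep.size),
        "n_dropped_multiallelic": n_dropped,
        "n_haplotypes": int(ts.num_samples),
        "n_afr_haplotypes": int(2 * n_afr),
        "n_eur_haplotypes": int(2 * n_eur),
        "region_length_bp": int(cfg["region_length_bp"]),
    }
    with open(f"{out_dir}/meta.json", "w") as fh:
        json.dump(meta, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
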