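# mdscape

Population-based analysis of molecular dynamics (MD) trajectories of the
stearoyl-CoA desaturase-1 (SCD1) substrate-binding tunnel — and of any
system where the question is "how do a pair of hydrogen-bond distances
gate a ligand torsion?".

SCD1 desaturates stearoyl-CoA at the C9-C10 bond. Its binding tunnel is
kinked by hydrogen bonding among Gln147, Trp153 and Thr261, and the
reaction requires the substrate's C8-C9-C10-C11 torsion chi to reach the
*actionable* negative gauche conformation near -60 degrees. `mdscape`
measures that coupling:

- **Geometry**: interatomic distances and IUPAC-signed proper dihedrals
  per frame, atoms addressed by residue number + PDB atom name
  (`Gln147 OE1`, `Trp153 HE1`, `Gln147 HE22`, `Thr261 OG1`, ligand
  `C8...C11`); plus internal-coordinate (NeRF) chain placement.
- **Free-energy landscapes**: paired distances binned in tenths of
  angstrom; per bin, dG = -kT ln(rho_i / rho_max), with unsampled bins
  held at a 10 kT sentinel; kT-level population tables, minima and
  secondary basins; per-replicate histograms pool by absolute bin edge.
- **Conformer statistics**: torsion distribution rho(chi), profile
  phi = -0.6 ln rho(chi) in kcal/mol, gauche/trans classification, and
  the actionable fraction conditioned on a both-pairs <= 2.5 A
  hydrogen-bond criterion.
- **Pocket volumetrics**: grid-occupancy volume of a 6 A sphere
  following the ligand's 5th tail carbon (1.4 A probe, Bondi radii).
- **Synthetic trajectories**: a two-state (kinked/open) Markov generator
  with per-state Gaussian distances and von Mises torsion mixtures,
  embedded exactly into a toy topology — ground-truth-labelled data for
  validating every stage without the (undeposited) production
  trajectories.
- **I/O**: multi-model PDB and CHARMM DCD read/write.

## Worked example

Five synthetic replicates of the substrate system under the standard
study conditions, pooled into a landscape:

```r
library(mdscape)

model <- preset_model("substrate")
reps <- lapply(1:5, function(r)
  simulate_trajectory(model, 10000, seed = 100 + r,
                      replicate_id = paste0("substrate_rep", r)))
obs <- lapply(reps, function(lt) {
  ser <- extract_series(lt$trajectory, tunnel_specs())
  list(d1 = series_values(ser, "Gln147-Trp153"),
       d2 = series_values(ser, "Gln147-Thr261"),
       chi = series_values(ser, "C8-C9-C10-C11"))
})
pooled <- pool_histograms(lapply(obs, function(o)
  bin2d(o$d1, o$d2, 0.1, "Gln147-Trp153", "Gln147-Thr261")))
fes <- free_energy(pooled)
print(fes)
#> <fes> Gln147-Trp153 vs Gln147-Thr261: minimum at (1.95, 2.15) A holding 5.63% of 50000 observations

head(level_populations(fes), 4)
#>   level_kT percent
#> 1        1  60.722
#> 2        2  20.608
#> 3        3   5.670
#> 4        4   3.788

ca <- conditional_actionable(unlist(lapply(obs, `[[`, "chi")),
                             unlist(lapply(obs, `[[`, "d1")),
                             unlist(lapply(obs, `[[`, "d2")))
conditional_table(ca)
#>         class n_frames n_actionable   fraction
#> 1     hbonded    44443         8109 0.18245843
#> 2 not_hbonded     5557          325 0.05848479
```

Reading the output: the pooled landscape minimum sits in the bin whose
center is (1.95, 2.15) A — within one 0.1 A bin of the generator's
kinked-state means (2.0, 2.2) A — and holds 5.6% of all observations.
The level table says 60.7% of frames lie within 1 kT of the minimum.
The conditional report shows the actionable contrast the substrate
system is built around: 18.2% of hydrogen-bonded frames have chi within
5 degrees of -60, versus 5.8% of non-bonded frames (the non-bonded class
mixes open-state frames with kinked-state excursions, so its fraction
sits above the open state's 3.5% torsion mass — `mdscape::
model_conditional_actionable()` gives the model-implied values).

The same pipeline runs from the command line:

```sh
Rscript scripts/mdscape.R generate --preset substrate --n-frames 10000 \
    --seed 1 --outdir runs/rep1
Rscript scripts/mdscape.R analyze --config run.yaml
```

where `run.yaml` lists replicate `topology`/`frames` paths and any
non-default parameters (hydrogen-bond cutoff, bin widths, pocket region,
...). The analysis writes per-replicate and pooled landscape CSVs, the
kT-level table, the torsion PMF, the conditional report and optional
pocket-volume series, each stamped with a config hash.

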