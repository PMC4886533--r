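# myoquant

Quantitative pipeline for studies of protease activity and failing muscle
regeneration in dystrophic (mdx^4cv) mouse muscle. The package
re-implements, as tested R code, the three bespoke analysis stages such a
study relies on, plus a ground-truthed synthetic-data generator that makes
every stage verifiable without any external data:

1. **Micrograph quantification** — split fluorescence channels (DAPI
   nuclei + MyHC/laminin/elastase/Ly6G marker), threshold them with the Li
   (minimum cross-entropy) or Triangle method, separate touching nuclei by
   watershed on the Euclidean distance transform, remove inseparable
   clusters above 900 px, and compute marker areas and myogenesis indices
   by mask logic. With N total nuclei, N_m nuclei inside marker-positive
   components and N_t nuclei in myotubes (components with ≥ 2 nuclei):

       differentiation index DI = N_m / N
       fusion index          FI = N_t / N_m

2. **Elastase activity kinetics** — blank-subtract plate-reader series of
   a fluorogenic elastase substrate (Suc-Ala-Ala-Ala-AMC), average the 3
   technical replicates, extract the inhibitor-sensitive fraction
   `sens(t) = uninhibited(t) − inhibited(t)` from the averaged curves, and
   summarise least-squares rates and percent inhibition
   `1 − rate_inhibited / rate_uninhibited` with propagated SE.

3. **Label-free differential abundance** — retain peptide features with
   charge 2+..7+, normalise runs by median log-ratio to the most complete
   run, quantify proteins as the **sum of unique peptide abundances**
   (shared peptides excluded), check replicate R², then per age group run
   a two-group ANOVA (WT vs Dys, log scale) with Bonferroni correction
   `q = min(1, p·m)`; proteins are tiered moderate (p < 0.05) or strong
   (q < 0.05).

The synthetic generators emulate the study design: micrographs with known
nucleus positions and memberships (including touching nucleus pairs that
merge under thresholding), linear product-accumulation kinetics with and
without inhibitors, and log-normal peptide tables over the 2 genotype × 2
age × 5 replicate design with a Serpinb1a-like protein planted at 6-fold
(3 months) and 7-fold (7.5 months) in the dystrophic runs.

## Worked example

```r
library(myoquant)

## ground-truthed scene: 40 nuclei, 3 myotubes x 3 nuclei, 3 mononucleated
## marker cells -> true DI = 12/40 = 0.30, FI = 9/12 = 0.75
sc  <- simulate_image(image_sim_params(seed = 3))
res <- quantify_image(sc$rgb)
res
#> Myogenesis indices:
#>   nuclei: 40 total, 12 in marker, 9 in myotubes
#>   myotubes: 3 (marker area 8777 px, 13.4% of image)
#>   differentiation index: 0.300   fusion index: 0.750

## kinetics: rate 2 AU/min, inhibitor removing half the activity
pl <- process_plate(simulate_kinetics(kinetic_sim_params(noise_sd = 0)))
pl$rates
#>   condition inhibitor rate_uninhibited rate_inhibited percent_inhibition
#> 1    sample  cocktail                2              1                0.5

## proteomics: 100 proteins, one planted at 6-fold in the 3-month group
ds  <- data.frame(protein = "P0001", age_group = "3", fold_change = 6)
sim <- simulate_peptide_table(proteome_sim_params(n_proteins = 100,
                                                  differential_spec = ds))
pep <- normalize_runs(filter_peptides(sim$peptides), sim$design)
mat <- rollup_proteins(pep, sim$design)
r3  <- differential_test(mat, sim$design, "3")
head(r3[order(r3$q_value), ], 1)
#>   protein age_group fold_change      p_value      q_value   tier flag
#> 1   P0001         3    5.552674 9.436709e-09 9.436709e-07 strong <NA>
```

(All generators default to `seed = 1`; the printed numbers are exactly
what the code produces at these seeds.)

## Analysis workflow

The numbered scripts under `analysis/` run the whole synthetic study over
the package functions and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R           # raw data + ground truth
Rscript analysis/02_image_quantification.R     # indices vs ground truth
Rscript analysis/03_elastase_kinetics.R        # sensitive fractions, rates
Rscript analysis/04_proteomics_differential.R  # rollup, QC, ANOVA + Bonferroni
```

The last stage, for example, reports (seeded, reproducible):

```
replicate QC: mean R^2 within groups 0.988, between genotypes 0.985
3 months: 535 tested, 31 at p<0.05, 1 at q<0.05
  top by q: P0001, fold 5.98 (planted P0001 at 6-fold), q = 8.30e-07
7.5 months: 535 tested, 29 at p<0.05, 1 at q<0.05
  top by q: P0001, fold 6.58 (planted P0001 at 7-fold), q = 9.63e-07
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch against the installed package —
simulating the study inputs at the given seed, quantifying the
micrographs, processing the kinetic plates and running the differential
stage — and writes the acceptance JSON to `--out`, logging a stage-by-
stage summary to stderr. The property-based acceptance checks themselves
(threshold-oracle equivalence, segmentation ground-truth recovery, mask
and size-filter invariants, kinetics additivity and recovery, statistical
calibration and effect recovery, rollup contracts, byte-level
determinism) live in `tests/testthat/test-acceptance.R` and run with the
normal test suite.
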