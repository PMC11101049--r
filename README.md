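# nemadisp

Spatial metacommunity analysis of nematode distributions in mountain
lakes: does a species' **female proportion** (a colonisation trait —
many nematodes are parthenogenetic, so one female can found a
population) or its **body size** (a wind-transport trait) shape the
spatial structure of where it occurs?

The package is for community ecologists analysing presence/absence data
across isolated sites (lakes, ponds, islands) who want to separate
dispersal-driven spatial pattern from environmentally driven pattern,
per species, and then compare that separation across species against
traits.

## The method

1. **Spatial predictors.** Lake coordinates are projected to a local
   plane; distances above the longest minimum-spanning-tree edge `t`
   are truncated to `4t`; the Gower-centred matrix
   `B = H(-d²/2)H` is eigendecomposed. Positive eigenvectors (PCNM
   axes) are orthogonal spatial waveforms classed large/medium/small
   scale by eigenvalue.
2. **Per-species GLMs.** Presence/absence ~ binomial(logit), forward
   selection by BIC within five candidate pools (three spatial scales,
   environment, altitude). A step is accepted iff BIC drops, the
   deviance χ² test has *P* < 0.05, and the fit has no boundary
   probabilities; boundary/non-convergent candidates are replaced by
   the next on the BIC list.
3. **Deviance partitioning.** The merged model's
   `adj-D² = 1 − ((n−1)/(n−p))(1−D²)` is split by leave-subset-out into
   fractions unique to each pool plus a shared remainder (negative
   values legal).
4. **Moran's I** per species under binary MST-threshold connectivity,
   tested with the normality variance against `E[I] = −1/(n−1)`.
5. **Trait models across species.** Unique fractions (÷100, zeros kept)
   ~ trait via zero-one-inflated beta regression with the Δ≥4
   information-criterion rule; Spearman rank tests as complements; and
   a Gaussian GAM of Moran's I on each trait with a df-4 smoothing
   spline. Per-lake female proportion and relative body size are also
   regressed on altitude.

A seeded synthetic generator (`synth_metacommunity()`) produces full
input sets with known ground truth for calibration and power checks.

## Worked example

The package ships the published per-species summary table and
deviance-partition table from a survey of 75 Pyrenean mountain lakes
(31 determined taxa, 4131 individuals, 3018 adults; 20 species pass
the ≥4-lakes / ≥6-adults filters).

```r
library(nemadisp)
tab  <- survey_species_table()
part <- survey_partition_table()
i <- match(part$species, tab$taxon)

# Do female-poor species carry more unexplained large-scale structure?
spearman_rho(tab$afp[i], pmax(part$large, 0))
#> $rho        -0.5816324
#> $p_value    0.007143921
#> $n          20

# Does the spatial-clustering ~ female-proportion relation survive
# removing the lowest-female-proportion species?
k <- which.min(tab$afp[i])
g <- gam_spline(tab$afp[i][-k], tab$moran_i[i][-k], df = 4)
g
#> smoothing-spline GAM: edf 4.00, adj-D2 54.1%, BIC -119.44
#> parametric (linear) p = 0.3805, nonparametric p = 0.002636, n = 19
```

Interpretation: the rank correlation is negative and significant —
species with fewer females have more of their distribution explained
uniquely by large-scale spatial structure, the signature of dispersal
limitation — and the spline of Moran's I on female proportion still
keeps over half the deviance after the robustness removal, with the
signal in the nonlinear component.

A full synthetic run:

```r
sim <- synth_metacommunity(synth_config(seed = 1))
run <- run_pipeline(sim$lakes, sim$counts, sim$morphometry, out_dir = "results/")
run
```

writes the trait, selection, partition, Moran, trait-model and
lake-summary tables plus a JSON summary and YAML config copy.

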