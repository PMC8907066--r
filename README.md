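# paleostruct

Population structure and demography from low-coverage ancient-DNA genotype
panels.

Ancient-DNA capture datasets typically consist of pseudohaploid genotypes
(one sequencing read sampled per site) at up to ~1.2 million SNPs, with
coverage spanning three orders of magnitude across individuals and most
cells missing. paleostruct implements, as tested reusable R code, the
statistical pipeline used to characterize deep population structure in
such panels:

- **f-statistics with a consistent f2 basis.** Block-jackknifed f2/f3/f4
  with the standard finite-sample bias corrections, and a
  system-of-equations estimator that computes every raw statistic on its
  own maximal SNP set, then solves for a single pairwise-f2 basis by
  inverse-variance weighted least squares — so all derived statistics are
  mutually consistent (identities like
  f4(A,B;C,D) = [f2(AD)+f2(BC)−f2(AC)−f2(BD)]/2 hold exactly) while usable
  coverage is maximized under missing data.
- **Rank tests for the number of ancestry streams** from the rank of the
  f4 matrix X<sub>ij</sub> = f4(l<sub>i</sub>, l<sub>1</sub>;
  r<sub>j</sub>, r<sub>1</sub>), with chi-squared "tail" and "taildiff"
  P values.
- **Mixture-proportion fitting** (K-way, sum-to-one GLS on f4 systems)
  with jackknife standard errors.
- **Excess relatedness**: residuals of outgroup-f3 statistics against the
  independent-mixture prediction α<sub>X</sub>ᵀ M α<sub>Y</sub>, plotted
  against haversine distance (plus a 0.001 km dummy) and summarized by an
  inverse-variance-weighted fit of y = 1/(mx + a) + b with decay scale
  (e−1)·a/m.
- **Kin detection** from pairwise allele-mismatch ratios (unrelated ≈ 2×
  the within-individual rate, duplicates ≈ 1×, relatives intermediate).
- **Recent effective population size** from runs of homozygosity: a
  genotype-likelihood Viterbi HMM caller, gap-merging and >4 cM filtering,
  and a Poisson-process maximum-likelihood Ne with profile-likelihood 95%
  intervals (possibly unbounded above).
- **Synthetic data**: admixture-graph frequency simulation
  (Balding–Nichols drift), geographic ancestry clines with hierarchical
  shared drift and known truth, read-level coverage/contamination, ROH
  length spectra — so the whole pipeline is testable offline.

See `vignettes/methods.Rmd` for the models, assumptions, parameter
defaults and numerical choices.

## Worked example

```r
library(paleostruct)

# simulate a geographic three-way ancestry cline with same-site excess drift
sc  <- cline_scenario(inds_per_site = 2, coverage = 0.5)
sim <- simulate_cline_dataset(sc, n_snps = 20000, seed = 42)
blocks <- build_blocks(sim$table$snp)
sim$table
#> genotype_table: 20000 SNPs x 52 individuals (23.4% missing)

# three-way mixture proportions for one individual (truth: 0.62/0.19/0.19)
fit_mixture(sim$table, "WK1_I1", c("S_E", "S_C", "S_S"),
            c("Neand", "WAfr", "AkaL", "KhoL", "AgawL"), blocks)
#> mixture_fit: WK1_I1 ~ 0.618 (se 0.070) S_E + 0.250 (se 0.069) S_C
#>   + 0.133 (se 0.072) S_S
#>   chisq = 0.152, dof = 2, P = 0.927

# excess relatedness records: outgroup-f3 residuals vs distance
f3    <- outgroup_f3_pairs(sim$table, "Neand", sim$coords$ind_id, blocks)
model <- fit_source_f3_matrix(f3, sim$truth$alpha)
pts   <- excess_relatedness_residuals(model, sim$coords)  # id1 id2 x y var_y

# the decay curve on points with known truth (m = 0.05, a = 1, b = 0.2;
# true decay scale 34.4 km)
fit_decay_curve(simulate_decay_points(0.05, 1, 0.2,
                                      seq(0.001, 400, length.out = 50),
                                      noise_vars = 1e-4, seed = 7))
#> decay_fit: y = 1/(0.05108 x + 0.9917) + 0.2041  (n = 50, wRSS = 48.53)
#>   decay scale = 33.36 km

# recent Ne from a simulated ROH length spectrum (truth: 500)
estimate_ne(simulate_roh_blocks(500, seed = 11))
#> ne_estimate: Ne = 681, 95% CI = 361-1505 (8 blocks in 4-Inf cM)
```

The mixture proportions land within one standard error of the generating
truth, the fitted decay scale sits within 5% of the generating value, and
the Ne interval covers the generating population size. On the default
cline scenario most excess relatedness is concentrated in same-site pairs
(the generator's shared drift is hierarchical, not a smooth spatial
process), so a decay fit to `pts` collapses to a sub-kilometre scale —
the behaviour expected when the signal comes almost entirely from
same-site pairs.

A command-line front end covering conversion, simulation, f-statistics,
rank/mixture fits, decay fitting and Ne estimation is installed as
`exec/paleostruct` (see `?paleostruct_cli`).

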