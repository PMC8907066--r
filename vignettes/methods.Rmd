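---
title: "Models and methods in paleostruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in paleostruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleostruct)
```

paleostruct analyzes low-coverage ancient-DNA genotype panels: capture-array
SNP data where most individuals are represented by pseudohaploid calls (one
sequencing read sampled per site) with heavy, individual-specific
missingness. This vignette explains the statistical models the package
implements, the tunable parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Genotypes, frequencies and bias corrections

Genotypes count copies of the first panel allele: diploid individuals
contribute values 0/1/2 and two alleles to the sample size; pseudohaploid
individuals contribute values 0/2 (a single sampled allele) and one allele.
The population frequency estimate at a SNP is the allele-count mean, and
the unbiased within-population heterozygosity estimate
$\hat h = n\,\hat p(1-\hat p)/(n-1)$ feeds the finite-sample corrections:
$f_2$ subtracts $\hat h_X/n_X + \hat h_Y/n_Y$, $f_3(X;Y,Z)$ subtracts
$\hat h_X/n_X$ for its target, and $f_4$ needs no correction. When a
population is a single pseudohaploid individual ($n = 1$), $\hat h$ is
undefined and is treated as zero: $f_4$-based analyses (rank tests, mixture
fits) are unaffected, but $f_2$ and target-side $f_3$ involving such
populations retain the sampling-noise inflation. This is the standard
limitation of single-individual "populations" and is why the downstream
residual model is built on cross-individual statistics only.

## Block jackknife

Standard errors come from a weighted delete-one-block jackknife over
contiguous blocks of at least 0.05 Morgans (configurable), never spanning
chromosomes. Weights are block SNP counts; with equal weights the estimator
reduces to the classical delete-one formula
$\mathrm{se}^2 = \frac{B-1}{B}\sum_j(\hat\theta_{-j}-\bar\theta)^2$, which
the tests assert as a special case. Covariances between statistics use the
vector generalization with the same weights.

## The consistent f2 basis

With missing data, each raw f-statistic is computable on its own maximal
SNP set ("allsnps" behaviour), but the resulting collection is mutually
inconsistent: identities like
$f_4(A,B;C,D) = \tfrac12(f_2(AD)+f_2(BC)-f_2(AC)-f_2(BD))$ fail across
statistics estimated on different sites. The basis solver computes every
raw $f_2$, $f_3$ and $f_4$ among the chosen populations, writes each as a
linear function of the $n(n-1)/2$ pairwise-$f_2$ parameters through the
identities, and solves the overdetermined system by weighted least squares
with inverse jackknife-variance weights, treating raw statistics as
independent given those weights (a diagonal weight matrix; the released
implementation of this idea may use a richer covariance, which is why the
package asserts exact oracle equivalence only on complete data and a
3-combined-se bridge under masking). The entire solve is repeated deleting
one block at a time to give the basis covariance, from which any derived
statistic inherits an se. All statistics derived from one basis satisfy the
identities exactly. Degenerate systems are solved by pseudoinverse with a
fixed tolerance of 1e-10 so behaviour on collinear input is deterministic.

## Rank tests and mixture fits

The number of ancestry streams relating test individuals to outgroups is
assessed through the rank of $X_{ij} = f_4(l_i, l_1; r_j, r_1)$: rank $k$
means $k+1$ sources. The package minimizes
$(\mathrm{vec}(X)-\mathrm{vec}(X_k))^\top Q^{-1}(\cdot)$ over rank-$k$
matrices by alternating generalized least squares on the bilinear
factorization $X_k = AB^\top$ (initialized from the SVD; the objective is
monotonically non-increasing and iteration stops at a 1e-12 relative
change). $Q$ is the block-jackknife covariance; if singular it is
ridge-regularized with an escalating multiple of the mean diagonal and a
warning. Absolute fit is the chi-squared tail P at
$(L-1-k)(R-1-k)$ dof; "taildiff" Ps compare consecutive ranks through the
chi-squared difference.

Mixture proportions solve
$f_4(T,R_1;R_j,R_1)=\sum_k \alpha_k f_4(S_k,R_1;R_j,R_1)$ under
$\sum\alpha=1$ by GLS, with ses from delete-one-block re-solves (the
weighting matrix held fixed, as is conventional). Sources collinear
relative to the outgroups — e.g. two sources forming a clade — give a
normal-matrix condition number above 1e8 and an explicit error. Negative
estimates are reported unclipped with a warning: clipping is a presentation
choice that would bias the downstream residual model.

## Excess relatedness and its decay with distance

Under the null that each individual is an independent mixture of the K
ancestry components, the expected outgroup-f3 between individuals X and Y
is the bilinear form $\alpha_X^\top M \alpha_Y$ with $M$ the symmetric
matrix of source-pair shared drifts. $M$ is fit by inverse-variance
weighted least squares over all pairs; each pair's *excess score*
(observed minus fitted) measures shared drift unaccounted for by ancestry
proportions. Both the residual (fitted minus observed) and the excess score
are reported; the decay analysis consumes the positive-excess score, under
which extra sharing is positive. Estimation is two-stage — proportions
first, then $M$ given proportions — with no iteration, keeping the
procedure deterministic; extra admixture components (food-producer
ancestry, contamination) enter as locked columns of the proportion matrix
so they cannot compensate for model misfit. Pairs flagged by the kin test
are excluded before curve fitting.

Distances are haversine great-circle distances on a 6,371 km sphere (the
standard mean Earth radius; the choice is inconsequential at the precision
of the analysis) plus a dummy 0.001 km so same-site pairs sit at a finite
distance. The decay curve $y = 1/(mx+a)+b$ is fit by inverse-variance
weighted least squares. The surface has near-flat directions (rescaling
$m$ and $a$ jointly trades off against $b$), so the optimizer uses a
deterministic multi-start — a log grid over $m$, $a$ from the
short-distance amplitude, $b$ from the long-distance tail — refined by
`nlminb` on $(\log m, \log a, b)$, which enforces $mx+a>0$. The decay
scale $(e-1)\,a/m$ is the distance at which the amplitude above baseline
falls to $1/e$; a vertical translation of all points is absorbed exactly
by $b$, reflecting that a score of zero has no special meaning.

## Kin detection

For a pair of individuals, one read is sampled per site from each and the
allele mismatch rate is compared with the within-individual rate obtained
by drawing two reads without replacement at sites with at least two reads.
For unrelated individuals the expected ratio is 2 (mismatch probability
$2p(1-p)$ against $p(1-p)$), for duplicates 1, for parent–child 1.5. Band
thresholds are the midpoints 1.25 and 1.75 between these anchors.

## ROH calling and recent Ne

Runs of homozygosity are called per individual from normalized
Phred-scaled genotype likelihoods (computed from allele read counts under
a symmetric per-read error model, default 1e-2 — the converter's model is
an assumption, flagged as such, since only the normalization is pinned
down externally). The caller is a two-state Viterbi HMM: the non-ROH state
uses Hardy–Weinberg genotype priors at a single default allele frequency
of 0.4 (0.36/0.48/0.16), the ROH state allows heterozygotes with
probability 1e-3, and switch probabilities over a gap of $d$ bp are
$1-e^{-\rho d}$ with $\rho = 6.7\times10^{-8}$ (into ROH) and
$5\times10^{-9}$ (out of ROH) — the documented defaults of the standard
caller this stage mirrors, of which only the allele frequency is
overridden in practice. Postprocessing merges blocks separated by a gap
under 0.5 cM with at most two apparent heterozygous sites, then retains
blocks longer than 4 cM.

Block lengths $\ell$ (Morgans) in a window $[u,v]$ are modelled as an
inhomogeneous Poisson process with intensity
$$\lambda(\ell;N)=\sum_{g=1}^{500}\pi_g(N)\sum_i\big[(2g)^2\max(G_i-\ell,0)+2(2g)\big]e^{-2g\ell},
\qquad \pi_g(N)=\tfrac{1}{2N}\big(1-\tfrac{1}{2N}\big)^{g-1},$$
over 22 autosomes totalling about 35.4 Morgans. The truncation at 500
generations changes the intensity above 4 cM by less than 1e-6 relative at
N = 100. The integral $\Lambda$ has a closed form (asserted against
numeric quadrature in the tests), the log-likelihood
$-\Lambda(N)+\sum_k\log\lambda(\ell_k;N)$ is maximized over $\log N$, and
the 95% interval is the profile-likelihood interval (drop of 1.92
log-units), reported as unbounded above when the likelihood never crosses
the threshold — which reproduces the asymmetric, sometimes one-sided
intervals this analysis produces on real data. With zero blocks the
likelihood is monotone in $N$ and the MLE sits at the search bound with an
unbounded upper limit. Individuals whose blocks longer than 12 cM total
more than 100 cM (about half the first-cousin expectation; the threshold
is a configurable stand-in since no numeric rule is pinned down) are
flagged for analysis on the 4–8 cM window.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes, not
sequence-level reality. Allele frequencies drift down an admixture graph
in Balding–Nichols fashion (child Beta-distributed around the parent with
variance $F p(1-p)$), which matches the variance parameterization
f-statistics measure and is fast at desk scale. The default demographic
graph has a deep outgroup, a west-African-related outgroup and three
deeply diverged source lineages, each paired with a cousin outgroup so the
sources are distinguishable in f4 space. The default cline scenario mixes
the three sources per site with proportions matching the study region's
pattern — 62/19/19 in the northwest of the cline, 54/12/34 in its centre,
and 20–30/5–10/60–70 in the south — over realistic site coordinates, and
draws per-individual capture coverage log-normally with median 0.06x,
truncated to the observed range 0.001–3.2x.

Excess relatedness is generated hierarchically (site below cluster):
members of a cluster share a Gaussian frequency perturbation of absolute
variance $\delta_{cluster}$, and site-mates share a further
$\delta_{site}$, so any same-site pair carries a known excess shared drift
of exactly $\delta_{cluster}+\delta_{site}$ in f2 units. Defaults are
$\delta_{site}=0.005$ and $\delta_{cluster}=0.002$, on the scale of the
small within-cluster drift branches the residual analysis is designed to
detect. This is exactly the model class the residual analysis assumes,
with analytically known truth — deliberately so: a green spike-in test
establishes that the estimator recovers shared drift under its own model
class, not that real data obey that class. Read-level contamination is
modelled by redirecting each read to a contaminant node's frequency with
probability $c$, mirroring how contamination enters real ancient-DNA
libraries before pseudohaploid calling. What the generator does *not*
emulate: linkage disequilibrium within blocks (SNPs are exchangeable given
the frequencies, so jackknife blocks are calibrated by construction rather
than by LD decay), post-mortem damage profiles, reference bias, and
non-stationary coverage along the genome.

Every generator is a pure function of its specification and an explicit
integer seed; truth records carry the generating parameters so a dataset
can be regenerated bit-identically.

## Scaling choices in the tests

The acceptance suite runs the stated operating-characteristic checks
(90/100-style replicate counts) at desk scale: the rank-test power check
uses the pinned 100,000-SNP panels, while checks that do not pin a panel
size use 15,000–40,000 SNPs so the whole suite stays within a
25-minute single-core budget. Replicate SNP panels are scaled-down
stand-ins for a ~1.2M-SNP capture array; the jackknife resolution
(several hundred blocks) is preserved.

## Known limitations

The basis solver's diagonal weighting is a stated simplification of the
fuller system it emulates. Single-individual populations leave $f_2$-type
quantities uncorrected for sampling noise. The rank-test chi-squared
construction uses the standard jackknife covariance without
small-block-count corrections, so with very few usable blocks the tail P
values are approximate. The ROH caller assumes sites are conditionally
independent given the hidden state (no linkage disequilibrium within
either state), which is adequate for the long (>4 cM) blocks used here
but would overcall short ROH on dense panels.
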