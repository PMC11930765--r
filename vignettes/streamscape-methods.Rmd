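---
title: "Methods: riverscape genomics for assisted-migration planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: riverscape genomics for assisted-migration planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamscape)
```

## The problem

Small stream fishes in dendritic river networks disperse only along the
water. Fragmentation — stream drying, dams, reservoirs — cuts drainages
into small, isolated demes that lose heterozygosity to drift and may
accumulate inbreeding. Managers weighing assisted gene flow need, from
genotype data alone: (i) which landscape features restrict gene flow,
(ii) which populations are small, isolated, inbred or loaded with
deleterious variation (candidate *recipients*), and (iii) which
populations could donate migrants with minimal outbreeding risk
(candidate *donors*). `streamscape` implements that full chain and a
synthetic generator that makes every stage testable without field data.

## Diversity and differentiation

Per-site gene diversity uses the Nei & Chesser (1983) small-sample
estimator, per locus

$$\hat H_S = \frac{\tilde n}{\tilde n - 1}\Big(1 - \sum_a \hat p_a^2 -
\frac{H_O}{2\tilde n}\Big),$$

averaged over loci (`expected_heterozygosity()`, with a naive
\(1-\sum \hat p^2\) mode). Pairwise differentiation is available as
Weir & Cockerham's variance-components \(\theta\) (ratio of summed
per-locus components) and as the Nei gene-diversity form
\((H_T - H_S)/H_T\) with the same small-sample corrections. The source
study names a "Watterson's FST" for its metapopulation comparisons; no
standard estimator of that name exists, so both conventional estimators
are provided and tested against loop-wise reimplementations to 1e-12.
Negative multilocus estimates are reported as-is; the linearization
\(F_{ST}/(1-F_{ST})\) used as a regression response truncates at zero so
responses stay finite, and a fixed pair maps to `Inf`.

SNP panels are pruned in the order: call rate (default ≥ 0.8), MAF
(≥ 0.05), a greedy 2 kb proximity scan that keeps the first locus of any
close-spaced run, then greedy LD pruning that drops the lower-MAF member
of any same-chromosome pair with dosage \(r^2 > 0.5\). The LD "weight"
of the source pipeline's pruning tool is not published; squared dosage
correlation is the conventional, testable reading.

## River-network engine

A network is a downstream-oriented tree (one outgoing edge per node,
positive lengths, single outlet). Distances between sites are undirected
path lengths with partial traversal of the host edges — fish move both
ways; flow direction matters only for identifying the outlet and the
furthest-downstream site, which anchors each metapopulation's upstream
distances (ties broken by site id, with a warning). Path covariates are
length-weighted means of per-edge attributes (intermittency fraction and
four land-cover fractions) plus a count of barrier edges crossed.
Length-weighting of the intermittency proportion is an implementation
choice; a segment-count definition would differ on heterogeneous paths.
Land cover is modelled as per-edge fractions: raster buffer extraction
is upstream preprocessing, out of scope.

## Isolation-by-distance landscape models

Within-metapopulation site pairs form the design; metapopulations with
four or fewer sites are excluded (six or fewer pairs cannot support a
within-drainage slope) and flagged outlier sites lose all their pairs.
The global model for linearized FST contains river distance,
intermittency, land-cover and obstruction terms, a metapopulation
factor, and a distance-by-metapopulation interaction; `dredge_models()`
enumerates every subset respecting marginality and ranks by Gaussian
AIC (\(n\log(RSS/n) + n\log 2\pi + n + 2k\), k counting coefficients
plus the variance), reporting the largest absolute correlation among
each model's continuous predictors as a collinearity screen.

Pairwise responses are not independent, so per-coefficient OLS p-values
are reported but labelled invalid for pairwise designs; inference uses a
permutation test: responses are shuffled *within* each metapopulation
(keeping the between-drainage structure fixed), the best model refitted,
and the observed \(R^2\) compared with the permuted distribution,
\(p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\})/(n_{perm}+1)\) with
`n_perm = 999` by default (the add-one estimator never returns zero).
Permuting responses across pairs within metapopulation follows the
quoted procedure of the source study; node-label permutation would be an
alternative but is not what the text describes.

## LD-based effective population size

Before estimation, analysis units are pruned of internal structure
(Wahlund-inflated LD biases Ne downward): while the mean pairwise FST
among a unit's sites is ≥ 0.02, the site with the highest mean FST to
the rest is removed (ties: fewer individuals, then site id); units
retaining 30 or fewer individuals are dropped.

For a unit, Burrows' composite disequilibrium for a locus pair is half
the unbiased sample covariance of the dosage vectors (carrying the
standard \(S/(S-1)\) correction), standardized to
\(\hat r^2 = \hat\Delta^2 / (\hat p(1-\hat p)\hat q(1-\hat q))\).
Pairs are restricted to different chromosomes by default — the source
tool uses all pairs, but physical linkage inflates \(\hat r^2\) — and
weighted by the pairwise-complete sample size. The weighted mean is
bias-corrected with the random-mating sampling expectations
(\(1/S + 3.19/S^2\) for \(S \ge 30\); \(0.0018 + 0.907/S + 4.44/S^2\)
below) and inverted; a corrected value at or below zero reports
`Inf` — rendered as the literal `Infinite` in output tables, matching
how unbounded upper limits are conventionally printed.

Confidence intervals use a delete-one jackknife on the weighted mean
\(\hat r^2\) with a chi-square pivot (effective df \(2/CV^2\)). The
jackknife unit is the *individual*, not the locus: every locus pair
shares one pedigree realization, so locus resampling misses a common
variance component — empirically it underestimated
\(\mathrm{Var}(\bar r^2)\) about four-fold and covered a true Ne of 100
only ~60% of the time, versus ~90% for the individual-based jackknife
at the package's validation settings (N = 100, S = 50, L = 500 unlinked
loci, 50 generations, 20 replicates). The locus variant remains
available as `ci_method = "jackknife_loci"` for comparison with
tools that jackknife over loci.

## Genome scans

`detect_roh()` is a plink-style scanner: windows of 100 consecutive
SNPs are homozygosity-compatible with at most 1 heterozygote and 5
missing calls; a SNP is in-ROH when at least 5% of covering windows are
compatible; runs become segments kept at ≥ 100 kb span and ≥ 25 SNPs.
Window size is read as SNPs (the cited tool's `--homozyg-window-snp`
semantics); the hit fraction, SNP floor and missing-call cap adopt that
tool's defaults since the source is silent, and all are arguments.
Validation plants tracts in synthetic genomes: at 1 SNP/kb and
heterozygote error 0.001, tracts ≥ 150 kb are recovered with recall and
precision 1.0 and 90 kb decoys are never reported.

Effect terms map to impact classes (stop/frameshift/splice → high;
missense, in-frame indels → moderate; synonymous → low; everything
else, including unknown terms, → modifier). Load counts are
dosage-weighted (a homozygous alternate genotype contributes two
alleles); the deleterious proportion divides by the count of noncoding
SNPs genotyped for that individual — the source's figure caption
suggests all genotyped SNPs as denominator, which is available as
`denominator = "all"`; the text's definition is the default. Structural
variants are counted per individual with breakends paired by mate id
(an unpaired breakend counts singly, with a warning) and a 50 bp size
floor, and each count is regressed on the supplied divergence
covariates.

## Donor/recipient prioritization

The qualitative management table — recipients should have low diversity,
low Ne, high isolation, inbreeding and load; donors low divergence and
structural differences from the recipient, high diversity, low load —
is concretized as oriented within-dataset z-scores aggregated by a
weighted mean (weights equal by default, renormalized over non-missing
components, exposed in the output). This aggregation rule is the
package's own: the source framework gives directions but no weights.
Normalizing by the sum of absolute weights makes scores invariant to
flipping a component's orientation while negating its weight, and
z-scoring makes them invariant to affine rescaling of any raw metric.
Same-metapopulation donors are flagged as the default safest class.

## The synthetic generator and what it does (not) show

`generate_network()` grows one random dendritic tree per drainage
(lognormal edge lengths, mean 8 km; Dirichlet land cover dominated by
grassland/cropland; ~40% of edges largely intermittent; barriers on
~20% of headwater edges) and joins drainages along a 250 km mainstem.
`simulate_genotypes()` is frequency-based stepping-stone Wright–Fisher:
migration \(m_{ij} = m_0 e^{-d_{ij}/\lambda}\,\psi^{f_{int}}\,
\beta^{barriers}\) acts on deme frequencies before binomial drift each
generation, and S diploids per site are drawn under Hardy–Weinberg at
the end. Defaults (4 metapopulations × 8 sites, deme sizes ramping 12
to 400, \(m_0 = 0.03\), \(\lambda = 30\) km, \(\psi = 0.1\),
\(\beta = 0.3\), 600 generations, 300 loci, 20 samples/site) were
calibrated once so the synthetic range reproduces the study system's
published character: drainage-level FST from roughly 0.1 to 0.8,
within-drainage medians near 0.03–0.06 with isolation by distance, and
site heterozygosity varying several-fold across drainages. The strong
intermittency penalty (\(\psi = 0.1\)) reflects evidence that stream
drying is a major barrier for this guild and gives the landscape model
a recoverable planted effect at these panel sizes.

Loci are unlinked and independent in the stepping-stone engine — by
design, matching the LD estimator's drift-LD assumption — which means
that engine produces *no* drift LD and cannot validate the Ne method.
`simulate_wf_deme()` exists for exactly that: an individual-based
Wright–Fisher deme with Mendelian segregation, whose finite parent
number generates the drift LD the estimator measures.
`simulate_genomes()` plants ROH tracts, effect classes at the published
genome-wide class frequencies (high 0.026%, moderate 1.16%, low 1.67%,
modifier 97.14%), a linear heterozygosity–load relation, and Poisson SV
counts increasing with divergence time.

What passing tests show: the estimators agree with independent oracles;
the pipeline recovers planted structure (IBD slopes, intermittency
effects, Ne, ROH tracts, load slopes) under clean, unlinked,
neutrally-evolving synthetic data. What they do not show: robustness to
genotyping error, linked selection, unmodelled relatedness, uneven
missingness, or reference bias — all present in real reduced-
representation and WGS data. Published quantities from the study system
(e.g. its Table of watershed Ne values) derive from raw sequence data
and are not reproducible at desk scale; validation is therefore
property-based throughout.

## Numerical choices and problem sizes

Validation problem sizes were chosen to give stable statistics at
desk scale: 20 replicates for stochastic recovery checks; L = 400–500
loci where FST or r-squared precision matters; permutation tests with
199 permutations inside replicated power studies and 999 for a single
analysis. Degenerate inputs are contracts, not crashes: monomorphic
locus pairs are skipped, units with one site pass through pruning with
a warning, individuals with no calls get missing heterozygosity, an
all-one-chromosome panel errors with advice to enable the all-pairs
fallback, and migration row sums above one abort before simulation.
Ties are deterministic everywhere (site id order in pruning and
upstream-distance; downstream position in LD pruning; label order in
priority ranks) so that equal seeds give byte-identical outputs.

## Known limitations

Non-tree (braided) networks are rejected rather than approximated.
The Nei and Weir–Cockerham estimators disagree in small samples, and
the choice is left to the user. LD-Ne assumes closed random-mating
units; with migration it drifts toward a metapopulation-scale quantity.
The prioritization scheme is a transparent linear aggregation — it
orders populations consistently with the management table's directions
but has no claim to decision-theoretic optimality.
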