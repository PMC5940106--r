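---
title: "Methods: phylogenetic regression of promoter CpG density on lifespan"
author: "cpglife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic regression of promoter CpG density on lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Promoters are enriched in CpG dinucleotides, the substrate of DNA
methylation, and methylation patterns degrade with age. If high promoter CpG
density buffers a gene against age-related epigenetic drift, species that
evolved longer lifespans may have been selected for denser promoters at the
genes that matter. The package asks this question locus by locus: for each
conserved promoter, does CpG density covary with species maximum lifespan
across a phylogeny?

A naive correlation across species is confounded by shared ancestry: close
relatives resemble each other in everything, so ordinary regression
overstates the evidence. The model is therefore phylogenetic generalized
least squares (PGLS). For one locus with $n$ species,

$$ y = \alpha + \beta x + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}\!\left(0,\; \sigma^2 V(\lambda)\right), $$

where $y_i = \ln(\text{maximum lifespan in years})$ of species $i$, $x_i$ is
the promoter's CpG density in that species (CpG count divided by ungapped
match length, per nt), and $V(\lambda)$ is the Brownian-motion tip
covariance of the tree — $C_{ij}$ equals the shared root-to-MRCA path length
— with Pagel's $\lambda \in [0,1]$ multiplying the off-diagonal. $\lambda$
is estimated per locus by profiled maximum likelihood; $\lambda = 0$
recovers ordinary least squares exactly, $\lambda = 1$ is pure Brownian
residual covariance.

Inference on the slope uses the classical $t$ statistic with $n - 2$ degrees
of freedom. Two scales coexist deliberately: $\hat\sigma^2$ inside the
$\lambda$ profile is the maximum-likelihood (divide-by-$n$) estimate, as ML
estimation requires, while the slope standard error uses the unbiased
$n - 2$ scale so the $t$ reference distribution is the classical one. The
type-I simulations below confirm this keeps the test calibrated.

Across loci, p-values are adjusted by Benjamini–Hochberg; a locus is called
positively (negatively) correlated when $q < \alpha$ (default $0.05$) and
the slope is positive (negative). The adjustment family is exactly the set
of successfully fitted loci in one dataset — skipped loci never consume
multiplicity, and each dataset (e.g. a primate subset vs a full mammal set)
is corrected separately.

## Upstream: from homology hits to locus tables

Raw input is one hit table per species in a 14-column tabular dialect
(query id and length, query and subject coordinates, subject accession,
e-value, bitscore, alignment length, percent identity, query coverage, and
both aligned sequences). Reduction to analysis units:

1. **Best hit per promoter per species** — maximum bitscore, ties broken by
   minimum e-value, maximum alignment length, then subject accession and
   start. The upstream search tool is silent about ties, so the chain is
   specified totally here: reproducibility requires a deterministic,
   order-invariant reduction.
2. **Identity filter** — a hit survives when percent identity is $\geq$ the
   threshold (default 70). The comparison is inclusive so that tier counts
   at 70/90/95/99% are cumulative.
3. **Locus assembly** — the stored per-species sequence is the
   *subject-side* aligned sequence with gaps removed. The species' own
   promoter composition is the evolving trait of interest, which is why the
   query side is not used; density on the gap-stripped subject is invariant
   to alignment padding. Minus-strand hits arrive already query-oriented,
   so no reverse-complementing is performed.

CpG density is count/length per nt. Any fixed positive rescaling of the
predictor (per-nt, per-kb, or raw counts when match lengths are
near-constant) leaves slope signs, $t$ statistics and p-values unchanged,
so the unit choice is cosmetic; the raw count is carried alongside.
Observed/expected CpG ratios are deliberately not used. `N` bases never
form a CpG and are excluded from the GC denominator.

Species names are reconciled by trimming and collapsing internal
whitespace/underscore runs to a single underscore; after that, matching is
exact. Unmatched species are dropped from the affected locus and logged. A
user-supplied alias map handles nomenclature drift between trait databases
and genome labels, and a user exclusion list handles manual outlier removal
(the analogue of dropping a single extreme-lifespan species from summary
statistics); there is no automatic outlier detection. One default trait
override is applied: the human maximum lifespan is capped at 90 years,
because the verified record (~122 y) reflects a sample size no other
species approaches.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| identity threshold | 70 | % | the conservation tier used for analysis |
| `alpha` | 0.05 | — | q-value significance level |
| `min_n` | 5 | species | below this a 2-parameter GLS with estimated $\lambda$ is too fragile; skipped loci are reported with a reason |
| `lambda` | `"ML"` | — | profile ML on $[0,1]$; a fixed value is accepted (0 = OLS) |
| human cap | 90 | years | see above; exposed via `overrides` |

## Numerical choices

* GLS is solved by Cholesky factorization of $V$; results agree with the
  explicit-inverse closed form to $10^{-8}$ relative (tested against a
  brute-force oracle on hundreds of random small trees).
* The $\lambda$ profile evaluates a 21-point grid on $[0,1]$, then refines
  with Brent search within the bracketing cells (tolerance $10^{-7}$).
  Estimates within $10^{-6}$ of a boundary are snapped to it and flagged
  `at0`/`at1`; a profile whose total range is below $10^{-6}$ (e.g. a star
  phylogeny, where $\lambda$ has no effect) is flagged `flat` and reported
  at $\lambda = 1$.
* If $V(\lambda)$ has condition number above $10^{12}$, one shot of
  $10^{-10}\cdot\overline{\mathrm{diag}}$ jitter is added; if the factorization
  still fails the locus is flagged unfit rather than silently mangled.
* Zero-variance predictors are unfit (slope undefined); an exactly linear
  relation is flagged degenerate rather than reported with $p = 0$ and a
  spurious standard error.
* A plain Pearson correlation of the model-frame variables is reported as a
  diagnostic next to every fit. It is never used for significance calls —
  the PGLS slope test is the p-value — but comparing the two exposes loci
  whose apparent correlation is purely phylogenetic.

## The synthetic generator

Real inputs are ~100 genomes plus a curated trait database; the generator
stands in for them with data whose ground truth is known exactly:

* **Tree**: pure-birth (Yule) topology, branch lengths rescaled to unit
  root-to-tip depth — an ultrametric chronogram like the consensus trees
  the analysis consumes.
* **Lifespans**: $\ln$-lifespan evolves by Brownian motion from a root of
  $\ln 28$ (28 years is a typical mammalian mean maximum lifespan) with
  rate $\sigma^2_{BM} = 0.6$ per unit depth and a configurable true
  $\lambda$. Tip standard deviation ~0.66 log-years gives lifespans
  spanning roughly 5–150 years, the observed mammalian range.
* **Locus densities**: for a planted-positive locus,
  $x_i = 0.06 + \beta (y_i - \bar y) + \text{BM noise} + \text{iid noise}$,
  clamped to $[0.005, 0.45]$; negative loci flip the sign, null loci have
  no trait term. The center 0.06 per nt is a promoter-like CpG density.
* **Sequences**: each density is rendered as a 600 nt sequence (the
  −499..+100 promoter window) whose CpG count equals
  `round(density * 600)` *exactly*: the required number of non-adjacent CG
  dinucleotides is placed uniformly (via the non-overlapping-dominoes
  bijection), remaining positions are filled toward the GC target without
  ever writing G after C, and a repair scan removes any residual unplanned
  CpG. Exactness means the only noise between the planted trait and the
  fitted slope is the noise planted on purpose (plus count quantization at
  1/600).
* **Hit tables**: optional per-species 14-column files with sub-70%
  identity decoy rows and lower-bitscore duplicate rows, so the filter
  chain is exercised against a known answer.

Defaults (frozen after a one-time calibration, reported here so they are
not mistaken for universal constants): 64 tips, 400 loci, 5% planted
positive and 0.3% negative — the regime in which roughly 5% of promoters
come out lifespan-correlated with a ~95% positive skew; planted slope
$\beta = 0.010$ density units per log-year, giving ~85% per-locus power at
64 tips (the design target was ~80%); density noise sd 0.015
phylogenetic + 0.002 iid.

The noise composition deserves its own justification. CpG counting is
exact, so there is essentially no measurement error in the predictor; what
varies is the promoter sequence itself, and that variation accumulates
along the tree. Density noise is therefore modeled as predominantly
Brownian, with a small iid term for alignment-boundary jitter. This is not
only the realistic choice: a large iid component in the predictor, whitened
through $V^{-1/2}$ on a tree with short terminal branches, concentrates in
a few high-precision contrast directions and makes the per-dataset
type-I rate — computed against one shared lifespan vector — strongly
dependent on that vector's realization. With tree-structured predictor
noise the whitened regression is homoskedastic and the slope test is
calibrated dataset by dataset, which the null simulations verify.

**What the generator does not emulate**: indels and alignment error,
CpG-island structure and promoter grammar, deamination-driven
composition drift, correlated effects across loci, missing species
(every tip is present at every locus unless the user drops some), and
non-ultrametric trees. Passing tests therefore validate the statistical
machinery and the plumbing, not the biological conclusions; on real data,
alignment quality and species sampling per locus are the dominant
uncontrolled factors.

## Problem sizes used in the checks

Simulation-based checks run at 64 tips and 100–400 loci with 20 seeds for
the global-null FDR property — sizes at which the Monte-Carlo error of each
checked quantity is comfortably inside the asserted band. Oracle-equivalence
checks run on 200 random trees of up to 8 tips (where explicit matrix
inversion is trustworthy), 500 random p-vectors, 1000 random sequences, and
a 500-configuration sweep of the sequence renderer.

## Downstream summaries

Direction skew is tested with the exact two-sided binomial test
(minimum-likelihood ordering) of the positive count against
$\text{Binomial}(n_{sig}, 1/2)$ — the natural test for a direction split,
reported with the skew proportion. Gene-level comparisons first deduplicate
promoter annotations (case-sensitive; unannotated promoters are kept under
their own ids), then report exact intersection/difference sizes. Skew is
computed on promoter counts; deduplication applies to the overlap analysis,
mirroring the order in which these summaries are conventionally reported.

## Design decisions that were genuinely open

* **Identity comparison** uses $\geq$, matching cumulative tier-count
  semantics ("70% match" includes everything above).
* **Which side of the alignment carries the density**: the subject
  (species) sequence, for the reason given above; computing on the query
  would measure the human reference everywhere.
* **BH family**: fitted loci only, per dataset. Skipped loci are reported
  but never adjust anyone's q-value.
* **$\lambda$ bounds**: $[0,1]$, no extension past 1; values above 1 are
  not interpretable as a correlation attenuation and the profile is
  routinely flat there on ultrametric trees.
* **min_n = 5**: a floor had to be chosen; 5 complete cases is the smallest
  n at which the $t$ test with 3 residual df is even nominally meaningful.
  It is exposed as configuration and every skip is reported.
* **Config file format**: YAML mirrored by CLI flags (flags win). YAML is
  the conventional R configuration format and a single archived file
  reproduces a run.
* **Exact binomial for the skew**: the source analyses report only
  "p < 0.001" for the direction bias without naming a test; the exact
  binomial is the canonical test for a two-outcome split and is named in
  the output.

## Known limitations

* The per-locus $t$ test conditions on $\hat\lambda$; no uncertainty in
  $\lambda$ propagates into the slope standard error. At 64 tips the null
  simulations show nominal behavior; at very small n the test will be
  optimistic.
* One lifespan vector is shared across all loci, so locus p-values are
  dependent. BH is robust to this positive dependence, but the realized
  false-positive count in any single dataset has more variance than the
  independent-loci intuition suggests.
* Gene-level deduplication trusts the annotation strings; orthology is not
  checked.
* The pipeline consumes trees; it neither builds nor dates them, and
  results inherit any branch-length error in the input chronogram.
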