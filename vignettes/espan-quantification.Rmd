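---
title: "Quantifying parental histone segregation from eSPAN data"
author: "espanr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying parental histone segregation from eSPAN data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(espanr)
```

## The measurement

When a replication fork passes a nucleosome, the parental H3–H4 tetramer is
either recycled onto one of the two daughter duplexes or lost and replaced by
a newly synthesized tetramer. eSPAN (enrichment and sequencing of
protein-associated nascent DNA) reads out where the old and new tetramers
land: chromatin is immunoprecipitated for a histone mark, the nascent single
strands are enriched by BrdU immunoprecipitation, and sequencing reports, for
each fragment, which reference strand (Watson or Crick) the nascent DNA came
from. At a bidirectional origin the leading-strand daughter maps to Watson on
the right of the origin and to Crick on the left (and vice versa for the
lagging strand), so strand identity plus position relative to the origin
identifies the daughter strand.

`espanr` implements the downstream quantification:

1. **Strand coverage** — Watson and Crick per-base coverage from
   already-aligned, deduplicated stranded fragments (BED6).
2. **Partition bias** — per origin, in 100-bp sliding windows across
   ±10 kb, the statistic $\mathrm{bias} = (W - C)/(W + C)$, where $W$ and
   $C$ are the strand coverage sums in the window. The same statistic
   computed on the matched BrdU-input sample is subtracted to cancel
   technical strand asymmetries shared by the two libraries. Profiles are
   aggregated across origins as mean ± 2×SE.
3. **Strand-resolved density** — per origin and strand class
   (leading/lagging), a no-intercept least-squares coefficient expressing
   the eSPAN signal in units of the matched BrdU signal over ±2.5 kb, with
   genotype-versus-reference fold changes and Welch two-sample t-tests.
4. **Origin filtering** — origins are retained when their BrdU enrichment
   (local ±1 kb mean over genome-wide mean coverage) clears a threshold in
   every reference replicate.

A marker histone mark stands for each histone class: H3K4me3 or H3K9me3 for
recycled parental tetramers, H3K56ac for new deposition, BrdU for replicated
DNA regardless of chromatin.

## The simulator and its ground truth

Because the statistics above are easy to get subtly wrong (strand/side
conventions, window bookkeeping, normalization), every stage is validated
against a generative model with known parameters. Per genotype:

* `p_lead` — probability that a recycled parental tetramer is deposited on
  the leading-strand daughter;
* `r_recycle` — probability that a disrupted parental tetramer is recycled
  at all;
* each daughter slot without a parental tetramer receives a new tetramer,
  so every slot carries exactly one tetramer per daughter (no tetramer
  splitting — segregation is modeled at the tetramer level).

These two numbers fix everything the pipeline should recover, in closed
form:

| quantity | closed form |
|---|---|
| parental occupancy, leading daughter | $r\,p$ |
| parental occupancy, lagging daughter | $r\,(1-p)$ |
| parental eSPAN bias (Watson-leading side) | $2p - 1$ |
| new-histone eSPAN bias (same side) | $r(1-2p)/(2-r)$ |
| folded leading-strand bias | $(\text{right} - \text{left})/2 = 2p-1$ |

Geometry: origins fire bidirectionally and each fork travels
`replicated_halfwidth` (default 5000 bp); nucleosome slots sit at
$(k + \tfrac12) \times$ `nucleosome_spacing` (default 160 bp) from the
origin. Fragment lengths are Normal(150, 15²) clamped at ≥ 50 bp,
resembling mononucleosomal ssDNA inserts; no library insert distribution is
published for this protocol, so these values are a fixed modeling choice.
Okazaki-fragment substructure is not modeled: the partition statistic
depends only on strand identity, not on fragment joinery.

**Population averaging.** A sequencing library pools material from millions
of cells, so the strand mixture observed at one nucleosome slot is a
population average over many independent segregation events, not a single
molecule's choice. The generator therefore simulates `cells_per_sample`
(default 1000) independent cells per library; per-slot tallies are drawn as
Binomial counts, which is distributionally identical to summing independent
single-cell draws. Without this, per-window bias values would be dominated
by single-molecule noise (a 100-bp window sees only ~1.6 nucleosome slots)
and no read depth could smooth them — a regime no real eSPAN experiment is
in. `reads_per_nucleosome` (default 0.3) is the expected number of
sequenced fragments per deposited tetramer per daughter; values below 1
reflect that a library samples a small fraction of the molecules present.

Default depths (1000 cells, 0.3 reads per tetramer, 3 BrdU fragments per
replicated bp, 200 origins) give per-window totals of a few hundred reads
and were chosen, before any validation was run, so that the aggregate
wild-type bias curve has per-bin standard errors well below 0.01 — the
scale on which the symmetry and recovery checks operate. The test-suite
problem sizes (200 origins for study-scale checks, 3–16 origins for unit
tests) are the package's validation conditions throughout.

`strand_recovery_w` applies a multiplicative Watson-recovery distortion
identically to all samples of an experiment. It exists to verify the stated
purpose of BrdU subtraction: a shared technical strand asymmetry must vanish
from the normalized curve while remaining visible in the raw one. Note the
cancellation is exact where the underlying bias is 0 and first-order
otherwise, so the distortion-removal check is run on the symmetric wild
type; at strongly biased loci a multiplicative distortion leaves a
second-order residual that subtraction cannot remove.

Genotype presets (`genotype_presets()`) — WT (0.5, 1.0), `mcm2_2A` (0.85,
0.6), `dpb4d` (0.25, 0.8), `mcm2_2A_dpb3d` (0.55, 0.45), `pob3d` (0.5,
0.35) — qualitatively emulate the published phenotype classes (leading-bias
mutant, lagging-bias mutant, additive double mutant, recycling-impaired
FACT mutant). They are illustrative ground truths for validating the
pipeline, not fitted estimates of the biology.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `radius` | 10000 bp | half-width of the bias profile around each origin |
| `window` | 100 bp | sliding-window width for $(W-C)/(W+C)$ |
| `step` | 10 bp | window-center grid; "sliding" implies overlap, and the aggregate curve is insensitive to the step |
| `exclude` | 300 bp | origin-proximal zone left out of folded summaries and density fits: leading/lagging identity is undefined at the initiation point, and fragments (~150 bp) plus the window half-width can straddle it |
| `halfwidth` (density) | 2500 bp | fit range of the BrdU coefficient |
| `bin` (density) | 100 bp | bin width of the fit |
| `filter_halfwidth` / `filter_threshold` | 1000 bp / 2 | origin-usage filter: local BrdU enrichment required in every reference replicate ("consistent usage" is not defined quantitatively in the source protocol; enrichment ≥ 2 in all replicates is this package's auditable operationalization) |

## Numerical and design choices

**Coordinates and strands.** 0-based half-open intervals throughout (BED
convention); `+` is Watson, `-` is Crick; origins are midpoints of their
BED intervals. Readers validate every record against the declared genome
and refuse rather than clamp.

**NaN policy.** A window with $W + C = 0$ is NaN, and NaN propagates
through BrdU subtraction and is excluded from aggregates; zero-filling such
windows would fabricate symmetry. Aggregate bins with fewer than two finite
origins are NaN. When the analysis radius exceeds the simulated forks'
reach, bins whose window leaves the replicated interval are masked NaN:
beyond the fork only fragment spill-over remains, and near-empty windows
produce bias values of magnitude up to 1 that would dominate the profile
tails.

**BrdU pairing.** Subtraction and density fits use the BrdU sample of the
same genotype; pairing across genotypes requires an explicit override, and
two genotypes sharing one BrdU sample is an error.

**Density fit.** "Fitting eSPAN signal by BrdU coefficients" is
operationalized as a per-origin, per-strand-class scalar regression through
the origin: $c = \sum e_k b_k / \sum b_k^2$, clamped at 0, bins with zero
BrdU dropped. This is the simplest reading that is scale-covariant, has an
exact closed form to test against, and controls for local variation in
BrdU incorporation. Whether the deposited analysis fitted per strand or
jointly is not documented; per-strand-class fitting is this package's fixed
choice.

**Normalization and fold changes.** `density_table()` offers
`normalization = "none"` (default) and `"cpm"`. With `"cpm"` each sample is
first rescaled to counts per million of its own total — the conventional
treatment when sequencing depths are arbitrary. But a genotype that
recycles fewer parental histones genome-wide yields proportionally less
parental-mark material overall, so its per-sample total absorbs exactly the
signal of interest: CPM-based fold changes then report only the
*redistribution* between strands, not absolute retention, and can show
spurious increases (the normalization artifact the double-mutant comparison
is known for). With `"none"` the fit uses raw fragment coverage, which
keeps densities proportional to absolute per-strand occupancy whenever
library yield tracks chromatin abundance — true of the simulator and of
spike-in-calibrated libraries — and makes fold changes recover
$r\,p/0.5$ and $r\,(1-p)/0.5$ exactly in expectation. Both modes are
reported with per-origin bin counts so normalization effects can be
audited. Multiplying any sample by a constant multiplies its densities by
that constant; fold changes against an identically scaled reference are
invariant.

**Statistics.** The 95% ribbon is mean ± 2×SE exactly (not a t-quantile),
matching how such profiles are conventionally displayed. The density test
is Welch's unequal-variance two-sample t-test, two-sided; raw p-values are
primary, with a Bonferroni column printed for transparency and no
correction applied to the primary column, matching per-strand reporting
practice.

**Determinism.** One master seed; each (genotype, mark) sample draws from
its own deterministic substream, so adding a genotype or mark never
perturbs another sample's data. Identical configurations reproduce
byte-identical output tables.

## A worked example

```{r example, eval = FALSE}
geo <- sim_genome(n_origins = 40)
cfg <- simulation_config(geo$genome, geo$origins, cells_per_sample = 200,
                         brdu_reads_per_bp = 1.5, seed = 1)
res <- simulate_experiment(cfg, genotype_presets()[c("WT", "mcm2_2A")],
                           marks = c("H3K4me3", "H3K56ac"))
covs <- lapply(res$samples, coverage_from_fragments, genome = geo$genome)

prof <- bias_profile(covs$mcm2_2A.H3K4me3, covs$mcm2_2A.BrdU, geo$origins,
                     replicated_halfwidth = 5000)
mean(prof$folded$folded)        # ~ 0.70 = 2 * 0.85 - 1

tab <- density_table(list(
  list(genotype = "WT", espan = covs$WT.H3K4me3, brdu = covs$WT.BrdU),
  list(genotype = "mcm2_2A", espan = covs$mcm2_2A.H3K4me3,
       brdu = covs$mcm2_2A.BrdU)), geo$origins)
tab <- fold_change(tab, "WT")
fold_change_summary(tab)        # leading ~ 1.02, lagging ~ 0.18
density_tests(tab, "WT")
```

The same experiment, end to end with all artifacts on disk:

```{r pipeline, eval = FALSE}
run_pipeline(system.file("extdata", "wt_vs_mutants.yaml", package = "espanr"))
```

## What passing the validation does and does not show

The simulator establishes that the implementation is *correct*: strand
conventions, window bookkeeping, subtraction, fitting and testing recover
known ground truth to within Monte-Carlo error. It does not establish that
real nascent-chromatin data satisfy the model's idealizations. In
particular the simulator has: uniform origin firing (no efficiency or
timing variation), fixed symmetric fork travel, evenly spaced nucleosomes,
no sequence composition, no mappability structure, no Okazaki-fragment
boundaries, and library yield proportional to chromatin abundance. Real
applications should treat the origin filter, the ±300 bp exclusion radius
and the normalization mode as the main knobs to revisit, and should note
that origin positions taken from annotation are used as interval midpoints
— a choice, not a community standard.

Estimating `p_lead` or `r_recycle` *from* real data is deliberately out of
scope: the package reports the measurable strand statistics; inverting them
under the model's assumptions is a separate inference problem.
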