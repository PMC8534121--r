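---
title: "Integrative transcriptomic, gene-dependency and pharmacogenomic analysis of metastasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative transcriptomic, gene-dependency and pharmacogenomic analysis of metastasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metintegrate)
```

## The analysis this package implements

Metastatic progression studies often integrate several public data layers:
bulk tissue expression across disease stages (normal tissue, primary tumour,
metastasis), cell-line expression panels, genome-wide CRISPR knockout
dependency screens, and pooled drug-viability screens. `metintegrate`
implements that integration as a tested pipeline:

1. **Differential ranking** of genes between two sample classes by
   signal-to-noise ratio, with a label-permutation null.
2. **Pathway-level readout** of the ranking via two complementary
   procedures: binomial over-representation analysis (ORA) of a top-gene
   list, and a weighted running-sum enrichment score (ES) over the whole
   ranking with leading-edge ("core enrichment") gene extraction.
3. **Target vs marker triage**: combining upregulation with average CRISPR
   gene dependency — an upregulated gene the cell cannot live without is a
   therapeutic candidate; an upregulated but dispensable gene is a
   diagnostic-marker candidate.
4. **Pharmacogenomic stratification**: splitting cell lines into drug
   responsive / non-responsive groups on viability log fold change, ranking
   the genes that separate the groups, and reading the top of that signature
   through ORA.
5. **Annotation shortlists**: intersecting the top upregulated genes with
   surfaceome, secretome and drug-target tables to nominate imaging markers,
   serum markers, and already-druggable targets.

Because the original cohorts are external downloads, the package ships a
synthetic-data module that generates every input with recorded ground truth;
all statistical claims in the test suite are claims about recovery of that
truth.

## The ranking statistic

For a gene with per-class values $a$ and $b$,

$$\mathrm{SNR} = \frac{\mu_a - \mu_b}{\sigma_a + \sigma_b},$$

with sample standard deviations ($n-1$ denominator). Each $\sigma$ is floored
at $0.2\,|\mu|$ for its group, and at $0.2$ when that floor is itself zero —
the convention of the GenePattern/GSEA tool family. The floor prevents
division by zero for constant genes and damps near-constant genes whose tiny
denominators would otherwise dominate the top of the ranking. One consequence
worth knowing: the floored statistic is equivariant under rescaling all
values (means, deviations and floors scale together) but *not* invariant
under adding a constant, because the floor tracks $|\mu|$; with
`sd_floor = "none"` the statistic is shift-invariant but can divide by zero.
Reported alongside is the linear fold change $2^{\mu_a - \mu_b}$, since
inputs are log2-scale expression values.

Significance is a two-sided label permutation test with the add-one
convention,

$$p = \frac{\#\{|\mathrm{SNR}^*| \ge |\mathrm{SNR}_{obs}|\} + 1}{n_{perm} + 1},$$

so $p$ is never zero and never above one. The default `n_perm = 499` puts
the attainable floor at exactly $1/500 = 0.002$, the value a strongly
differential gene reports. Permutations are drawn uniformly with
replacement (uniqueness not enforced). In `rank_table()` one label
reshuffle per iteration is shared by all genes — the standard
phenotype-permutation scheme, and what makes 499 permutations over
thousands of genes cheap; `permutation_p()` on a single gene draws its own
permutations. Ranks break SNR ties lexicographically by gene id so the
ordering is reproducible.

## Enrichment procedures

**ORA.** With a query of $n$ genes inside a universe of $U$, and a set
covering $T$ universe genes of which $F$ are in the query, the p-value is
the upper binomial tail $P(X \ge F)$, $X \sim \mathrm{Bin}(n, T/U)$;
$F = 0$ gives $p = 1$. The universe defaults to the genes actually measured
in the expression matrix — not every gene ever annotated — because that is
the space the query was drawn from. The test is one-sided
(over-representation only). FDR control is Benjamini–Hochberg step-up,
computed across the sets actually tested after the size filter (default
5–2000 members inside the universe); `bh_fdr()` delegates to
`stats::p.adjust(method = "BH")` and is checked in the test suite against an
independent quadratic-time step-up reference.

**Running-sum ES.** Genes are sorted by score descending (stable sort:
equal scores keep their input order — the documented, deterministic tie
rule). Walking down the list, an in-set gene adds
$|s_i|^w / N_R$ (with $N_R = \sum_{hits} |s_i|^w$) and an out-of-set gene
subtracts $1 / (N - N_H)$. The ES is the running sum at its maximum absolute
deviation (earliest position on ties, detected with $10^{-12}$ slack so
floating-point summation order cannot flip a tie); with $w = 0$ this is the
classic Kolmogorov–Smirnov statistic. The leading edge is the set members at
or before the peak for positive ES, at or after it for negative. Degenerate
cases are rejected: a set covering the whole list, or all in-set scores zero
under the weight. A set with no member in the list is skipped with a
warning. The default weight of 1 is the canonical weighted scheme;
significance, when requested, is a phenotype-label permutation p-value
(re-rank per permutation, recompute ES) — a normalized enrichment score and
cross-set permutation FDR machinery are deliberately out of scope, since the
analysis reports raw ES values.

## Dependency triage and pharmacogenomic stratification

Gene-dependency values are probabilities in $[0,1]$ that a knockout reduces
a line's viability. `mean_gd_by_origin()` averages them per gene separately
over primary-origin and metastatic-origin lines, excluding `NA` cells from
numerator and denominator alike (screens do not cover every gene in every
line) and emitting observed counts. `triage()` labels a gene a
`therapeutic_candidate` when SNR reaches the cut **and** the
observation-weighted overall mean dependency is at least `high_gd`
(default 0.9, "close to 1"), a `marker_candidate` when dependency is at most
`low_gd` (default 0.1), and `other` in the dead zone between. The default
SNR cut is the statistic of the 300th-ranked gene — the size of a top-300
upregulated shortlist — and every threshold is a parameter.

Drug response is a per-line viability log fold change versus vehicle.
`stratify()` uses `lfc <= -0.5` for the responsive group (the boundary
belongs to responsive), `-0.5 < lfc <= 0.5` for non-responsive, and excludes
stronger growers. The upper boundary's ownership is essentially arbitrary
and configurable; it rarely binds. The responsive-vs-non-responsive SNR
ranking is the drug-response signature, and its top 150 genes (default) feed
ORA.

## What the synthetic data emulates — and what it does not

The generators' defaults mirror the study conditions of a metastasis
reanalysis: a merged tissue cohort of 41 normal / 140 primary / 31
metastasis samples (two sub-cohorts of 30/131/19 and 12/9/8 in the demo),
a 621-line cell panel with 253 metastatic-origin lines, a 464-line
drug-response intersection in the acceptance checks, 499 permutations, and
top-500/300/150 list sizes. The gene universe is 2000 genes rather than the
~38,000 transcripts of a full array — large enough for calibrated
tail statistics, small enough that the whole pipeline runs in seconds.

* **Expression** is additive Gaussian on the log2 scale around per-gene
  baselines (mean 7, sd 1.5 across genes; default noise sd 0.5 within
  genes), the right first-order model for RMA-style normalised data.
  Planted differential genes are shifted by a fixed 2 log2 units in the
  metastasis class only, so metastasis-vs-primary carries all the signal
  and primary-vs-normal is flat.
* **Dependency** is Beta(20, 1) for planted essential genes (mean ≈ 0.95)
  and Beta(1, 20) otherwise (mean ≈ 0.05), reproducing the near-0/near-1
  bimodality of genome-scale knockout screens.
* **The response signature is a co-expressed module**: its genes share a
  per-line latent "invasion activity" factor (loading 1, residual sd 0.5).
  This is a deliberate design choice. If signature genes were independent,
  selecting lines on their mean expression would shift each gene by only
  $\sigma/\sqrt{k}$ between response groups — undetectable per gene at any
  realistic size — whereas a co-regulated module (the realistic reading of
  an invasion/ECM signature) shifts every member by the full latent-factor
  difference. Drug response is then
  $-\mathrm{coupling} \cdot z(\text{signature score}) + \varepsilon$
  with noise sd 0.1 at the strong-coupling setting used for power checks.
* **Annotations** draw random membership (15% surfaceome, 10% secretome,
  10% druggable by default); about a fifth of secretome members carry only
  the protein-atlas "Secreted" location with no curation tag, exercising
  the OR-filter's second evidence route.

Not emulated: probe-level microarray structure, cross-cohort batch effects
(the merge function assumes comparably normalised inputs and offers an
explicit, off-by-default per-cohort median-centring switch instead of a
silent correction), copy-number or mutation layers, and realistic
correlation structure outside the planted module. Passing recovery tests on
this data therefore demonstrates the statistical machinery is correct and
calibrated — not that real cohorts would yield any particular gene list.

## Numerical and design choices

* Permutation p-values use the add-one convention; 499 permutations is a
  choice between 499 and 999 that the printed floor of 0.002 cannot
  distinguish ($1/500$ vs $2/1000$); it is configurable.
* The acceptance checks run the null calibration at 2000 genes × 10-vs-20
  samples × 499 permutations, recovery sweeps at 20 seeds each
  (1000–2000 genes), and the determinism check on a 1000-gene demo at 199
  permutations; the full default demo (2000 genes, 499 permutations) runs
  in about ten seconds on one core.
* Expression files are written with 17 significant digits so TSV/GCT round
  trips are bit-exact; the GCT reader verifies header dimensions against
  the body and names the offending row/column on malformed input.
* Missing values are rejected in expression input (SNR and ES assume
  complete vectors) but allowed in dependency matrices.
* Gene identity is the symbol string, case-sensitive; no alias resolution.
* Seeds fan out additively (`seed`, `seed + 1`, ...) to per-stage
  substreams, and every generator restores the caller's RNG state.

## A worked demo

```{r demo, eval = FALSE}
out <- file.path(tempdir(), "demo")
demo <- run_demo(seed = 7, out_dir = out)
demo$manifest$row_counts
read.delim(file.path(out, "results", "diff.tsv"), nrows = 3)
```

`run_demo()` generates the full synthetic input bundle (two cohorts, gene
sets with two planted sets plus the planted response module as a set,
dependency with 40 essentials planted inside the differential genes,
coupled drug response, annotations), writes a YAML config, and runs the
pipeline: `diff.tsv`, `ora.tsv`, `gsea.tsv`, `triage.tsv`, `sig_ora.tsv`,
`surface.tsv`, `secreted.tsv`, `druggable.tsv` plus `manifest.json`. The
outputs are pure functions of (inputs, config, seed).

## Known limitations

* The permutation scheme shares each label reshuffle across genes; gene-level
  p-values are therefore conditionally independent across genes but share a
  permutation set, which is standard and harmless for calibration yet worth
  knowing when resampling the p-values themselves.
* ORA uses the binomial approximation to sampling without replacement (the
  convention of pathway-portal over-representation tests), not the
  hypergeometric; for queries that are a large fraction of the universe the
  binomial tail is conservative.
* The ES implementation reports raw enrichment scores; set-size
  normalisation across sets is out of scope, so ES values should be
  compared across sets of similar size only.
* Triage thresholds ("close to 1", "closer to 0") are sharp cutoffs on
  means; genes near a threshold flip class under resampling.
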