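---
title: "Estimating spontaneous mutation rates from mutation-accumulation lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spontaneous mutation rates from mutation-accumulation lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malines)
```

## The experiment and the model

A mutation-accumulation (MA) experiment propagates many replicate lines
from one progenitor cell through repeated single-colony bottlenecks.
Because each bottleneck reduces the population to one cell, genetic
drift overwhelms selection for all but strongly deleterious mutations,
and mutations fix in a line at close to the rate at which they arise.
After a few hundred bottlenecks the lines are whole-genome sequenced
and the fixed differences counted.

The estimator is a Poisson rate:

$$\mu = \frac{M}{\sum_{\ell} N_\ell \, T_\ell}$$

where $M$ is the number of mutations over all lines, $N_\ell$ the
number of analyzed (callable) sites in line $\ell$, and $T_\ell$ the
number of cell divisions the line went through. $T$ is itself
estimated from colony counts: a colony grown from one cell with CFU
viable cells took about $\log_2(\mathrm{CFU})$ divisions, so $T$ =
mean divisions per transfer × number of transfers
(`estimate_divisions()`). The package accepts either raw CFU lists or
a pre-computed mean; published means are usually rounded, so totals
computed from them differ slightly from totals computed from raw
counts, and we deliberately expose $T$ directly rather than hide that.

Mutation counts of a handful are the norm at low rates, so every rate
carries an exact (Garwood) Poisson interval rather than a normal
approximation: the lower bound solves $P(X \ge M \mid \lambda) =
\alpha/2$ (zero when $M = 0$), the upper solves $P(X \le M \mid
\lambda) = \alpha/2$, computed through the chi-squared identity
$\lambda_{lo} = \tfrac12\chi^2_{\alpha/2}(2M)$, $\lambda_{hi} =
\tfrac12\chi^2_{1-\alpha/2}(2M+2)$ and scaled by the site-division
denominator. For $M = 0$ the upper bound is $-\ln(\alpha/2)$ scaled
the same way, which is how a class with no observed mutations still
gets a meaningful ceiling.

### Interval conservatism

Exact Poisson intervals are conservative by construction: their
coverage is at least the nominal level for every true $\lambda$, not
approximately equal to it. At $\lambda = 5$, for instance, the 95%
interval covers exactly when the count falls in 1..10, so the true
coverage is $P(1 \le X \le 10) = 0.9796$. Simulation checks of the
interval must therefore test *coverage at least nominal and equal to
the analytic value within binomial noise* — a band symmetric around
95% would be testing a property exact intervals do not have.

## Consensus calling

The caller works from pileup tables — per line and site, the counts of
reads supporting each base, an insertion or a deletion — and makes two
nested consensus decisions (`call_mutations()`):

1. **Line consensus.** A site in a line is called if depth ≥
   `min_depth_line` (default 10), the majority base holds at least
   `min_consensus_fraction` (default 0.8) of reads, and, when the
   pileup carries forward/reverse counts, each strand contributes at
   least `min_reads_per_strand` (default 2) supporting reads. These
   defaults follow the consensus-calling conventions of the MA
   literature and are configuration (`caller_config()`), not
   constants.
2. **Ancestral consensus.** The ancestral state at a site is the
   strict majority (> 50%) of the called line consensuses, requiring
   at least `min_lines_for_ancestral` (default 3) called lines. Using
   the cross-line majority rather than the reference sequence means an
   assembly error — which misleads every line identically — cannot
   generate calls.

A substitution is called where a line's consensus differs from a
defined ancestral base; insertion/deletion status is decided per line
from the indel-supporting read fractions under the same thresholds and
compared across lines the same way. A line's analyzed-site count
$N_\ell$ is the number of sites where that line has a called consensus
*and* the ancestral state is defined — the same sites at which a
mutation could have been observed, which is what the denominator
requires.

Ties resolve to no-call at every level. This is conservative: it
trades false negatives (which inflate nothing, they only shrink $N$)
against false positives (which directly inflate $\mu$). With the
default fraction gate above 0.5 a tied majority can never pass, so
argmax tie-breaking order is irrelevant.

Line-level QC (`qc_lines()`) drops lines whose median genome-wide
depth falls below `line_min_median_depth` (default 20; sites missing
from the pileup count as depth 0) and reports breadth — the fraction
of the genome with any coverage — for inspection without acting on it.
`flag_contamination()` flags line pairs whose call sets overlap with
Jaccard index ≥ `contamination_shared_fraction` (default 0.5, with at
least two calls each); independent MA lines should share essentially
nothing, so high overlap indicates cross-contamination rather than
coincidence.

## Spectrum, bias and equilibrium composition

Substitutions are pooled into the six strand-symmetric classes
(G:C→A:T covers G→A and C→T, and so on). Because a G:C→A:T mutation
can only happen at a G:C site, each class rate is conditioned on its
context: count divided by (context fraction × site-divisions)
(`conditional_rate()`). When per-line analyzed-site composition is not
available the genome-wide G+C fraction is the documented fallback for
the context fraction. The composition-weighted conditional rates
always reconstruct the total substitution rate exactly — an identity
`spectrum_table()` preserves on every input and the tests assert.

From the conditional rates: the A/T bias $m$ = (μ_GC→AT +
μ_GC→TA)/(μ_AT→GC + μ_AT→CG); the transition/transversion ratio from
raw counts; and the equilibrium A+T content $p = v/(u+v)$, with $v$
the rate sum toward A/T and $u$ toward G/C — the composition the
genome would drift to under mutation pressure alone. Zero
denominators return `Inf` with a warning (`at_bias()`, `ts_tv()`)
since a zero-count direction is a legitimate observation at low rates.

Coding and non-coding rates (`region_rates()`) condition on the
coding/non-coding site partition from the CDS annotation, with a
two-sided Fisher's exact test (via `stats::fisher.test`) on the 2×2
table of mutation counts against region site counts — the site counts
stand in for non-mutated site-divisions, from which they differ only
by the shared division factor. Effective neutrality in an MA design
predicts no difference; a significant coding deficit would signal
selection leaking through the bottlenecks.

## Four-fold diversity and effective population size

`fourfold_sites()` marks third-codon positions whose codon family
encodes one amino acid for all four third bases (the eight families
CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN under the standard genetic
code). Minus-strand CDS are read on their reverse complement, the
`phase` leading bases and trailing partial codons are skipped, codons
with `N` in the determining prefix are skipped, and positions covered
by another CDS in which they are *not* a four-fold third position are
excluded — overlapping genes disagree about degeneracy and the safe
choice is to drop the site. Degeneracy is classified on the focal
(reference) strain's annotation and projected through the alignment's
reference row, dropping columns where that row is gapped; classifying
per strain would require an annotation per strain, which the data do
not provide.

`theta_fourfold()` computes, per masked column with $n' \ge 2$ non-gap
strains, $h = \frac{n'}{n'-1}(1 - \sum_b p_b^2)$ and averages over
columns. The small-sample factor uses the *column's* non-gap count
$n'$ rather than the global strain number: with missing data the
global-$n$ correction under-corrects columns where strains are absent
and would bias θ downward. For $n' = 2$, $h$ is exactly the pairwise
mismatch indicator, and in general $h$ equals the fraction of
mismatched strain pairs in the column — the identity the tests use as
an independent oracle. Finally `effective_population_size()` applies
$N_e = \theta / 2\mu$, the haploid mutation-drift equilibrium
relation.

## The simulator: what it emulates, and what it does not

The generator produces every pipeline input with known truth, with all
randomness derived from a mandatory integer seed:

* `generate_genome()` — i.i.d. bases at a target GC fraction with
  non-overlapping CDS (random strand, ATG start, no internal stops,
  terminal stop codon) covering a target coding fraction.
* `plant_mutations()` — per line and class, Poisson counts with mean
  (conditional rate × context sites × T), positions uniform within
  context, 1 bp indels, no site hit twice per line.
* `simulate_pileups()` — negative-binomial depth per site (so
  low-coverage no-call paths are exercised, unlike fixed depth), each
  read flipped to a uniform wrong base with the per-base error
  probability; indel-supporting reads land in the `nIns`/`nDel`
  columns.
* `simulate_cfu()` — CFU = round(2^N(mean, sd)), the forward model of
  the division bookkeeping.
* `simulate_strains()` — each strain independently substitutes each
  four-fold site with probability *d*; two strains then differ at a
  site with probability $2d(1-d) + \tfrac{2}{3}d^2$, the closed form
  the diversity tests check against.

The default configuration **is the study design the package targets**:
52 lines, 4517 divisions/line, a 5,171,217 bp genome at 42.39% GC,
~86.5% coding (5,240 genes of mean length 854 bp), 163× mean depth,
per-class rates of order 10⁻¹²–10⁻¹⁰, a 13-strain diversity panel, and
per-site strain density 0.042 chosen once to put pairwise diversity
near 0.08. The per-base error rate defaults to 0.003, a typical
post-filter short-read mismatch rate.

What the simulator deliberately leaves out: read-level artifacts
(quality scores, mapping error, strand bias), multi-base and complex
indels, double hits at one site, and selection during propagation. A
passing recovery test therefore demonstrates that the estimator chain
is correct *given* pileups whose errors are independent per read; it
does not show robustness to alignment artifacts, which in real data
are handled upstream of the pileup.

## Problem sizes used by the tests

Full-scale runs (5.17 Mb × 52 lines) are not needed to exercise any
code path, so the test suite uses two reduced configurations chosen as
the package's own validation design: `sim_config_scaled()` — 0.5 Mb,
20 lines, T = 500, per-class rates ×100 (expected substitution yield
≈ 30 per replicate, the same counting regime as the real experiment),
depth 60×, error 0.003 — for the 20-replicate end-to-end recovery
check of CI coverage; and assorted 5–200 kb configurations for the
caller-equals-truth oracle, false-positive, QC and diversity checks.
`demo_config()` (50 kb, 8 lines, rates ×2000) drives the one-command
`run_pipeline()` demonstration.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere (GFF3/VCF
  convention); no half-open interval appears in any interface.
* **Alphabet** is restricted to A, C, G, T, N; other ambiguity codes
  are rejected at the door rather than propagated.
* **Readers reject rather than repair**: malformed pileup rows,
  out-of-bounds CDS, duplicate FASTA ids and genome-inconsistent
  reference alleles are errors naming the file and line, because a
  silently "fixed" input corrupts denominators downstream.
* **VCF output** is minimal 4.2 (CHROM/POS/REF/ALT + a LINE tag),
  indels anchored per VCF convention; externally called variants are
  ingested through `read_variant_table()` instead of reimplementing a
  haplotype caller, consistent with a design in which the consensus
  caller is the native method and an external caller's output is a
  cross-check.
* **Indel calls** carry presence and 1 bp length only; the pileup
  count columns cannot encode allele strings, and multi-base events
  are out of scope.
* **Rounding** happens only at print time (3 significant digits);
  every object retains full precision.
* **Determinism**: callers are pure functions of their inputs (row
  order of the pileup is irrelevant), simulators are pure functions of
  (config, seed), and `run_pipeline()` reruns byte-identically given
  the same configuration, which the manifest's checksums make easy to
  verify.

## Limitations

Rate heterogeneity along the genome, mutation-rate plasticity across
environments, Bayesian rate estimation, recombination-aware diversity
and Watterson's estimator are out of scope. The equilibrium
composition formula treats the genome as a two-state (A:T vs G:C)
system under mutation pressure alone; real genomes also experience
selection and gene conversion on composition, so the equilibrium value
is a statement about mutation pressure, not a prediction of where the
genome will actually settle.
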