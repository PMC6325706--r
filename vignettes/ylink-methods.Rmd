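---
title: "Methods: sex-linkage assignment, gene conversion, and repeat landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-linkage assignment, gene conversion, and repeat landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylink)
```

`ylink` implements the bespoke computations used when an assembly is
enriched for heterochromatin and its Y-linked portion has to be identified
and characterized: partitioning reads into a heterochromatin-enriched
subset, assigning contigs to the Y, X, or autosomes from male and female
sequencing depth, estimating gene-conversion rates in Y-linked multicopy
gene families, and summarizing repeat landscapes. A synthetic-data module
generates every input the pipeline consumes, so each stage is testable
offline against a known truth. This vignette records the models, the
parameter choices, and the places where the design was genuinely open.

## Sex-linkage from male/female depth

In a male *Drosophila*-like karyotype (X/Y males, X/X females), a Y-linked
site is present in one copy in males and zero copies in females, so its
expected female depth is zero while its male depth is half the autosomal
level. The assignment statistic is the **median per-site female-to-male
depth ratio**: a contig or window whose median ratio over eligible sites
equals 0 is Y-linked; medians at or above the X threshold are X-linked;
anything in between is autosomal.

Parameters and their defaults:

* **Site eligibility** (`min_site_reads = 2`): a site counts only when the
  two samples together contribute at least two reads with MAPQ >= 10. The
  source convention excludes "sites with one or fewer" qualifying reads;
  whether that count is per sample or combined is not stated, so the
  combined reading is the default and the threshold is exposed. A site
  with zero depth in both samples is always ineligible, which prevents
  unmappable sequence from counting as "female-free".
* **MAPQ cutoff** (`min_mapq = 10` in `depth_from_alignments()`): the
  uniquely-mapped-read convention of samtools-style depth (`-Q 10`).
  Aligned reference spans come from the CIGAR; deletions are covered,
  reference skips and clips are not.
* **Window size** (10 kb) and **ambiguity guard**
  (`min_eligible_bp = 1000`): a unit is assigned only with strictly more
  than 1 kb of eligible sites, otherwise it is `AMBIGUOUS` and excluded
  from evaluation.
* **X threshold** (`x_threshold = 1.5`): the midpoint of the expected
  female-to-male ratios for the X (2) and the autosomes (1). The source
  gives no X cutoff; the midpoint is symmetric and exposed.
* **Median convention**: for an even number of eligible sites the lower
  central value is used, so a unit with exactly half zero-ratio sites is
  still called Y — conservative toward the median-equals-zero rule.
* **No library-size normalization** by default: the statistic targets
  PCR-free libraries of comparable depth, and a median of exactly zero is
  scale-free. Labels are invariant under multiplying both samples' depths
  by any constant (a tested property).

The **chromosome quotient** (CQ) — the female-to-male ratio of total
alignment counts over a reference, called Y below 0.05 — is provided as
the comparator. Its weakness is that a modest amount of spurious female
cross-mapping (e.g. from repeats shared with other chromosomes) inflates
the quotient past the threshold, while the median of per-site ratios
ignores a minority of contaminated sites entirely. On fixtures where 20%
of a Y contig's sites receive female cross-mapping at autosomal depth, the
median rule keeps 100% sensitivity while CQ drops to zero; with 2%
contamination CQ still works (quotient about 0.04). Both behaviors are
asserted in the tests.

Evaluation treats Y as the positive class: sensitivity is the fraction of
truly-Y units labeled Y, the false-assignment rate is the fraction of
Y-labeled units that are not truly Y, and ambiguous units are excluded
from both.

## Heterochromatin read partitioning

The enrichment rule retains a read iff its **primary** alignment is
unmapped, maps to a reference outside the declared euchromatic set, or —
when euchromatic spans are supplied — has at least one aligned base
outside those spans. Secondary and supplementary records never influence
the decision; basing the rule on the primary alignment alone keeps the
partition deterministic under multi-mapping. The span mechanism
reconciles the two phrasings of the rule found in practice (exclude whole
chromosome arms vs. keep reads hitting pericentric heterochromatin of
those arms): with spans covering only euchromatin, a read straddling the
euchromatin boundary is retained, which favors recall — the right bias for
an enrichment step. By default any primary mapping counts as mapped;
`min_mapq_for_confident` optionally treats low-MAPQ primaries as unmapped.

The partition is total (every read lands in exactly one class), idempotent
on its retained subset, and monotone: enlarging the euchromatic set can
only shrink the retained set. All three are tested as properties.

## Gene-family recombination and conversion statistics

Y chromosomes do not cross over, so four-gamete violations and linkage
breakdown among tandem gene-family copies measure **intrachromosomal gene
conversion**.

**Site matrices.** Aligned copies shorter than 280 non-gap bp are dropped
(inclusive bound: a 280-bp copy stays). Gaps and N are missing data.
Biallelic columns with minor count >= 2 become 0/1 sites (major = 0; count
ties resolve to the lexicographically smaller base). Singletons are
excluded by default because they cannot create four-gamete violations;
the threshold is exposed since it changes the segregating-site count S.

**Rmin.** Every site pair is tested for all four gametes over
pairwise-complete copies (missing data: pairwise deletion; the source is
silent, and pairwise-complete is the least destructive choice).
Incompatible pairs become intervals; intervals containing another
incompatible interval are removed; the minimum number of exchange events
is the size of the maximum pairwise-disjoint set of the remainder, found
greedily on sorted right endpoints. "Disjoint" means sharing no site.
The implementation is checked against an exhaustive subset-search oracle
on hundreds of random matrices.

**LD-based rho.** The per-locus population recombination parameter `C` is
estimated by matching the observed variance of pairwise differences,
$S_k^2$ (denominator = number of pairs), to its neutral-coalescent
expectation, solved by monotone bisection on `[0, 1000]` with tolerance
`1e-4`; an observed variance above the `C = 0` expectation yields 0. The
expectation is assembled from standard coalescent moments:

$$E[S_k^2] = \mathrm{Var}(k_{ij}) - \mathrm{Var}(\bar k),$$

where the variance of the mean involves the covariances of pairwise
differences for pairs sharing two, one, or zero lineages. Each covariance
splits into a shared-mutation term (linear in $\theta$; unaffected by
recombination, coefficients 1, 1/2, 1/3) and a shared-genealogy term
(proportional to $\theta^2$) that decays with `C` through the two-locus
coalescence-time covariances $(x+18)/D(x)$, $6/D(x)$, $4/D(x)$ with
$D(x) = x^2 + 13x + 18$, integrated uniformly over the locus. At `C = 0`
these reduce exactly to the classical single-tree moments (1, 1/3, 2/9)
and the full expression reproduces the textbook variance of the mean
pairwise difference for any sample size. Validated against coalescent
simulations (n = 50, theta = 10): the expectation tracks the empirical
mean of $S_k^2$ within a few percent across `rho` in {1, 5, 20}.

A property of this moment estimator worth knowing: $S_k^2$ is strongly
right-skewed, so inverting the mean-matching equation at the observed
value is median-biased upward when `rho` is small. The tests therefore
assert factor-two median recovery at `rho` of 5 and 20 and monotone
ordering at 1, rather than pretending the estimator is median-accurate
everywhere.

**Conversion rates.** Three routes are provided:

* `cg_from_rho()`: $c_g = \rho/(nL)$ — the scaling that converts a
  per-locus rho into events per site per generation for an $n$-copy,
  $L$-bp family. This is a *reconstruction*: it reproduces the published
  (rho, n, L, c) quadruples to their printed precision (e.g.
  `cg_from_rho(2.67, 107, 857)` gives 2.9e-5), but the original
  supplementary derivation is not restated here, so the function is
  documented as arithmetic, not as theory.
* `cg_from_similarity()`: at mutation–conversion balance the standing
  divergence among copies satisfies $\bar d \approx \mu/c$, so
  $c_g = \mu/\bar d$ with $\mu$ = 2.8e-9 per site per generation by
  default. A copy-number variant ($\mu n/\bar d$) is selectable because
  the exact published expression is not available; under the simulator's
  model the pair-divergence ODE $\dot d = 2\mu - 2cd/(n-1)$ actually
  equilibrates at $\mu(n-1)/c$, which is why the similarity route should
  be read as order-of-magnitude.
* `cg_from_rho_scaled()`: the scaling used to validate rate recovery on
  simulated families. At conversion–drift balance the copies' genealogy
  is a coalescent whose timescale conversion itself sets, so rho alone is
  dimensionless in $c$; combining it with diversity restores units. With
  per-site $\theta = 4N\mu$ and $\rho = 4N r_\ell$, and the effective
  locus-wide exchange rate of conversion $r_\ell \approx 6wc$ — $w$ the
  probability that a geometric tract (mean 500 bp) separates a uniformly
  chosen site pair, and 6 arising from twice the mean pair separation
  $L/3$ entering the locus-wide parametrization — the estimate is
  $c_g = \hat\rho \,\mu / (6 w \hat\theta_{site})$. On families simulated
  at equilibrium this recovers the true rate with a median ratio near 2
  across a tenfold range of $c$ (inside the factor-3 band the tests
  assert); the residual factor reflects the kernel mismatch between
  tract-style exchange and crossover-style exchange, and is documented
  rather than corrected away.

**Chimeras and shared variants.** Diagnostic columns between two families
are those where the family consensuses differ and each family is at least
90% pure; a query is chimeric when it carries at least `min_run = 3`
consecutive diagnostic alleles of *each* family, with the breakpoint
reported at the midpoint between the flanking runs. Shared variants
between families count the biallelic columns of one family (singletons
included, since "variant sites" counts all variants) at which the other
family carries the identical minor allele.

## Repeat landscapes

`parse_repeatmasker()` and `parse_trf()` read the standard `.out` and
`-ngs` `.dat` dialects (the TRF `-ngs` format carries the contig only in
the preceding `@` header). Composition summaries group Repbase class
strings through an editable map (LTR, LINE, DNA, Satellite/Tandem —
including simple and low-complexity annotations — rRNA+IGS, Other);
overlaps are resolved base-by-base with the higher RepeatMasker score
winning and ties going to the earlier record (the original summarization
scripts' policy is not printed; score priority is the natural choice),
and tandem arrays claim only bases not already masked. Unclaimed bases
are `Nonrepetitive`, so per group the class totals sum exactly to the
assembled length — an invariant the tests assert.

Whole-chromosome extrapolation assumes the unassembled remainder is
simple tandem repeat — the standing model for repeat-dense Y chromosomes:
the tandem fraction becomes
$(\mathrm{total} - \mathrm{assembled} + \mathrm{tandem}_{assembled})/\mathrm{total}$
and every other class is its assembled bp over the assumed total. With a
40-Mb chromosome, 14,578,684 bp assembled and 742,964 bp of assembled
tandem repeat this yields 65% (and 5% of the assembled sequence), the
arithmetic the acceptance script reproduces. The assembled length is an
explicit argument because published extrapolations are not always
internally consistent about gap treatment.

The positional-clustering test for duplications is a two-sided Fisher
exact test on `[[hits in region, hits outside], [bands in region, bands
outside]]`; the 2x2 construction is a documented reconstruction (the
source states only the inputs and the p-value, which the reconstruction
reproduces: 12/13 duplications across 11/25 bands gives p = 0.005). The
p-value sums hypergeometric probabilities not exceeding the observed
table's, with the classical `(1 + 1e-7)` tie tolerance, and is verified
against exhaustive enumeration for every table with N <= 40.

## The synthetic-data module

The generators define the study conditions the tests measure under:

* **Genome plans**: contigs with known truth class, lengths drawn
  uniformly from the requested range, mappable fractions from
  `[0.5, 1.0]`. Each contig carries its own mask seed so the unmappable
  sites are a property of the contig — male and female tracks share the
  mask, as they would share a real mappability track.
* **Depth**: expected depth = haploid depth x copy number (male A:2 X:1
  Y:1, female A:2 X:2 Y:0), i.e. Y sits at 50% of autosomal depth in
  males and 0 in females; Poisson noise by default,
  negative-binomial optional. Tracks are dense (every site emitted); the
  reader also accepts sparse files, filling absent positions with zero.
* **Reads**: minimal valid SAM with `@HD`/`@SQ` header, primary mappings
  with MAPQ, and a sidecar truth table for the partition rule.
* **Gene families**: all copies start from one uniform-random ancestor.
  Mutations hit uniform sites at rate mu per site per generation (uniform
  choice among the three alternative bases — no transition bias, as
  nothing in the source constrains one). Conversion tracts initiate at
  rate c/tract_mean per site, take a uniform donor among the other
  copies, and have geometric lengths with mean 500 bp — the tract-length
  distribution is an assumption (geometric is the standard choice and the
  empirical Drosophila scale), flagged here and configurable. `c` is the
  per-site per-generation probability of being covered by a tract,
  matching the "events per site per generation" unit. The whole history
  is drawn as a marked Poisson process over `(0, T]` and applied in time
  order — distributionally equivalent to a generation loop and fast
  enough for 50 copies x 1 kb x 10 million generations. The event log
  records every conversion, and the logged count obeys its Poisson law
  (a tested invariant).

What the simulator does **not** emulate: read-level sequence errors,
long-read alignment artifacts, reference bias, copy-number variation
within families, selection, and biased gene conversion. Passing tests
therefore demonstrate the statistical machinery, not robustness to every
real-data pathology.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations for a
single CPU: 300 contigs x 20 kb (600 windows, 12 M sites) for the
assignment battery; 30 ten-kb contigs for the cross-mapping comparison;
20 gene-family replicates at n = 50, L = 1 kb for rate recovery (the
c = 1e-5 families run 9.8 M generations each); 200 random matrices for
the Rmin oracle; all 135,751 2x2 tables with N <= 40 for the Fisher
oracle. Bisection tolerances are 1e-4 (rho); the rho search is capped at
1000, where the expectation is already within noise of its large-C
asymptote. Degenerate inputs are defined, not exceptional: an invariant
alignment yields an empty site matrix and Rmin 0; a family with identical
copies reports infinite similarity-based c with a warning; a unit without
eligible sites is AMBIGUOUS.

## Worked example

```{r example}
plan <- build_genome_plan(n_auto = 2, n_x = 1, n_y = 1,
                          length_range = c(30000, 40000), seed = 1)
model <- depth_model(haploid_depth = 15, seed = 9)
male <- simulate_depth_tracks(plan, "male", model)
female <- simulate_depth_tracks(plan, "female", model)
profile <- compute_ratio_profile(female, male)
windows <- tile_windows(setNames(plan$length, plan$name), 10000)
assignments <- assign_units(profile, windows)
table(assignments$label,
      plan$truth_class[match(assignments$contig, plan$name)])
```

```{r example2}
fam <- simulate_gene_family(
  family_sim_params(n_copies = 20, L = 1000, mu = 1e-7,
                    conversion_rate = 5e-5, generations = 50000, seed = 2))
sm <- extract_biallelic_sites(fam$sequences)
c(S = length(sm$sites), Rmin = rmin(sm)$rmin,
  rho = round(hudson_rho(sm)$rho_locus, 2))
```

## Known limitations

* The rho estimator inherits the high variance and low-rho median bias of
  variance-of-pairwise-differences matching; treat point estimates from
  single loci as order-of-magnitude.
* `cg_from_rho()` is printed-arithmetic reconstruction; its theoretical
  status is unresolved here, and at strict conversion-drift equilibrium
  rho is uninformative about c without a diversity anchor (use
  `cg_from_rho_scaled()` on simulated families).
* Assignment assumes comparable male and female library depths; grossly
  unbalanced libraries should be normalized upstream or the eligibility
  threshold raised.
* Whole-chromosome extrapolation is only as good as the
  unassembled-is-tandem assumption and the assumed chromosome size.
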