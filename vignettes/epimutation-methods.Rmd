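---
title: "Methods: calling epimutations and tracking their inheritance across generations"
author: "epimutools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling epimutations and tracking their inheritance across generations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimutools)
```

## The problem this package addresses

Multi-generation stress-exposure experiments in plants ask whether an
environmental stress leaves heritable marks on the DNA methylome. The
canonical design — implemented here for a rice drought study layout —
propagates an epimutation-accumulation line by single-seed descent under
repeated stress and profiles, per variety, 16 whole-genome bisulfite
sequencing (WGBS) samples: four generations (G0, the original; G10; G11;
and G10R1, a recovery generation grown well-watered for one generation
after G10) crossed with two treatments (drought D, well-watered W) and two
sibling replicates, at a mean strand-specific depth near 13x.

Three kinds of epimutation are called from per-cytosine bisulfite counts
and then tracked across generations:

* **DMP** (differentially methylated position): a cytosine whose
  methylation *level* differs between two sample groups
  (hyper-/hypo-methylated).
* **SMP** (single-cytosine methylation polymorphism): a cytosine whose
  binary methylation *status* differs (re-/de-methylated).
* **DMR** (differentially methylated region): a merged run of 200-bp
  windows enriched in same-direction DMPs.

Downstream statistics quantify **recurrence** (are drought-induced events
concentrated in "hot spots"?), **maintenance** (do events induced in G0
persist in the drought lineage of advanced generations?), and
**transgenerational inheritance** (do events accumulated between D0 and
D10 survive both another treated generation and the removal of stress?).

## Methylation calling model

For each sample, a cytosine with $n$ reads of which $x$ support
methylation is tested against the conversion-error background with a
one-sided binomial test, $p = P(X \ge x \mid n, p_e)$. The error
probability combines the bisulfite non-conversion rate $\varepsilon_{nc}$
— estimated as the pooled methylated-read fraction over an unmethylated
lambda phage spike-in — with a configurable T-to-C sequencing error rate
$\varepsilon_{tc}$ (default 0.001, taken as configuration because the
spike-in cannot separate it from non-conversion):

$$p_e = 1 - (1 - \varepsilon_{nc})(1 - \varepsilon_{tc}).$$

P-values are Benjamini–Hochberg corrected over all callable sites
(coverage $\ge$ 3) and a site is called methylated at $q \le$ 0.05, which
keeps the proportion of false methylation calls among truly unmethylated
cytosines below 5%. The "false positive rate below 5%" requirement is
operationalised as FDR control rather than a raw per-site threshold; a raw
mode (`method = "raw"`) is retained for sensitivity analysis.

Two definitions recur throughout and are kept strictly apart:

* **methylation level** of a site = methylated reads / covering reads; of
  a region = the *unweighted mean* of site levels (the read-pooled ratio
  is available as `pooled = TRUE` but is not the default, because deep
  sites would otherwise dominate a region);
* **methylation density** of a region = methylated cytosines / cytosines.
  The denominator defaults to callable cytosines; counting uncallable
  sites (`denominator = "all"`) makes density depth-dependent, which is
  why it is opt-in.

The MSRE-qPCR validation formula, level $= 2^{-\Delta\Delta Ct} \times
100\%$ with $\Delta\Delta Ct = Ct_{digested} - Ct_{undigested}$, is
provided for completeness (`msre_qpcr_level()`); values above 100% are
returned as computed, with a warning, rather than truncated.

## Differential calling

**DMPs.** Only the *eligible* universe — cytosines with coverage $\ge$ 3
in all 16 samples — is tested. For groups $\{g_1r_1, g_1r_2\}$ vs
$\{g_2r_1, g_2r_2\}$, each of the four cross-group replicate pairings gets
a Fisher exact test on its (methylated, unmethylated) 2x2 table, combined
conservatively by Bonferroni: $p_c = \min(1, 4\min_{ij} p_{ij})$. A site
is a candidate when $p_c < 0.01$ *and* neither within-group
replicate-vs-replicate Fisher test is significant at the same threshold
(sibling discordance disqualifies a site). Genome-wide FDR is controlled
by Benjamini–Hochberg across the combined p-values of **all** tested
sites, reporting candidates with $q \le 0.05$. We deliberately do not
restrict the BH correction to the candidate set: correcting only
pre-selected small p-values is anti-conservative, and on the package's own
null-plus-spiked simulations it inflates the empirical FDR to roughly
13%, versus under 5% for genome-wide correction. Direction is hyper when
the pooled level of group 1 exceeds group 2. Fisher tests are two-sided by
default (one-sided modes exposed), and a replicate-pooled single-test
combine mode is available as an alternative interpretation of the
per-site combination.

The 2x2 Fisher test itself is implemented vectorised over millions of
tables (sum of hypergeometric point probabilities not exceeding the
observed table's); the test suite pins it against `stats::fisher.test`
and against an exhaustive log-binomial enumeration oracle for every table
with row margins up to 30.

**SMPs.** A site is an SMP when both replicates of one group share one
binary status, both replicates of the other group share the opposite
status, and the site is not status-invariant across the entire 16-sample
panel (invariant sites carry no information and are removed from the SMP
universe). Any uncallable status in the four comparison samples skips the
site.

**DMRs.** 200-bp windows advanced in 50-bp steps tile each chromosome
from position 1. Per window, a Fisher test compares replicate-pooled
counts between groups; BH correction runs over all tested windows. A
window is retained when adjusted $p < 0.01$, the pooled level changes
$\ge$ 1.5-fold, and it holds $\ge$ 7 DMPs matching the window's
direction. Retained same-direction windows with gaps $\le$ 100 bp are
merged; opposite-direction neighbours are reported separately. Numerical
choices: windows with a zero level on one side use the pseudo-level
$1/(\text{pooled reads}+1)$ for the fold change; windows with both levels
zero are never candidates; terminal partial windows are tested only when
they still hold $\ge$ 7 eligible cytosines. Merged DMRs are trimmed to
their outermost supporting DMPs by default (`trim = FALSE` restores
window-union boundaries): window unions overhang a true differential run
by up to a window width, and trimming is what keeps recovered boundaries
within 100 bp of planted region events in the package's own simulations.

## Dynamics across generations

**Recurrence.** Over $K$ comparisons (here the four drought-vs-control
comparisons), a locus+direction pair recurring in $\ge 2$ comparisons is
a hot-spot candidate. Position events match exactly by (chrom, pos,
strand, direction); DMRs match by reciprocal overlap $\ge$ 50% with equal
direction (the threshold is configurable; region identity across
independent callings has no exact equivalent). The observed recurring
fraction is judged against the uniform-random expectation: with
per-comparison counts $k_i$ over $N$ eligible loci and
$p_i = k_i / N$, each locus's hit count is Poisson-binomial and

$$E[\text{recurring fraction}] =
  \frac{1 - \prod_i (1-p_i) - \sum_i p_i \prod_{j \ne i}(1-p_j)}
       {1 - \prod_i (1-p_i)},$$

a ratio of expectations that the test suite checks against exhaustive
enumeration on a tiny universe and against seeded permutation (placing
$k_i$ events without replacement, 100 replicates by default).

**Maintenance.** An event induced in G0 (called between D0 and W0) is
maintained when the same locus+direction is called in the advanced
drought-vs-control comparisons — in at least one of them (`mode = "any"`,
the default) or in all (`mode = "all"`). The wording "maintained in
advanced generations" is genuinely ambiguous between the two readings, so
both are computed; percentages are reported per direction and pooled, the
pooled value always being the ratio of summed counts.

**Transgenerational inheritance.** An accumulated event (D10 vs D0) is
transgenerational when its locus+direction appears both in at least one
drought-treated offspring comparison (D11 vs D0) and in at least one
well-watered recovery comparison (D10R1 vs D0): the change survived
another treated generation *and* the removal of stress.

**Clustering.** Samples are clustered by average-linkage agglomeration on
per-sample methylation levels at a chosen locus set (Euclidean or
1-correlation distance); loci undefined in any sample are dropped and
columns are ordered lexicographically by label so ties resolve
deterministically. The dendrogram is exported as Newick.

All printed percentages round half-up to two decimals
(`round_half_up()`); base R's round-half-even would disagree with the
published style of reporting on exact .005 boundaries.

## The synthetic methylome generator

Every stage is validated against `simulate_methylome()`, which emulates
the study design rather than any particular dataset. Defaults are the
study conditions where stated, and a field-typical choice elsewhere:

| parameter | default | rationale |
|---|---|---|
| samples | 16 = 4 generations x 2 treatments x 2 siblings | the design |
| `depth_mean` | 13 | reported mean strand-specific depth (~13.45x / ~11.21x) |
| coverage model | Poisson (`nbinom` switch, size 5) | only the mean depth is reported |
| `nonconversion_rate` | 0.005 | typical lambda-calibrated non-conversion |
| `mc_fail_rate` | 0 | over-conversion knob, off by default |
| `tc_error_rate` | 0.001 | typical Illumina T/C confusion |
| `context_mix` | CG .25 / CHG .25 / CHH .50 | CHH is the most abundant context in a grass genome |
| `te_fraction` | 0.35 | TEs cover at least ~35% of the rice genome |
| `base_level_by_context` | CG bimodal-high, CHG intermediate, CHH low; TE sites methylated in all contexts | the canonical plant methylome shape |
| `effect_size` | 0.6 | no induced-effect-size distribution is published; 0.6 gives the 0.8-to-0.2 contrasts used in the recovery suites |
| `maintenance_prob` | 0.8 | free parameter of the inheritance model |
| `hotspot_fraction` / multiplier | 0.01 / 10 | a small locus class with strongly elevated induction |
| `n_lambda_sites` | 1000 | spike-in for conversion calibration |

Sites are *derived from* a simulated random reference sequence (both
strands scanned for cytosines, context read off the sequence), so context
assignment, strand handling and annotation run on exactly the same
substrate as real data. Gene/TE features are laid out along the sequence
with exon/intron/UTR structure, and the generator emits standard formats:
per-sample cytosine reports, FASTA, GFF3, and a TSV truth ledger.

The event model has three classes:

1. **Drought-induced point events**: per generation, sites shift their
   true level by `effect_size` in that generation's drought group only.
   Direction is hyper when the baseline is below 0.5 (hypo otherwise), so
   a planted contrast always survives clamping to [0, 1] at half the
   effect size or better. Hot spots draw induction independently each
   generation at the elevated rate, creating true recurrence.
2. **Inheritance** follows the lineage: a G0-induced change persists into
   the G10 drought lineage with probability `maintenance_prob`, and, given
   G10, onward into G11 and into the recovery generation G10R1, each with
   the same probability (a Markov chain on the pedigree, not independent
   per-generation draws — under it, presence in G10 implies presence in
   "any" advanced generation, so the any-mode maintained fraction
   estimates `maintenance_prob` directly).
3. **Generational drift** (`drift_rate`): sites that shift in *both*
   lineages of all advanced generations, modelling spontaneous
   epimutation accumulation between G0 and G10. Induced D-vs-W contrasts
   alone cannot reproduce the observed clustering structure in which all
   four G0 samples separate from the advanced generations; drift is what
   creates that G0-vs-descendants axis. Drift sites are sampled disjoint
   from induced sites so that every ledger event retains its full planted
   contrast in its inducing comparison.

Region (DMR-like) events are planted as runs of $\ge$ 8 cytosines within
200 bp shifted as a unit (in regions free of point events), giving the
window caller recoverable targets; their contrast guarantee holds at
region level, because clamping of individual extreme-baseline sites
averages out in pooled window counts.

Determinism: the design seed drives reference construction and event
planting, and each sample's read sampling runs on a fixed per-sample
substream, so identical designs are byte-identical on disk and sibling
replicates share truth while differing only by sampling noise.

### What the generator does *not* emulate

Read-level artefacts (mapping bias, clonal duplicates, M-bias),
sequence-driven methylation (the simulated baseline is independent of the
local sequence beyond context), linked genetic variation, and
chromosome-scale methylation territory structure. Passing recovery tests
therefore demonstrates the correctness of the statistical machinery under
the stated sampling model, not robustness to alignment artefacts — those
are upstream of this package's inputs.

## Problem sizes used in the validation suites

The packaged suites run the full 16-sample design at 8,000–10,000 sites
per run: 10,000 sites at 30x with ~200 planted point events for DMP
recall/FDR, ten planted region events for DMR recovery, 50,000 sites for
the null false-positive bound, and 8,000 sites at the design depth (13x)
for clustering. These sizes give binomial standard errors comfortably
inside the asserted bounds (e.g. recall $\ge$ 0.95 is tested where the
point estimate is ~0.97–0.99 over ~200 events) while keeping each suite
in seconds. The random-recurrence expectation is computed at the full
published scale — four placements of 858,301 events over 86,672,538
eligible cytosines — since both the analytic form and the permutation
scale comfortably.

## Known limitations and open choices

* The published per-comparison event counts behind the pooled recurring
  totals are not printed; the random-recurrence reproduction splits the
  pooled total evenly across the four comparisons. The expectation varies
  only in the second decimal under any split consistent with the total.
* The per-generation accumulation figure reported alongside the
  accumulated-DMP total does not follow from the printed total and any
  stated divisor; this package reports total / number-of-generations and
  leaves reconciling the published average to the reader.
* Promoter length (1 kb upstream of the TSS) and the TE-first labelling
  precedence are not published choices; both are parameters and are
  echoed into output headers.
* DMR identity across comparisons (reciprocal overlap 50%) is this
  package's convention; published methods are silent on region matching.
* The coverage filter treats strands separately ("strand-specific"
  coverage); symmetric-CG collapsing is intentionally not performed.
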