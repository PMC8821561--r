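---
title: "Methods: ensemble CNV call-set combination, filtering and benchmarking"
author: "cnvensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble CNV call-set combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvensemble)
```

## The problem

Copy-number variants (CNVs) — deletions (DEL) and duplications (DUP)
larger than ~50 bp — are called from whole-genome sequencing by tools
that read different signals: discordant read-pair orientation and
split reads (Delly, Manta) or depth-of-coverage deviations in fixed
bins (ERDS, CNVnator).  Call sets from such tools overlap poorly, each
signal has characteristic failure modes, and no single caller gives an
acceptable compromise between sensitivity and positive predictive
value.  `cnvensemble` implements the ensemble approach: normalize the
four callers' outputs into a single representation, clean each set
with per-caller filters, and combine them, either permissively (union)
or conservatively (intersection-union), optionally followed by a
non-reference genotype filter applied to externally regenotyped calls.

## Core conventions

**Coordinates.**  All intervals are 0-based half-open internally.  At
the VCF boundary, internal `start = POS` and internal `end = INFO/END`,
so the internal length is `END − POS` — the same span a
bedtools-style VCF-to-BED conversion produces for symbolic SV records,
which keeps reciprocal-overlap arithmetic consistent across sources.
The alternative convention (`start = POS + 1`, treating POS as the
base before the event) differs by a single base pair; we chose the
span-consistent one and apply it symmetrically on read and write, so
the conversion is a bijection.  Contig names are normalized by
stripping a `chr` prefix (configurable), since hg19-era resources mix
both dialects.

**Reciprocal overlap (RO).**  For intervals $a$, $b$ with intersection
length $o$,

$$\mathrm{RO}(a,b) = \min\!\left(\frac{o}{|a|}, \frac{o}{|b|}\right)
                   = \frac{o}{\max(|a|,|b|)}.$$

Two calls are considered shared at RO > 0.5; the stricter 0.75 is used
for within-pair intersection and the delamp filter.

**Matching.**  Call-to-call comparison uses *greedy one-to-one*
matching: candidate pairs at or above the threshold are accepted in
decreasing RO, ties broken by the leftmost left-side call then the
leftmost right-side call, and each call joins at most one pair.  The
convention is not dictated by the RO definition itself — one-to-many
counting is equally defensible — so we fixed the deterministic,
oracle-checkable variant and exposed many-to-many semantics separately
(`count_overlaps()`, `max_allele_frequency()`) under different names.
A useful consequence of greedy acceptance in threshold order: the
matching at a higher threshold is exactly the subset of the matching
at a lower one, so threshold monotonicity holds structurally, not just
statistically.

## Filters

Each filter is contractive (output ⊆ input), idempotent, and returns a
report in which `retained + removed = input` always holds.

* **delamp** (`filter_delamp`, RO ≥ 0.75): a paired-end caller
  occasionally labels one locus both DEL and DUP.  Both members of any
  cross-type overlap at or above the threshold are removed — a locus
  carrying both labels is untrustworthy in either.  Removing all
  participants (rather than a one-to-one matching) makes a single pass
  sufficient and the postcondition (no surviving cross-type pair)
  checkable by exhaustive scan.  Applied within each paired-end
  caller's own set, before any intersection.
* **Support fraction** (`filter_support_fraction`, > 0.3): retain a
  call if its paired-end *or* split-read support fraction exceeds the
  threshold, strictly — "above 0.3" is implemented as printed.  For
  Delly-style records the fractions are computed as
  `DV/(DV+DR)` and `RV/(RV+RR)`; when neither fraction is available
  the call is retained and flagged not-applicable, because a quality
  filter should not punish absent metadata.
* **Adjusted p** (`filter_adjusted_p`, < 0.5): coverage callers such
  as CNVnator attach an adjusted p value; absent values are again
  retained and flagged.
* **Same-signal confirmation** (`filter_same_signal_confirmation`):
  retain calls confirmed by the same-signal partner caller
  (Delly↔Manta, ERDS↔CNVnator) at RO 0.5 or 0.75.
* **Non-reference genotype** (`filter_genotype_nonref`): after
  external regenotyping, keep HET/HOM_ALT.  Missing genotypes are
  removed *conservatively* and counted separately — unlike the quality
  filters, a regenotyping filter exists precisely to demand genotype
  evidence.
* **Population frequency** (`filter_frequency`, AF ≤ 0.05 at RO ≥ 0.5):
  remove calls whose maximal allele frequency among qualifying
  population SV records exceeds the threshold.  We require same-svtype
  records and reciprocal (not any-bp) overlap by default, for
  consistency with the call-sharing rule; both knobs are configurable
  because the reference-matching criterion is a genuine judgment call.
  Multi-allelic AF entries collapse to their maximum.
* **Size/type rules and region masks** (`filter_size_and_type`,
  `filter_region`): optional, off by default.  Large gains (> 50 kb)
  from coverage callers are rarely confirmed and can be dropped by
  rule; blacklist/exon masks use plain shared-bp (bedtools-intersect)
  semantics, deliberately distinct from RO matching.

## Combination strategies

* **Union** (`combine_union`): joins all four sets; same-type calls
  matching at RO ≥ 0.5 collapse into one record.  Collapsing is
  iterative greedy in caller priority order (Manta > Delly > ERDS >
  CNVnator — paired-end callers are base-pair precise, coverage
  callers are limited by bin size).  Representative coordinates come
  from the highest-priority source; provenance lists every supporting
  caller with its original interval.  Iterative greedy, rather than
  clique merging, is deterministic and order-stable; when a chain of
  calls overlaps pairwise but not transitively the chain resolves in
  priority order, a documented deviation risk we accept.
* **Intersection-union** (`combine_intersection_union`): delamp each
  paired-end set, intersect Delly∩Manta and ERDS∩CNVnator separately
  at RO ≥ 0.75, then union the two pools at RO ≥ 0.5.  Every output
  call therefore carries provenance from both members of at least one
  same-signal pair — an invariant asserted on the output alone in the
  tests.
* **`*_sv2` variants** (`run_strategy`): either strategy followed by
  the non-reference genotype filter over an externally regenotyped
  VCF.  The regenotyper itself (an SVM classifier in the reference
  workflow) is out of scope: the toolkit writes candidate calls and
  consumes the genotyped output, matching records by id with a
  best-RO (≥ 0.9) fallback.  Deduplication happens before
  regenotyping; a flag to reverse that order was considered and
  dropped as it changes only ids, not intervals.

The final dedup threshold of the union step is not forced by the
strategy definition; we use the conventional sharing threshold 0.5 and
expose it (`dedup_ro`).

## The simulator

`simulate_truth()` draws non-overlapping truth calls: svtype
Bernoulli(0.6 DEL), sizes log-uniform on [1 kb, 100 kb], positions
uniform over four 60-Mb contigs.  The size is drawn once per call and
only the *position* is re-sampled on collision, so crowding cannot
bias the size distribution (verified by a goodness-of-fit test).  The
size range is chosen where all four signal types plausibly operate —
above the coverage-caller bin resolution and in the range array
platforms report — making a flat per-caller sensitivity table
physically meaningful.

`simulate_caller()` applies a per-caller error model: detection
probability 0.9 (scalar or svtype × size-bin table), false positives
at 5/Mb placed uniformly with truth-distribution sizes, independent
rounded-Gaussian breakpoint jitter (sd 100 bp for coverage callers,
echoing their bin size; 0 for paired-end callers), an optional
opposite-type mislabel probability (paired-end only — coverage signal
cannot confuse loss with gain), and optional correlated "shared
artifact" calls injected into every caller.  Labels
(TRUE_POSITIVE / FALSE_POSITIVE / SHARED) partition the output
exactly.  Mislabel and shared-artifact rates default to 0: they are
switched on explicitly by the tests that exercise the delamp filter
and the SHARED label, keeping the default conditions aligned with the
independence assumptions of the analytic oracle below.

**What the simulator does not emulate:** nested and tandem CNVs,
GC-coverage bias, breakpoint-sequence effects, caller-to-caller error
correlation beyond the explicit shared-artifact channel, and
inheritance structure.  Passing tests demonstrate the *combinatorial*
correctness of matching, filtering and pooling under a known error
model — not caller behavior on real genomes.

## Analytic oracle and expected performance

Under caller independence, a truth call survives the
intersection-union iff at least one same-signal pair detects it twice:

$$s_{IU} = 1 - (1 - s_1 s_2)(1 - s_3 s_4),$$

which at $s_i = 0.9$ gives $1 - 0.19^2 = 0.9639$; the union analogue is
$1 - \prod_i (1 - s_i)$.  The expected number of false positives
surviving a pair intersection is obtained by numerically integrating,
over the log-uniform size distribution on a deterministic grid, the
measure of relative placements at which two independent intervals
reach RO ≥ 0.75.  The formula ignores breakpoint jitter; under the
default conditions the jitter-induced deficit is ≈ 0.001 (it grows for
truth sizes comparable to the jitter sd), within the Monte-Carlo error
of the recovery experiment (20 cohorts × 2000 truth calls) that the
acceptance tests run.

## Benchmarking semantics

Statistics are computed over a *labeled call pool*, not genome-wide:
sensitivity = TP retained / TP; "specificity" = FP removed / FP (the
fraction of labeled false calls the transform eliminates); PPV = TP
retained / all retained, undefined (NA) when nothing is retained;
accuracy = (TP kept + FP removed) / pool size — this definition is
declared by the package, since pool-based "accuracy" admits several
readings; and the PPV ratio divides the post-filter PPV by the
unfiltered pool's PPV.  SHARED and DOUBTFUL labels are excluded from
the 2×2 table and reported alongside.  `detection_rate()` additionally
reports the best observed RO per truth call, the standard diagnostic
when a low-resolution reference technique (e.g. array CGH) defines the
truth intervals: most misses at RO 0.5 are near-misses with a lower
overlap.

## Numerical and degenerate-input choices

Thresholds compare as printed: support fraction strictly `>`,
adjusted p strictly `<`, RO and AF inclusive (`>=`, `<=`).  Empty call
sets flow through every stage and write header-only files.  Calls
below 50 bp are rejected at construction (the SV size convention);
sub-minimum and unresolvable VCF records are skipped-and-counted by
default, or abort under `strict = TRUE`.  Genotypes absent altogether
are distinct from MISSING until a genotype filter runs, at which point
both are treated as missing evidence.  Positions are stored as
doubles (exact below $2^{53}$), so concatenated-genome coordinates are
safe.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config()              # the default study conditions
cohort <- simulate_cohort(cfg, seed = 1)
iu <- run_strategy("intersection_union", cohort$callsets)
detection_rate(cohort$truth, list(iu = iu$calls), ro_min = 0.5)$any_fraction
```

Problem sizes used throughout the suite: oracle-equivalence checks run
on hundreds of random instances of 40–500 calls; the parameter-recovery
experiment uses 20 cohorts of 2000 truth calls on a 240-Mb genome;
containment properties run on 50 simulated four-caller cohorts of 60
truth calls.

## Known limitations

Inversions, insertions, translocations and breakend records are out of
scope (skipped with a count on read).  The union's iterative greedy
dedup is order-dependent for non-transitive overlap chains (see
above).  The regenotyper is consumed, not modeled.  Real-data
performance claims require real labeled data; the package's own
numbers quantify internal consistency and recovery of its simulator's
configured error model.
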