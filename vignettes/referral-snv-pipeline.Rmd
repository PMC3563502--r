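---
title: "Annotating and classifying SNVs from a referral-laboratory gene screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and classifying SNVs from a referral-laboratory gene screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvcohort)
```

## The problem

A referral laboratory that sequences a single disease gene for years
accumulates a cohort of patient-variant observations that is deliberately
enriched for rare variation: most samples arrive only after a common-mutation
panel failed to explain the phenotype. Summarizing such a cohort raises a set
of bookkeeping problems that are simple individually but easy to get subtly
wrong in combination: mapping HGVS coding-DNA (c.) positions onto codons and
gene regions, deciding which variants are novel relative to several mutation
databases, counting variants within and across self-reported ethnicity
groups, and applying a laboratory's stepwise classification heuristics
consistently. `snvcohort` implements that bookkeeping as small, separately
testable functions plus one deterministic pipeline, with a fully seeded
synthetic-data generator so every summary table can be checked against
planted ground truth.

The package is written around a CFTR-shaped use case — a 27-exon gene coding
for a 1480-residue protein, a cohort of 555 patients over eight ethnicity
groups, 184 distinct single-nucleotide variants — but every one of those
quantities is a parameter.

## Coordinates and regions

All positions use HGVS c. convention: c.1 is the A of the initiator ATG,
intronic positions hang off the nearest exonic base (`c.869+11` is 11 bases
into the intron after the exon ending at c.869), and upstream positions are
`c.-N`. The codon mapping is the usual arithmetic bijection,
codon = floor((pos − 1)/3) + 1 and phase = ((pos − 1) mod 3) + 1, so c.1408
lies at phase 1 of codon 470 — which is why a substitution there is reported
as p.M470V:

```{r codons}
codon_index(c(1408, 2562, 4389))
```

Region labels are assigned from the descriptor and the transcript model:

* **promoter** — any position upstream of the translational start,
  regardless of distance. No 5'UTR/promoter distinction is made.
* **splice_site** — intronic offsets within `splice_halfwidth` bases of an
  exon/intron boundary. The default halfwidth of 2 interprets "the four
  positions flanking each boundary" as the two intronic bases on each side
  (donor +1/+2, acceptor −1/−2), matching the canonical GT/AG dinucleotides.
  The alternative reading — two intronic plus two exonic bases per boundary —
  is available as `exonic_splice = TRUE` in `annotate_variants()`, which adds
  a second label to boundary-adjacent exonic variants; it is off by default
  because the intronic reading is the conservative one for the splice
  machinery, and because multi-label variants complicate class tallies.
* **intronic** — deeper intron offsets; a strict `> 20` bp rule further
  flags **deep intronic** positions (offset 21 is deep, offset 20 is not).
* **exonic** — everything else inside the CDS; exonic variants are
  translated with the standard nuclear genetic code into synonymous,
  missense or nonsense calls. Stop-loss and start-loss collapse into
  missense, since the six-class scheme has no separate category for them.

Intron-offset descriptors are validated against the model: `c.N+k` requires
N to be the last coding base of an exon, `c.N-k` the first base of the next
one, and `|k|` may not exceed the intron length. Reference-allele mismatches
between a descriptor and the model CDS raise errors rather than being
re-anchored: the cohort file is trusted laboratory output, so a mismatch
means the wrong transcript model, which should never be glossed over.

## Database cross-referencing and novelty

Database snapshots are plain sets of canonical variant strings, and matching
is exact string equality after canonicalization — no proximity matching, no
allele flipping. A variant is *novel* exactly when it is absent from every
provided snapshot. Percentages in the presence table are percentages of the
distinct-variant total, rounded half-up to two decimals (`19/36` prints as
`52.78%`); half-up rounding is deliberate, since `base::round()`'s
round-half-to-even would disagree with conventional table formatting on
exact halves.

## Ethnic-stratified summaries

A variant is *ethnic-specific* when its full-cohort support comes from
exactly one ethnicity group. Two conventions needed deciding:

* `Other/Mixed` is a catch-all rather than an ethnicity, so it gets no
  ethnic-specific count of its own (the cell prints `N/A`), but by default
  it still *defeats* specificity of named groups: a variant seen in
  Caucasian patients and in one Other/Mixed patient is not
  Caucasian-specific. The alternative (ignore Other/Mixed support entirely)
  is available as `count_other_mixed_support = FALSE`, since the stricter
  reading could not be confirmed from practice.
* Observation counts weigh homozygotes twice (both alleles carry the
  variant), but distinct-variant counts per group ignore zygosity.

## The classification ladder

`classify_variants()` applies, in order: (1) database/literature pathogenic
assertions (a "suspected" level assertion yields the corresponding suspected
tier); (2) benign assertions; (3) absent contrary evidence, a population
frequency at or above `common_threshold` yields benign, and synonymous or
deep-intronic variants with unknown or sub-threshold frequency yield
suspected benign; (4) otherwise the variant is of unknown significance.
In-silico consensus scores may only move a call between the uncertain tiers
(an extreme consensus converts unknown significance into a suspected tier);
they can never produce pathogenic or benign on their own. Assertion
precedence over the frequency heuristic is this package's explicit choice —
laboratories differ in how they weigh discordant sources, so the order is
fixed, documented, and visible in the per-variant `rule_trace`, which records
every fired rule and replays to the assigned tier.

`common_threshold` defaults to 0.01, the conventional carrier-screening
notion of "common"; it is surfaced as a parameter (and echoed in the run
log) precisely because the underlying practice never pins it down. The
`unrecorded` tier exists only for legacy variants whose evidence row is
flagged `recorded = FALSE`.

## What the synthetic generator emulates

`gen_transcript()` builds a random gene of the configured shape (default 27
exons, 1480 codons ⇒ 4443 nt of CDS including the stop; exon sizes are a
multinomial partition with a 12 bp floor, intron lengths uniform on
60–3000 bp). `gen_cohort()` plants, exactly rather than in expectation:

* 184 distinct variants in a fixed class mix (105 missense, 33 synonymous,
  20 intronic, 12 splice-site, 11 nonsense, 3 promoter). The class totals
  were chosen to keep the missense share at 105 of 184 (57%) while summing
  to the distinct total, because single-label planting cannot reproduce a
  published column sum that exceeds its distinct total due to unidentified
  multi-label variants; the tally code itself handles multi-label variants
  and reports both numbers.
* 107 singletons (observed exactly once, heterozygous).
* four common polymorphisms at exactly 955, 728, 427 and 236 observations
  (a missense, two synonymous and one intronic variant, mirroring the
  classes such polymorphisms had in practice), with homozygotes planted
  wherever an observation count exceeds the cohort size.
* patient ethnicities drawn from weights proportional to 61/1/4/403/40/3/1/42
  over the eight groups; 70% of non-common variants are confined to a single
  weighted group, producing a realistic ethnic-specific structure.

`gen_snapshots()` withholds exactly `forced_novel_count` (default 21) keys
from all databases and assigns every remaining key a membership triple drawn
from independent Bernoullis (defaults 0.85/0.64/0.40) *conditioned on at
least one inclusion*, via rejection sampling. The conditioning makes the
novel count exact by construction; its price is that each database's
marginal coverage of known variants is p/(1 − Π(1 − p)) rather than p, a
deliberate trade documented here and asserted as such in the tests.

`gen_evidence()` plants a target tier mix (default 97/8/37/30/6/6 overall,
with 4 pathogenic, 8 benign, 3 suspected benign and 6 unknown among the 21
novel variants) subject to the ladder's own constraints: heuristic suspected
benign requires a synonymous or deep-intronic variant, unknown significance
requires one the heuristics do not catch, novel variants can carry
literature but not database assertions, and assertions only name databases
that actually contain the key. If a randomly drawn novel set lacks enough
compatible variants for a quota, the shortfall moves to a compatible tier
and the returned ground truth records what was actually planted.

What the generator does *not* emulate: real CFTR sequence content,
transition/transversion bias, linkage between variants, indels (the entire
package is restricted to single-nucleotide substitutions, the scope of every
tabulated quantity it reproduces), and any correlation between a variant's
class and its population frequency beyond what the evidence planting
imposes. Passing tests therefore demonstrate that the *accounting* — parsing,
coordinate algebra, set operations, stratified counting, rule application —
is correct, not that any biological conclusion transfers to real cohorts.

## Numerical and degenerate-input choices

* Half-up rounding everywhere a percentage is printed, with a 1e−9 epsilon
  guarding against binary representation of exact halves.
* `most_common_variants()` breaks ties by canonical key order so output is
  stable across platforms.
* Empty variant sets are errors for `cross_reference()` (the summary would
  be undefined), while empty inputs to the tally functions return zero
  tables.
* An intron-free model admits no valid intron-offset descriptor, so
  intronic/splice labels are unreachable for it by construction.
* All generator randomness flows through an explicit seed and restores the
  caller's RNG state; the pipeline itself uses no randomness, so reruns are
  byte-identical.

## Problem sizes used in the test suite

The bundled tests run the full default fixture (555 patients, 184 variants,
three databases) once and share it across files; property suites use 1000
random descriptors for the parse/format round trip, exhaustive scans of
small 5–6-exon transcripts against a brute-force boundary oracle, a
10,000-variant cross-reference compared with a per-element membership scan,
and 40 replicate snapshot draws for the binomial coverage check. These sizes
keep the suite comfortably within a few minutes on one CPU while still
exercising every advertised invariant.

## Worked example

```{r example}
dir <- tempfile()
fx <- write_fixtures(dir, seed = 11)
cfg <- run_config(fx$paths$gff, fx$paths$fasta, fx$paths$cohort,
                  unlist(fx$paths$snapshots), fx$paths$evidence,
                  out_dir = file.path(dir, "out"))
res <- run_pipeline(cfg)
res$xref
head(read.delim(res$paths$table1))
```

## Known limitations

Single-nucleotide substitutions only — no indels, so a deletion-heavy locus
needs different machinery; one transcript per gene; no genomic (g.) or
protein (p.) coordinate input; in-silico predictors and literature are
opaque inputs, not computed; and the classification ladder predates (and
does not implement) the 2015 ACMG/AMP criteria.
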