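---
title: "Inferring flowering-regulator lncRNAs from short-day / night-break RNA-seq"
author: "lncflower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring flowering-regulator lncRNAs from short-day / night-break RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question and the design

Short-day plants flower when nights are long enough; a night break (NB) —
a short light pulse in the middle of the dark period — breaks that signal
and delays flowering. Sampling leaves early under short days (SD1), late
under short days (SD2), and after a night-break treatment (NB), each with
three biological replicates, creates a two-contrast design in which a
transcript genuinely coupled to the flowering signal should respond to
*both* contrasts in opposite directions: induced from SD1 to SD2
(flowering approaching) and repressed from SD2 to NB (flowering delayed).
`lncflower` applies this logic to long noncoding RNAs: transcripts longer
than 200 nt with no credible protein-coding capacity, a class with known
regulatory roles in plant flowering (e.g. the *FLC*-locus lncRNAs of
Arabidopsis).

A lncRNA that moves in only one contrast is ambiguous — it may follow age,
growth or light-dose rather than the floral signal — so single-contrast
responders are deliberately labelled `none`. Transcripts up in both or
down in both contrasts contradict the antagonistic expectation and are
likewise `none`.

## Stage-by-stage model

### Identification and positional classes

Assembled transcripts not present in the reference annotation are
candidate lncRNAs when spliced length > 200 bp (strict), exon count ≥ 2,
and the coding-potential consensus is `noncoding`. The in-house coding
rule calls a transcript coding when its longest ATG-initiated,
stop-terminated ORF (three sense-strand frames) reaches 300 nt (100
codons): plant lncRNAs typically carry only ~100 bp ORFs while mRNA ORFs
are several times longer, so 100 codons separates the two populations
cleanly. Verdict tables from external tools (CPC, CNCI, CPAT, Pfam or any
others) can be supplied; the consensus is `noncoding` only when *every*
provided call agrees with the in-house call. Intersection was chosen over
majority voting because it is the conservative rule — a single coding
verdict disqualifies a candidate — and the voting scheme is configurable
at the table level (pre-filter the table to implement majority).

Positional classification against the reference gene models is a
first-match cascade — sense (≥ 1 bp same-strand exonic overlap) >
intronic (span within a single same-strand intron) > antisense
(≥ 1 bp opposite-strand span overlap) > lincRNA. The precedence makes the
four classes a deterministic partition; two consequences worth noting:
any same-strand exonic overlap (not full containment) suffices for
`sense`, and a transcript inside an intron on the *opposite* strand is
`antisense`, because the antisense class is strand-defined.

### Expression and replicate QC

FPKM is computed as `counts × 10⁹ / (length × column total)`, with the
"million mapped fragments" denominator taken from the count matrix itself
(externally determined totals can be supplied). A feature is "expressed"
in a condition when its mean FPKM over the three replicates strictly
exceeds 0.1 (lncRNA) or 1 (mRNA) — strict inequalities, so boundary cases
are excluded. Replicate quality is summarized by the Spearman correlation
matrix of all sample pairs.

### Differential expression

The test is a deliberately transparent simplification of the
negative-binomial framework used by DESeq2-class tools (which remain
pluggable through the TSV interface):

* median-of-ratios size factors, rescaled to geometric mean 1;
* per feature and condition, means of normalized counts; the log2 fold
  change is `log₂((μ̂₂ + ½)/(μ̂₁ + ½))` — the pseudo-count of 0.5 keeps
  fold changes finite on zeros while biasing large counts negligibly;
* NB dispersion α (variance μ + αμ²) by method of moments within each
  condition, pooled with df weights. With three replicates the raw
  estimate has 4 df and routinely collapses below the truth, which would
  inflate the Wald statistic badly (measured type-I error ~0.11 at a
  nominal 0.05), so each feature's dispersion is floored at the
  genome-wide *median* of the raw estimates — the same information-sharing
  idea as DESeq2's fitted-trend lower bound, in its simplest form. With
  the floor the measured null type-I error sits within three binomial
  standard errors of 0.05 (checked at 2000 null features in the test
  suite);
* Wald `z = log2FC / SE` with the delta-method SE, two-sided normal
  p-value, BH-FDR over all tested features (all-zero features are
  excluded from the family);
* calls: FDR < 0.05 and |log₂FC| ≥ 1; the orientation is second-named
  condition over first, so "up in SD1_vs_SD2" means higher at SD2.

The per-feature log2FC estimate at 3 vs 3 replicates, mean 100 and
dispersion 0.1 has a sampling standard deviation near 0.4, so accuracy is
asserted on the *mean* estimate across ≥ 200 planted features (a bias
check), not per feature.

### Targets, flowering labels, networks, enrichment

*Cis* targets are coding genes whose genomic span lies within 100 kb of
the lncRNA span — inclusive at exactly 100 000 bp, strand-agnostic, with
overlapping spans at distance 0. Host genes of sense/intronic lncRNAs are
*not* excluded; they appear at distance 0, and callers can drop them if
desired. *Trans* targets require both |PCC| > 0.9 and p < 0.01 (strict),
with the correlation computed on log₁₀(FPKM + 0.01) — expression heatmaps
in this field are read on the log₁₀ scale and correlations on it are not
dominated by the largest counts; a raw-scale switch is provided.

Flowering labels follow the two-contrast direction logic above. Networks
are bipartite (lncRNA ↔ mRNA) per label with cis and trans edges
mode-tagged and de-duplicated; the common-target report intersects the
pooled (cis ∪ trans) target sets by default, with a trans-only option,
and degree rankings break ties lexicographically so output is stable.
Enrichment is a hypergeometric upper tail per term, BH-corrected across
terms; the default universe is all genes with a nonzero count in at least
one sample, since the proper background for over-representation is the
set of genes that could have been observed at all.

## The simulator: what it emulates and what it does not

`simulate_study()` builds a toy study in seconds: 2 chromosomes × 2 Mb,
200 coding genes (3 exons, 4.2 kb span) in the first 70% of each
chromosome, and 40 lncRNAs — 25 lincRNAs plus 5 each of intronic, sense
and antisense transcripts placed unambiguously with respect to a host
gene, so positional classification has an exact known answer. A gene
desert beyond 100 kb of every gene hosts the lincRNAs that must have no
cis partner; the `cis_fraction` of planted regulators is placed ~2 kb
from a host gene. Coding transcripts carry a 990 nt ORF; lncRNA sequences
are rejection-sampled to have no ORF ≥ 300 nt.

Counts are negative binomial with variance μ + αμ² (α = 0.05 by default,
shared genome-wide), baseline means log-uniform over 10¹–10³ (lncRNAs half
a decade lower, matching their characteristically lower expression), and
per-sample library-size factors log-uniform in [0.7, 1.4] so size-factor
estimation is non-trivial. Planted positive regulators have condition
means (m, m·2ᵉ, m) across (SD1, SD2, NB) with e = 3 by default; negative
regulators the reverse. Planted features draw their baselines from the
top expression decade — regulators that cannot be measured cannot be
recovered, and weak-expression robustness is a separate question from
logic correctness.

Trans modules: each planted regulator receives five target mRNAs whose
log-means track the regulator's *realized* normalized log2 profile, with
a loading solving ρ²/(1−ρ²) against the target's own NB noise so the pair
correlation reaches `trans_target_corr` (0.99 by default) in expectation.
Using the realized profile as the module latent factor — rather than an
additional independent latent added to both sides — matters: a shared
additive factor large enough for ρ = 0.99 would inject ~10 (log₂ units)²
of within-condition variance into the regulator itself and erase the very
DE signal the classifier needs. With the realized-profile construction
the regulators stay plain NB around their condition means.

Twenty regulators are planted (10 positive, 10 negative) rather than a
handful: precision and recall are estimated from the call set, and with
only 5 planted per class a single chance mislabel of a noisy low-count
background lncRNA moves precision from 1.0 to 0.83 — the validation would
measure single-call luck, not method behaviour. With 10 per class one
stray call still leaves precision above 0.9.

What the simulator does *not* emulate — and therefore what passing tests
do not certify on real data: multi-isoform genes and quantification
ambiguity, read-level artifacts (mapping bias, GC effects, rRNA
carryover), mean-dependent dispersion trends, batch effects, partially
overlapping gene models, and any sequence-level signal beyond ORF length.
Results on real studies still depend on upstream assembly quality and on
the external coding-potential tools chosen.

## Numerical and design choices

* Coordinates are 1-based inclusive end to end: GTF on disk and
  GRanges/IRanges in memory share that convention, so no coordinate shift
  exists anywhere in the package and no off-by-one conversion can go
  wrong.
* The 100 kb cis boundary is inclusive and pinned (a gap of exactly
  100 000 bp is in; 100 001 is out) so oracle tests are exact.
* Dispersion floor 10⁻⁸ (after the median floor) avoids zero standard
  errors for perfectly flat features; such features get z = 0, p = 1.
* BH is the classic step-up, returned in input order; ties and order
  preservation are oracle-tested against the reference implementation.
* Degree rankings and all emitted pair tables are sorted with
  lexicographic tie-breaks, making every output file deterministic.
* Fixed seed ⇒ byte-identical outputs, including `summary.json`;
  the pipeline re-derives everything from the seed and config alone.
* The command-line surface is the R API itself plus
  `scripts/acceptance.R`; the audience for this analysis works in R, so a
  separate shell tool would only duplicate `run_pipeline()`.

Problem sizes used by the validation suite — 2000 features for null
calibration, 10⁴ profile pairs for the trans false-positive rate, 500
transcripts for classifier/oracle equivalence, the default toy study for
end-to-end recovery — were chosen so the whole suite runs in well under a
minute per file while leaving the statistical assertions with
three-standard-error headroom.

## Known limitations

The NB Wald test has no outlier handling (Cook's-style) and supports only
two-group comparisons; the enrichment stage tests term sets independently
(no ontology-graph weighting); trans prediction is purely correlational
and cannot distinguish direct regulation from co-response to the
photoperiod signal — indeed the simulator's own cross-label correlations
show how antagonistic modules share targets through sign-flipped
correlation. Headline counts from any real study additionally depend on
assembler and coding-potential tool versions, so set-level identities
(unions, shares, direction logic) are the reproducible quantities, not
raw counts.
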