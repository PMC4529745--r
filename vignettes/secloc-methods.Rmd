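---
title: "Consensus subcellular location assignment: model and design notes"
author: "secloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus subcellular location assignment: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secloc)
```

## The model

`secloc` treats protein subcellular localization as a *rule cascade*
over two evidence sources: curated UniProtKB annotation and the
verdicts of seven sequence-based predictors. The cascade is
deterministic and ordered; the first rule that fires decides the
category, and the fired rule is logged per protein (`ruleTrace`), so
any assignment can be audited.

The core scientific assumptions are:

* **Curation outranks prediction.** A reviewed curated location is taken
  at face value, whatever the predictors say. Unreviewed (TrEMBL-style)
  annotation is machine-derived and is *not* treated as curated by
  default (`reviewedOnly = TRUE`); a flag relaxes this for users who
  trust it.
* **Secretion is a vote.** Four tools observe the same biological
  signal (an N-terminal secretory signal peptide / extracellular
  destination) with roughly independent errors, so agreement is
  evidence: ≥ 3 of 4 votes is "highly likely", 2 "likely", 1 "weakly
  likely". Only curated + highly-likely entries should be counted as a
  secretome; the lower tiers are retained for exploration because some
  of their members are real.
* **Two known confounders are excluded before calling secretion.**
  A transmembrane helix outside the N-terminal 70 residues marks a
  membrane protein (helices *within* the first 70 residues are ignored
  because signal peptides masquerade as them), and a C-terminal
  KDEL-type motif (PROSITE PS00014) marks an ER resident. Either
  exclusion removes a protein from the secreted set regardless of its
  votes.
* **Mitochondria need agreement.** TargetP `M` *and* WoLF PSORT `mito`
  must coincide: on the curated benchmark the conjunction keeps the MCC
  of the better single tool while pushing specificity to 98.5%, whereas
  the disjunction costs accuracy. The price is sensitivity (42.5%), a
  documented limitation — most mitochondrial proteins are simply not
  called.
* **GPI anchoring is a refinement of the secretory call**, requiring a
  SignalP 3 signal peptide (the protocol is explicit about using
  version 3 here, while the secretion vote uses version 4) plus a
  FragAnchor class at or above the threshold. Only "highly probable"
  counts by default, since no class cutoff is prescribed anywhere; the
  threshold is a parameter (`gpiThreshold`). GPI-anchored proteins are
  reported as their own category and are not folded into secretome
  sizes.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `nTerminalCutoff` | 70 residues | helix starts ≤ cutoff are ignored by the membrane rule |
| `gpiThreshold` | `HIGHLY_PROBABLE` | least FragAnchor class counted as a GPI anchor |
| `reviewedOnly` | `TRUE` | honour curated annotation from reviewed entries only |
| `mode` | `strict` | missing predictor verdicts error; `lenient` counts them as negative votes with one warning |
| `minLength` (benchmark) | 70 residues | shorter proteins excluded from evaluation |
| `includeLikely` (summaries) | `FALSE` | add the likely tier to secretome sizes (sensitivity analysis only) |

The membrane cutoff interprets "within the N-terminus" as *helix start
≤ 70*: a helix beginning at residue 71 is membrane evidence, one
beginning at 70 is not. The benchmark keeps reviewed, single-location,
unhedged (no "By similarity" / "Probable" / "Potential"), full-length
(initial Met, ≥ 70 aa, not a fragment) entries; proteins annotated
both cytoplasm and cytoskeleton are counted as cytoskeleton — curated
cytoskeleton entries are routinely double-annotated with cytoplasm, and
treating them as multi-location would empty the cytoskeleton category.

## Design decisions where the protocol is open

* **Cascade order.** Conflicts between rules are not specified anywhere;
  the implementation fixes the order curated → secretion (with
  exclusions) → mitochondrial → ER → WoLF locations → residual
  membrane → unknown, mirroring the order in which the rules are
  conventionally presented, and logs the fired rule so users can audit
  disagreements.
* **ER rule: OR, not AND.** "Predicted using WoLF PSORT and PS-Scan"
  is ambiguous; the implementation ORs the two signals (WoLF `E.R.`,
  or SignalP 4 signal + retention motif), which matches the observation
  that signal-peptide+KDEL proteins "often are luminal ER proteins".
  The choice is visible in each protein's rule trace.
* **Dual WoLF PSORT labels** (`extr_plas`) vote and classify through
  their *first* underscore component, because WoLF PSORT lists the
  dominant compartment first.
* **Multi-location curated entries** collapse to one category through a
  fixed precedence list (secreted first, cytoskeleton before
  cytoplasm); the full mapped set is kept in the rule trace. The
  benchmark, by contrast, excludes them entirely.
* **Bare curated organelle terms** ("Endoplasmic reticulum",
  "Mitochondrion", "Nucleus") default to the non-membrane subcategory;
  only explicit membrane terms map to the membrane split. The
  vocabulary ships as a TSV (`inst/extdata/location_vocabulary.tsv`) so
  a revision is a data update. Unrecognised terms map to `UNMAPPED` —
  never silently dropped — and do not count toward the benchmark's
  multi-location exclusion (otherwise topology notes such as
  "Single-pass membrane protein" would evict valid single-location
  entries).
* **PROSITE subset.** The pattern compiler implements exactly the
  syntax PS00014-class patterns need (literals, classes, exclusions,
  `x`, the C-terminal anchor); repetition ranges and N-terminal anchors
  raise a clean "unsupported construct" error rather than silently
  mis-matching.

## Numerical choices

Sn and Sp are reported in percent to 0.1, MCC to 0.01, both rounded
half-up (base R's `round()` is banker's rounding, which would turn
49.75 into 49.7 half the time). MCC is computed with an exact integer
numerator and one full-precision square root, and reported on the
−1..1 scale. A zero marginal (e.g. a category with no predicted
positives, as happens for vacuolar proteins, which WoLF PSORT never
calls) raises an undefined-metric error that the rule-evaluation table
converts into an `undefined` flag rather than a number.

TMHMM coordinates are kept in their native convention — 1-based,
inclusive — everywhere; there is no internal half-open representation.
Signal-peptide cleavage sites are stored as the last residue of the
signal peptide (a site printed "between 22 and 23" is stored as 22).

## What the simulator emulates — and what it does not

`simulateProteome()` draws truth categories from a configurable mix
whose default approximates a metazoan proteome (≈ 30% cytoplasm, 30%
nucleus, 12% plasma membrane, 8% secreted, 6% mitochondria, small
organelle classes), then derives each tool's *true* verdict from the
truth category and passes it through per-tool asymmetric error channels
(independent false-positive/false-negative flips at the verdict level).
Sequences carry only the features the package itself reads: the
initial Met, a planted C-terminal retention motif for ER-truth
proteins (and a guaranteed motif-free tail for everyone else), and
enough length to host the planted transmembrane helix (start 100) of
membrane-truth proteins. A configurable fraction of proteins receives a
reviewed curated comment instead, including hedged qualifiers and
lower-precedence second locations to exercise the benchmark filters.

This validates the cascade, the parsers (the simulator emits the
tools' native file dialects) and the metrics — *not* the predictors:
errors are independent across tools by construction, whereas real
predictors share failure modes (e.g. all four vote for an N-terminal
TM helix), real sequence biology is absent, and curated annotation is
error-free here. Passing tests therefore demonstrate correctness of
the protocol's logic and arithmetic, not field accuracy on real
proteomes; the reference confusion counts shipped with the package are
what ties the rules to measured accuracy on curated data.

Validation problem sizes, chosen to exercise every category while
keeping the suite quick: the exhaustive decision-table comparison runs
5,184 cases (every vote pattern × TargetP state × 12 WoLF labels ×
TM/motif flags × three curation states × three GPI combinations); the
noiseless end-to-end round trip uses 5,000 proteins; the binomial
noise-recovery check uses 20,000 proteins per scenario (3 binomial
standard deviations ≈ ±0.32 percentage points around the expected
97.68% highly-likely sensitivity at a 6.5% per-tool false-negative
rate); the motif property test enumerates windows over 10,000 random
sequences.

## Known limitations

* Leaderless (non-classical) secretion is out of scope by design; the
  secretome here is the classical, signal-peptide-routed one.
* Mitochondrial sensitivity is intrinsically low (≈ 42%) under the
  agreement rule; per-species mitochondrial proteome sizes are
  underestimates.
* Isoform-specific locations, UniProt XML/RDF dialects and GO terms are
  not parsed; only the flat-text `CC -!- SUBCELLULAR LOCATION` block
  feeds curation.
* The regression of secretome size on proteome size is descriptive
  OLS across species; it ignores phylogenetic non-independence.
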