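---
title: "Prioritizing gene fusion candidates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing gene fusion candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionprior)
```

## The problem

Chimeric-transcript discovery tools run on paired-end RNA-seq routinely
report hundreds to thousands of candidate gene fusions per sample, the
large majority of which are artifacts or passenger events. Because the
tools overlap poorly, practice is to take the *union* of calls from
several callers — which makes the list even longer — and then to shrink
it down to a set small enough for PCR validation. `fusionprior`
implements that shrinking as an auditable cascade: every candidate that
disappears is recorded together with the stage that removed it, and each
sample gets its own result file.

## The cascade

Records from all callers are harmonized into one table (coordinates
1-based inclusive; interbase/0-based caller dialects are shifted on
read), then processed per sample in a fixed order:

1. **Duplicate collapsing.** The same caller can report one fusion
   several times with different supporting reads. Records agreeing on
   (caller, 5' gene, 3' gene, both breakpoints) are merged, with the
   split-read sets unioned. The merge key deliberately includes the
   breakpoints: collapsing on the gene pair alone would conflate
   genuinely distinct isoform junctions. Cross-caller agreement on a key
   is recorded (`multi_tool`), as is recurrence of a key across samples
   (`shared_sample`, the shared-vs-private distinction).
2. **Unannotated-partner filter.** Fusions where either partner's name
   starts with one of the configured prefixes (defaults in
   `default_exclude_prefixes()`: accession-style names such as `LOC`,
   `AC0`, `AL5`, plus `NCRNA`, `RNASE`, `HLA`, ...) are removed — no
   functional hypothesis or driver probability can be formulated for an
   uncharacterized partner. The match is a plain case-sensitive prefix
   test on the gene symbol.
3. **Normal subtraction.** Fusions whose key also occurs in any supplied
   healthy-sample call table are removed (pooled normals: one hit in any
   normal suffices). Fusions present in non-neoplastic tissue are
   unlikely drivers.
4. **Split-read filter.** Only fusions supported by at least one split
   read — a read harbouring the junction within its sequence — are kept;
   without one the junction sequence cannot be reconstructed or
   validated. Consensus-reporting callers pass this filter through their
   reported split-read *count* even though they do not provide the read
   sequences themselves.
5. **Structure classification** (below), then **priority marking**: a
   fusion is *priority* if its junction structure is biologically
   reliable and/or an external driver probability exceeds the threshold
   (strictly; default 0.7). The rule is a union on purpose — the two
   evidence types are complementary and their classifiers overlap
   little. Driver scores are consumed from tables produced by external
   classifiers; they are never computed here, and an absent score is
   `NA`, which never exceeds any threshold.

Stages 2–4 commute as predicates; the order above is fixed so that the
per-stage counts in the run log are well defined.

## Virtual-reference structure classification

For a fusion with 5'-partner breakpoint $b_5$ (last retained transcribed
base) and 3'-partner breakpoint $b_3$ (first retained transcribed base),
let $P(x)$ be the `flank_len` transcript-orientation bases ending at the
breakpoint inclusive (the promoter-proximal side), $T(x)$ the
`flank_len` bases starting immediately after it, and $T_3(x)$ those
starting at it inclusive. Four junction hypotheses are reconstructed
from genomic sequence, each `2 * flank_len` long with the junction at
the midpoint:

| label       | construction            | retains                              |
|-------------|-------------------------|--------------------------------------|
| `PROM_END`  | $P(5')\,T_3(3')$        | 5' promoter side + 3' end side       |
| `END_PROM`  | $P(3')\,T(5')$          | 3' promoter side + 5' end side       |
| `PROM_PROM` | $P(5')\,\mathrm{rc}(P(3'))$ | both promoter sides              |
| `END_END`   | $\mathrm{rc}(T(5'))\,T_3(3')$ | both 3'-end sides              |

The fusion's split reads (or, for consensus-reporting callers, its
consensus sequence) are matched against each reference. The score per
reference is the length of the longest *exact, ungapped* common
substring between the reference and the query or its reverse complement
that **spans the junction** (covers positions `flank_len` and
`flank_len + 1`); `N` never matches. The assigned label is the
reference with the largest score at or above `min_overlap`, ties broken
by a fixed preference order that tries the biologically reliable
structures first; if no reference reaches `min_overlap` the call is
`NO_MATCH`. `PROM_END` and `PROM_PROM` calls — the structures
compatible with active transcription of the chimera — set the
`reliable_structure` flag.

Design choices that were genuinely open, and how they were resolved:

* **Flank length.** A "reference length of 30 bp" could mean 30 per
  flank or 30 total. We use 30 **per flank** (60 bp references), so
  that a 15 bp minimum overlap can sit asymmetrically across the
  junction; `flank_len = 15` reproduces the other reading.
* **Orientation of the symmetric references.** `PROM_PROM` reverses the
  second promoter flank and `END_END` the first end flank, so the two
  retained portions face each other as they would in a fold-back or
  reciprocal rearrangement; the simulator uses the identical
  construction, keeping simulation and classification self-consistent.
* **Exact matching.** Matching is mismatch-free and ungapped. No error
  model is attached to the evidence, exactness admits a trivially
  correct brute-force oracle (enumerate all junction-spanning
  substrings), and the `min_overlap` cutoff — not an alignment score —
  carries the sensitivity/specificity trade-off. Raising `min_overlap`
  can only turn labels into `NO_MATCH`, never change one label into
  another.
* **Breakpoint convention.** $b_5$ = last retained base, $b_3$ = first
  retained base (the common caller convention); this keeps `PROM_END`
  references gap-free and duplication-free at the junction.

## Tunable parameters

| parameter          | default | units | meaning |
|--------------------|---------|-------|---------|
| `flank_len`        | 30      | bp    | flank per side of each breakpoint; reference length is twice this |
| `min_overlap`      | 15      | bp    | smallest junction-spanning exact match that supports a structure label |
| `driver_threshold` | 0.7     | probability | strict lower bound for "high" external driver scores |
| `exclude_prefixes` | 17 prefixes | —  | gene-name prefixes treated as unannotated |
| `tissue`           | unset   | label | `EPI`/`HEM`/`MES`/`AVG`, only used to emit the driver-score coordinate file |

`0 < min_overlap <= 2 * flank_len` is enforced; the defaults are the
operating point used throughout the tests.

## What the simulator emulates — and what it does not

`simulate_fusion_data()` is the test substrate for every stage. It
generates uniform-composition toy chromosomes (default two of 10 kb —
large enough that 60 bp references are effectively unique, small enough
that the whole suite runs in seconds), places fusions of all four
structural classes on both strands, and derives their evidence *from
the same virtual-reference construction the classifier uses*: split
reads for half of the fusions (a read-reporting caller), a consensus
sequence for the other half (a consensus-reporting caller), half of the
reads reverse-complemented. Reads match their generating reference in a
junction-centered core of `junction_margin` bases (default: the whole
read) and are padded with random bases whose first position is forced
to mismatch — so the junction-spanning overlap of a simulated read is
exactly its margin, and a margin below `min_overlap` provably yields
`NO_MATCH`. Planted decoys (excluded-prefix gene names), normal-shared
fusions and zero-split-read fusions are mutually disjoint categories,
which makes the expected removal count of every stage computable from
the ground-truth table alone. Everything derives from one seed;
identical seeds give byte-identical output files.

What passing on this substrate shows: the bookkeeping (collapsing,
recurrence, provenance), the coordinate conventions, and the
classification geometry are exactly right, because recovery on
error-free junction-spanning evidence is exact by construction. What it
does not show: behaviour under sequencing error, gapped or clipped
reads, repetitive genomic context (where several references can share
long substrings), transcript-model (exonic) rather than genomic flanks,
or realistic caller disagreement. Real-data performance depends on
those, and the exact matcher is deliberately conservative there.

Simulation sizes used by the shipped checks: 50 fusions per class for
the classification round trip, 1000 random query/reference pairs for
the oracle comparison, and 40 + 8 planted fusions for the cascade
accounting — comfortably small, chosen so the whole validation runs in
about a minute on a laptop core.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally; the
  interbase dialect is shifted by +1 on read and −1 on write (a
  bijection, covered by tests).
* Merging consensus-only duplicates keeps the *maximum* reported
  split-read count rather than the size of an (empty) read-sequence
  union, so consensus-reporting callers are not zeroed out by
  collapsing; when read sequences exist the count is the union size.
* A fusion reaching the classifier without reads or consensus is an
  error, not a silent `NO_MATCH` — the split-read filter upstream makes
  this unreachable in the pipeline, so hitting it indicates malformed
  input.
* Flanks running off a chromosome end are errors (no silent
  truncation); breakpoints must sit at least `flank_len` from the ends.
* Ties in the structure score are broken deterministically
  (`PROM_END > PROM_PROM > END_PROM > END_END` by default, reliable
  structures first) so reruns are reproducible.

## A small worked example

```{r example}
dir <- tempfile("fpdemo_")
sim <- simulate_fusion_data(dir, seed = 7, n_per_class = 3,
                            frac_decoy = 0.25, frac_normal_shared = 0.25,
                            frac_no_split = 0)
res <- run_pipeline(sim$paths$tumor, sim$paths$genome,
                    normal_paths = sim$paths$normal,
                    score_path = sim$paths$scores,
                    outdir = file.path(dir, "out"))
res$stage_counts
```

```{r example2}
rep1 <- res$reports[[1]]$retained
rep1[, c("gene5", "gene3", "structure_label", "reliable_structure",
         "priority")]
```

Every retained fusion carries its structure call and priority flag;
removed fusions appear at the bottom of each sample's report file with
the stage that removed them in `removal_stage`.

## Known limitations

Flanks are genomic, not exon-aware: a breakpoint near a splice site can
produce references that differ from the spliced fusion transcript, and
real junction reads may then fail the exact match. Gene-symbol matching
is verbatim (no synonym resolution), breakpoint matching is exact (no
fuzzy windows), and reciprocal fusions are deliberately distinct
entities. All of these are conservative: they cause missed merges or
`NO_MATCH` calls rather than wrong ones.
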