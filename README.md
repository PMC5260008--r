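# fusionprior

Filtering and prioritization of gene-fusion candidates from paired-end
RNA-seq.

Chimeric-transcript discovery tools (deFuse-, ChimeraScan-,
MapSplice-style callers) emit long, poorly overlapping lists of
candidate fusions — far more than can be validated by PCR. Taking the
union of several callers, as good practice demands, makes the lists
longer still. `fusionprior` shrinks that union down to a short list of
*priority* fusions through an auditable, sample-centered cascade:

1. harmonize caller outputs (several TSV dialects; interbase/0-based
   coordinates shifted to 1-based) into one record table;
2. collapse same-caller duplicate calls and label cross-caller and
   cross-sample recurrence;
3. remove fusions with unannotated partner genes (configurable
   gene-name prefix list), fusions shared with healthy control samples,
   and fusions lacking split-read support — each removal recorded with
   its stage;
4. classify each surviving fusion's junction structure by
   reconstructing four **virtual references** from breakpoint-flanking
   genomic sequence — promoter side vs 3'-end side retained on each
   partner (`PROM_END`, `END_PROM`, `PROM_PROM`, `END_END`) — and
   finding the longest exact junction-spanning overlap between the
   fusion's split reads (or consensus) and each reference;
5. mark as **priority** every fusion whose structure is biologically
   reliable (`PROM_END` or `PROM_PROM`: promoter retained upstream of
   the junction) **and/or** whose externally computed driver
   probability (two classifier sources supported) strictly exceeds a
   threshold.

The structure call for a fusion with breakpoints $b_5$, $b_3$ uses
references of length $2\ell$ ($\ell$ = `flank_len`, default 30 bp) with
the junction at the midpoint; a read $q$ supports reference $r$ with
score

$$\mathrm{ov}(q, r) = \max \{\,|s| : s \text{ a common substring of }
r \text{ and } q \text{ or } \mathrm{rc}(q) \text{ spanning the
junction}\,\}$$

and the label is the arg-max reference with
$\mathrm{ov} \ge$ `min_overlap` (default 15 bp), else `NO_MATCH`.
External driver scores are consumed from tables; the package never
computes them.

A deterministic simulator (`simulate_fusion_data()`) generates toy
genomes, fusions of every structural class with read/consensus evidence
drawn from the same reference construction, planted decoys,
normal-shared fusions, zero-split-read fusions, driver scores and a
ground-truth table — the substrate for all tests.

## Worked example

```r
library(fusionprior)

dir <- tempfile()
sim <- simulate_fusion_data(dir, seed = 7, n_per_class = 5)
res <- run_pipeline(sim$paths$tumor, sim$paths$genome,
                    normal_paths = sim$paths$normal,
                    score_path   = sim$paths$scores,
                    outdir = file.path(dir, "out"))
res$stage_counts[res$stage_counts$sample_id == "S1", ]
#>    sample_id              stage n_in n_out n_removed
#> 1         S1           collapse   11    11         0
#> 2         S1 filter_unannotated   11    10         1
#> 3         S1      filter_normal   10     8         2
#> 4         S1 filter_split_reads    8     7         1
#> 5         S1          structure    7     7         0
#> 6         S1           priority    7     4         3
```

Reading the log: sample S1 entered with 11 collapsed candidates; one
had an excluded-prefix partner, two were shared with the normal sample,
one had no split reads. All 7 survivors received a structure call, and
4 ended up priority (reliable structure and/or a driver score above
0.7). Each sample's report file (`out/S1_report.tsv`) lists retained
fusions first — with tools, recurrence, structure label, scores and
flags — and removed fusions after, each with its `removal_stage`.

A thin command-line front end is installed at `exec/fusionprior`:

```sh
fusionprior simulate --seed 7 --outdir sim
fusionprior run --genome sim/genome.fa --tumor sim/tumor.tsv \
    --normal sim/normal.tsv --scores sim/scores.tsv --outdir out
```

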