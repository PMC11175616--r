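# cag2caa

Analysis tools for **CAG-to-CAA base-editing strategies at the *HTT*
trinucleotide repeat** in Huntington's disease (HD).

HD onset is driven by the length of the *uninterrupted* CAG run in *HTT*
DNA, not by the encoded polyglutamine length. Because CAA also encodes
glutamine, a cytosine base editor acting on the antisense strand
(CTG-repeat) can convert CAG codons to CAA, shortening the uninterrupted
run without changing the protein. This package implements the computational
methods needed to design and quantify such strategies:

* **Repeat-allele arithmetic** — canonical (`(CAG)^n` + CAA-CAG, n + 2
  glutamines), loss-of-interruption (LOI, n glutamines) and
  duplicated-interruption (DI, n + 4 glutamines) structures; uninterrupted
  CAG length; in-silico conversions (`apply_conversion`); and
  canonical-equivalent *effective CAG* with class offsets (LOI +3, DI −1).
* **Guide/editor target prediction** — Hamming-register enumeration on both
  strands, ranked PAM classes (NGG-restricted BE4max, NGN-relaxed
  NG/SpG/evoCDA1 variants), and mapping of the editing window (13–17 nt
  from the PAM for BE4) onto sense-strand CAG sites.
* **Amplicon QC and conversion calling** — the four read-level filters
  (mean Phred < 20, forward/reverse pair difference, < 6 CAGs, missing full
  primers), codon-wise typing over nine trinucleotide variants, per-site
  CAA percentages with empty-vector baseline subtraction,
  duplicated-interruption and multi-conversion quantification, and
  allele-specific comparisons (Welch t-test across replicates).
* **Onset modelling** — the exponential onset law
  `onset = alpha + exp(beta − gamma·CAG)`, and the least-squares grid
  search `SS = Σ(observed − predicted onset)²` that estimates the
  CAG-equivalent offsets of LOI and DI alleles.
* **Somatic instability** — the expansion index (10% relative peak-height
  threshold, anchored on the tail modal allele):
  `EI = Σ_{Δi>0} f_i·Δi`, with fractions `f_i` over retained peaks; and
  OLS regression of the index on treatment + tail CAG + age + sex + batch.
* **Seeded simulators** for every input: paired amplicon FASTQ with
  configurable per-site conversion, indel and error rates; onset cohorts
  with class offsets; and fragment-analysis traces with geometric expansion
  tails and analytic truth.

## Worked example

The central arithmetic: converting the 42nd CAG of a canonical 43-CAG
allele creates a duplicated interruption, and with the fitted DI offset
(−1 CAG-equivalent) the expected onset moves from the 43-CAG mean (48 y)
to the 40-CAG mean (60 y):

```r
library(cag2caa)

a43 <- canonical_allele(43)
edited <- apply_conversion(a43, 42)
edited
#> <repeat_allele> canonical_43_c42: 45 codons, DI, 41 uninterrupted CAG, 45 glutamines

onset <- onset_table(c(`43` = 48, `40` = 60))
onset_delay(a43, 42, c(DI = -1), onset)
#> [1] 12
```

The edit preserves all 45 glutamines but shortens the uninterrupted run to
41; with the DI offset it behaves like a canonical 40-CAG allele, a
predicted 12-year onset delay.

Target prediction and quantification on simulated MiSeq data:

```r
tpl <- htt_template()   # printed primers; HEK293 16/17-CAG alleles
g2 <- guide("gRNA2", "CTGCTGCTGCTGCTGCTGGA")
predict_edit_sites(g2, editor_be4max(), tpl, tpl$alleles[[2]], max_mismatch = 0)
#>      strand start mismatches mismatch_pos_from_pam pam pam_rank sites
#> 1 antisense    83          0                       AGG        1   4,5

sim <- simulate_reads(tpl, n_pairs = 1500, per_site_caa = c(`2` = 0.3), seed = 7)
qc  <- qc_filter(sim$pairs, qc_params(tpl$primer_fwd, tpl$primer_rev))
qc$report
#> <qc_report> 1500 input pairs, 1140 kept (76.0%)
#>   removed by mean_phred:      0
#>   removed by pair_discordant: 360
#>   removed by cag_count:       0
#>   removed by primer:          0

calls <- call_reads(qc$sequences, tpl)
head(per_site_conversion(calls, tpl$alleles[[2]]), 5)
#>   site pct_all pct_eligible pct_raw  pct
#> 1    1     0.0          0.0     0.0  0.0
#> 2    2    28.6         30.7    28.6 28.6
#> 3    3     0.0          0.0     0.0  0.0
#> 4    4     0.0          0.0     0.0  0.0
#> 5    5     0.0          0.0     0.0  0.0
```

The guide's only NGG register targets CAG sites 4/5; the simulated 30%
site-2 conversion is recovered at 30.7% among clean reads (`pct_eligible`,
binomial noise) and 28.6% of all reads (`pct_all`, the headline
"percent of all sequence reads" convention). Pairs removed as discordant
are those carrying any sequencing error, since mate merging demands an
exact overlap.

See the vignette (`vignettes/cag-to-caa-pipeline.Rmd`) for the model
details, simulator assumptions, and design choices.

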