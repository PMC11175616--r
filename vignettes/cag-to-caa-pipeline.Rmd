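---
title: "Quantifying CAG-to-CAA base-editing outcomes at the HTT repeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CAG-to-CAA base-editing outcomes at the HTT repeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cag2caa)
```

## The scientific problem

Huntington's disease (HD) is caused by an expanded CAG repeat in *HTT*, and
age-at-onset is driven by the length of the *uninterrupted* CAG repeat in
DNA, not by the encoded polyglutamine length. Most disease alleles are
*canonical*: an uninterrupted `(CAG)^n` run followed by a single CAA-CAG
doublet, encoding n + 2 glutamines. Rare alleles lack the doublet (*loss of
interruption*, LOI; n glutamines) or carry it twice (*duplicated
interruption*, DI; n + 4 glutamines). Because CAA also encodes glutamine, a
cytosine base editor acting on the antisense strand can convert CAG codons
to CAA, shortening the uninterrupted run without touching the protein — a
therapeutic hypothesis this package's pipeline is designed to quantify.

The package covers five analysis layers plus a simulation layer:

1. **Repeat arithmetic** (`repeat_allele`, `classify_structure`,
   `glutamine_length`, `uninterrupted_cag_length`, `apply_conversion`,
   `effective_cag`): codon-wise bookkeeping of alleles and in-silico edits.
2. **Guide/editor target prediction** (`enumerate_registers`, `pam_rank`,
   `window_cag_sites`, `predict_edit_sites`).
3. **Amplicon QC** (`qc_filter` and its four component filters).
4. **Conversion calling** (`call_reads`, `per_site_conversion`,
   `duplicated_interruption_fractions`, `multiconversion_histogram`,
   `allele_specific_summary`).
5. **Genotype–phenotype and instability statistics** (`estimate_offset`,
   `onset_delay`, `expansion_index`, `instability_regression`).
6. **Synthetic data** (`simulate_reads`, `simulate_cohort`,
   `simulate_trace`, `simulate_instability_samples`).

## Repeat arithmetic and the onset model

An allele is an ordered codon list; the structure class is always derived,
never declared. Conversion sites are indexed over CAG codons from the 5'
end, skipping the CAG of a CAA-CAG interruption doublet, so a canonical
allele of 43 uninterrupted CAG has exactly 43 addressable sites and "the
42nd CAG" is the penultimate one:

```{r}
a43 <- canonical_allele(43)
edited <- apply_conversion(a43, 42)
edited
```

Editing the 42nd CAG yields a duplicated interruption of 41 uninterrupted
CAG that still encodes 45 glutamines. Patient cohorts show that structure
classes carry *additional* onset effects beyond the uninterrupted length:
LOI carriers behave as if they had about three more CAGs, DI carriers as if
they had one less. `effective_cag()` applies those offsets, and
`onset_delay()` translates an edit into years:

```{r}
onset <- onset_table(c(`43` = 48, `40` = 60))
onset_delay(a43, edit_site = 42, offsets = c(DI = -1), model = onset)
```

The offsets themselves are estimated by `estimate_offset()`: predicted
onsets for a class cohort come from the canonical onset-CAG curve, the CAG
length is shifted over an integer grid (default -10..+10), and the offset
minimizing the residual sum of squares
`SS = sum((observed - predicted)^2)` is reported. Ties are broken toward
the smaller |offset| (parsimony; the choice matters only on degenerate
data). The grid is integer-valued because the published class effects are
whole-CAG equivalents; a finer grid can be passed explicitly.

The parametric onset curve is `onset = alpha + exp(beta - gamma * CAG)`,
the standard exponential-decay family for onset-CAG regression. The default
coefficients (`alpha = 21.5`, `beta = 9.56`, `gamma = 0.146`) are
*simulation defaults* chosen to give realistic onsets (about 52 years at 42
CAG, falling to about 30 years at 50 CAG); they are not re-derived cohort
estimates, which are not printed in the source material.
`fit_onset_model()` fits the same family by profiling gamma (each candidate
gamma reduces the problem to ordinary least squares on `exp(-gamma * CAG)`,
and the profile is polished by golden-section search), which is exact on
noiseless data and avoids start-value sensitivity.

## Guide and editor geometry

A guide is a 20-nt spacer; a register is any placement of that spacer on
either strand with a 3-nt PAM immediately 3' of the protospacer and at most
`max_mismatch` Hamming mismatches (substitution-only, no bulges, matching
the off-target search settings used in practice). Window positions are
counted *from the PAM*: position 1 is PAM-adjacent, and the BE4-class
activity window is positions 13-17, i.e. spacer positions 4-8 from the
PAM-distal end. CAG-to-CAA requires editing the antisense strand: the
edited C pairs with the third-position G of a sense CAG codon.

```{r}
tpl <- htt_template()
g2 <- guide("gRNA2", "CTGCTGCTGCTGCTGCTGGA")
predict_edit_sites(g2, editor_be4max(), tpl, tpl$alleles[[2]],
                   max_mismatch = 0)
```

The two front-end guides anchor the geometry: with 10 and 2 upstream-flank
bases at their PAM-proximal ends they are predicted to convert CAG sites
{1,2} and {4,5} respectively. Ranking in `predict_edit_sites()` is (PAM
rank, mismatch count, PAM-distal mismatch preferred); this operationalizes
the observed behaviour of repeat-composed guides that act through a
one-mismatch register flanked by a stronger PAM, and is an interpretation,
not a published formula. Editor profiles ship as data: BE4max is
NGG-restricted; NG/SpG variants rank NGG first and NGN second; the
evoCDA1-SpG profile widens the window to 11-19 as a configurable stand-in,
since its true bounds are not quantified.

The locus template's flanks are anchored on the printed amplification
primers: the 5' flank ends at the base before the first repeat CAG and the
3' flank begins with the first CCG of the proline-rich tract and ends at
the reverse-primer binding site. Exact spacers for the remaining published
guides live in supplementary material and are therefore user configuration
(`read_locus_config()` reads a YAML with locus, alleles and guides; see
`inst/extdata/htt_locus.yaml`).

## Quality control and conversion calling

`qc_filter()` applies the four published read-level filters in order,
attributing each removal to the first failing filter: (1) mean Phred of
either mate below 20 (the boundary value 20.0 is kept); (2) forward/reverse
pair difference — implemented as failure to find an exact, 0-mismatch
overlap of at least 30 nt between the forward read and the
reverse-complemented reverse read, a deliberate reading of "difference
between forward and reverse read pair" for an amplicon short enough that
mates span the repeat; (3) fewer than 6 non-overlapping CAG occurrences in
the merged read; (4) absence of the full (exact-match) primer sequences.

Kept, merged reads are decomposed into codons between two exact flank
anchors (`decompose_repeat()`), assigned to the nearest-codon-count allele
(ties to the shorter allele — the data do not distinguish a one-codon
deletion of the longer allele from the shorter allele, and the conservative
call is the shorter), and classified as indel-free, in-frame
insertion/deletion, or frameshift. Indel-free reads are typed codon-wise
against the nine trinucleotides scanned in the source protocol (CAT is
deliberately absent; `conversion_type_counts(types = ...)` can extend the
set), excluding the terminal interruption codons. Typing is presence-based
per read; a per-codon mode exists but is off by default.

Per-site conversion restricts the numerator to reads of the expected codon
count containing only CAG or CAA, and reports two denominators: `pct_all`
(all QC-passed reads of the allele — the "percent of all sequence reads"
convention used for headline numbers) and `pct_eligible` (clean reads
only — the estimand that equals an injected per-site conversion
probability, used by the recovery tests). Empty-vector baseline
subtraction floors negatives at zero and keeps the raw value.

```{r}
sim <- simulate_reads(tpl, n_pairs = 1500, per_site_caa = c(`2` = 0.3),
                      seed = 7)
qc <- qc_filter(sim$pairs, qc_params(tpl$primer_fwd, tpl$primer_rev))
qc$report
calls <- call_reads(qc$sequences, tpl)
head(per_site_conversion(calls, tpl$alleles[[2]]), 5)
```

## Somatic instability

`expansion_index()` quantifies somatic expansion from fragment-analysis
peaks already calibrated to repeat units: peaks below 10% of the tallest
peak are discarded as noise, remaining heights are normalized to fractions,
and the index is the fraction-weighted sum of positive repeat-unit gains
over the main allele, which is anchored on the matched tail trace's modal
peak (using the analyzed trace's own modal peak, with a warning, when no
tail anchor is given). Contractions are reported separately by
`contraction_index()` and never enter the expansion index.
`instability_regression()` is ordinary least squares of the index on
treatment plus tail CAG, age, sex and batch, reference-coded to PBS,
female, and the first batch.

```{r}
smp <- simulate_instability_samples(treatment_effect = -0.5, seed = 12)
instability_regression(smp)[1:2, ]
```

## What the simulators emulate — and what they do not

`simulate_reads()` draws amplicons from the template alleles, applies
per-site CAG-to-CAA conversion probabilities, optional non-CAA codon
variants, whole-codon insertions/deletions plus a frameshift class, and
emits full-length mate pairs with independent per-base substitution errors
(default 0.001/base) and Normal(35, 3) Phred profiles. The default
per-read indel probability of 0.10 reproduces the ~10% basal apparent-indel
load reported for repeat amplicon sequencing. Discordant pairs are injected
as reverse-mate-only substitutions. One integer seed makes each simulator
byte-reproducible, and every simulator emits a truth table; estimators are
always tested against truth, never against another estimator.

Deliberately *not* modelled: PCR stutter chemistry (length artifacts appear
only through the generic indel channel), instrument-specific quality decay
along the read, chimeric reads, and UMI structure. Passing recovery tests
therefore demonstrate correctness of the estimators under a clean
generative model, not robustness to every real MiSeq artifact. Likewise
`simulate_cohort()` uses additive Gaussian onset noise (default SD 6 years,
a free parameter — the real residual distribution is unknown), and class
sizes default to the published cohort (n = 21 LOI, n = 69 DI, with a
564-record canonical arm matching the printed reference-allele count).
`simulate_trace()` builds a geometric expansion tail
(`height(+d) = main * tail_frac * tail_decay^(d-1)`) whose analytic index
is recorded as truth; `simulate_instability_samples()` draws indices
directly from a linear model so the regression estimator has exact
generating coefficients to recover.

## Numerical and design choices

* Codon lists, not raw strings, represent the tract: every published
  metric is codon-wise. The CCG-rich proline tract belongs to the 3' flank.
* Conversion sites skip interruption CAGs, so site counts equal the
  uninterrupted length for canonical alleles.
* Phred encoding is fixed at Sanger/Illumina-1.8 (offset 33).
* Flank anchors for decomposition are 12 nt and exact; reads with mutated
  anchors are excluded and counted (`attr(calls, "n_failed")`).
* The empty repeat allele is representable but analysis operations reject
  it (`per_site_conversion` errors on zero eligible reads; `estimate_offset`
  on empty cohorts).
* Test and example problem sizes (10,000 read pairs, 500 offset-recovery
  replicates, 1,000 regression null replicates) were chosen so each
  stochastic check has at least 3-sigma resolution against its target while
  the whole suite stays desk-scale.

## Known limitations

* Genome-wide off-target search is out of scope (an external service was
  used in the source study); registers are enumerated on the supplied locus
  only.
* Deaminase sequence-context efficiency (e.g. reduced activity at GC
  dinucleotides) is carried only as a note on the editor profile, not as a
  quantitative model.
* The expansion-index variant implemented is the threshold-and-main-peak
  rule described for this assay; other published weighting schemes exist.
* With alleles one codon apart (16/17 CAG), single-codon indels are
  genuinely confounded with the other allele; the nearest-count rule makes
  this explicit rather than hiding it.
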