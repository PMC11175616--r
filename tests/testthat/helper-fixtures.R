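# Shared fixtures: the HTT locus template and the two NGG guides whose
# register geometry is known (front-end guides with 10 and 2 flank bases at
# the PAM-proximal end, hitting CAG sites {1,2} and {4,5}).

hek_template <- function() htt_template()

hek51_template <- function() {
  htt_template(alleles = list(canonical_allele(17, name = "normal_17"),
                              canonical_allele(51, name = "mutant_51")))
}

guide_front1 <- function() guide("gRNA1", "GCTGCTGCTGGAAGGACTTG")
guide_front2 <- function() guide("gRNA2", "CTGCTGCTGCTGCTGCTGGA")
guide_polyctg <- function() guide("polyCTG", strtrim(strrep("CTG", 7), 20))

default_qc <- function(tpl = hek_template()) {
  qc_params(tpl$primer_fwd, tpl$primer_rev)
}

# build a concordant pair (full-length mates, uniform quality) from a sense
# amplicon sequence
make_pair <- function(seq, id = "p1", q = 35L, rev = NULL, fwd_q = NULL,
                      rev_q = NULL) {
  if (is.null(rev)) rev <- revcomp(seq)
  d <- data.frame(id = id, fwd = seq, rev = rev, stringsAsFactors = FALSE)
  d$fwd_qual <- list(if (is.null(fwd_q)) rep(q, nchar(seq)) else fwd_q)
  d$rev_qual <- list(if (is.null(rev_q)) rep(q, nchar(rev)) else rev_q)
  d
}

bind_pairs <- function(...) do.call(rbind, list(...))

# independent brute-force register scan used as the enumerate_registers
# oracle: character-vector sliding window on each strand
brute_registers <- function(spacer, locus_seq, max_mismatch) {
  out <- list()
  for (strand in c("sense", "antisense")) {
    s <- if (strand == "sense") locus_seq else revcomp(locus_seq)
    ch <- strsplit(s, "")[[1]]
    sp <- strsplit(spacer, "")[[1]]
    for (start in 0:(length(ch) - 23L)) {
      mm <- sum(ch[start + 1:20] != sp)
      if (mm <= max_mismatch)
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, start = start, mismatches = mm,
          pam = paste(ch[start + 21:23], collapse = ""),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(strand = character(), start = integer(),
               mismatches = integer(), pam = character())
}
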