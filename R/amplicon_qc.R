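#' QC parameters for paired amplicon reads
#'
#' Defaults follow the published filter thresholds: reads with mean Phred
#' below 20, discordant mate pairs, fewer than 6 CAGs, or missing full
#' primer sequences are removed.
#'
#' @param primer_fwd,primer_rev primer sequences (sense orientation, as
#'   supplied to PCR).
#' @param min_mean_phred reads with mean base quality strictly below this
#'   are removed (boundary kept).
#' @param min_cag_count minimum number of CAG occurrences in the merged
#'   read.
#' @param min_overlap minimum exact-match overlap (nt) between the forward
#'   read and the reverse-complemented reverse read.
#' @param primer_slack how far from the read ends the primer matches may
#'   sit (nt).
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(primer_fwd, primer_rev, min_mean_phred = 20,
                      min_cag_count = 6L, min_overlap = 30L,
                      primer_slack = 5L) {
  structure(list(primer_fwd = toupper(primer_fwd),
                 primer_rev = toupper(primer_rev),
                 min_mean_phred = min_mean_phred,
                 min_cag_count = as.integer(min_cag_count),
                 min_overlap = as.integer(min_overlap),
                 primer_slack = as.integer(primer_slack)),
            class = "qc_params")
}

#' Read a paired FASTQ (Phred+33) into a pair table
#'
#' @param r1,r2 paths to the forward and reverse FASTQ files.
#' @return data.frame with columns `id`, `fwd`, `rev` (character) and
#'   list-columns `fwd_qual`, `rev_qual` (integer Phred vectors).
#' @export
read_fastq_pairs <- function(r1, r2) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq",
                                      with.qualities = TRUE)
    q <- as.character(S4Vectors::mcols(x)$qualities)
    list(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
         qual = lapply(q, function(s) utf8ToInt(s) - 33L))
  }
  a <- rd(r1); b <- rd(r2)
  if (length(a$id) != length(b$id) || !all(a$id == b$id))
    stop("R1/R2 ids do not match", call. = FALSE)
  out <- data.frame(id = a$id, fwd = a$seq, rev = b$seq,
                    stringsAsFactors = FALSE)
  out$fwd_qual <- a$qual
  out$rev_qual <- b$qual
  out
}

#' Mean base Phred quality of a read
#'
#' @param quals integer Phred vector.
#' @return arithmetic mean.
#' @export
mean_phred <- function(quals) {
  if (length(quals) == 0L) stop("empty read", call. = FALSE)
  mean(quals)
}

#' Merge a read pair by exact-overlap alignment
#'
#' Reverse-complements the reverse read and searches for an exact
#' (0-mismatch) overlap of at least `min_overlap` nt with the forward read;
#' the merged sense-oriented consensus extends the forward read by the
#' non-overlapping tail of the reverse read. Returns `NA_character_` when no
#' such overlap exists (a discordant pair).
#'
#' @param fwd,rev read sequences (reverse read in sequencing orientation).
#' @param min_overlap minimum exact overlap length.
#' @return merged sequence or `NA_character_`.
#' @export
merge_pair <- function(fwd, rev, min_overlap = 30L) {
  rcr <- revcomp(rev)
  lf <- nchar(fwd); lr <- nchar(rcr)
  for (off in 0:(lf - min_overlap)) {
    n <- min(lf - off, lr)
    if (n < min_overlap) break
    if (substr(fwd, off + 1L, off + n) == substr(rcr, 1L, n)) {
      return(paste0(substr(fwd, 1L, off), rcr))
    }
  }
  NA_character_
}

#' Are the mates of a pair concordant?
#'
#' @param fwd,rev mate sequences.
#' @param min_overlap minimum exact overlap length.
#' @return logical.
#' @export
pair_concordant <- function(fwd, rev, min_overlap = 30L) {
  !is.na(merge_pair(fwd, rev, min_overlap))
}

#' Count CAG occurrences in a sequence
#'
#' Non-overlapping, left-to-right scan on the sense-oriented sequence.
#'
#' @param seq DNA string.
#' @return integer count.
#' @export
count_cag <- function(seq) {
  m <- gregexpr("CAG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Does a merged read carry both full primer sequences?
#'
#' The forward primer must match exactly at (or within `primer_slack` nt of)
#' the 5' end and the reverse complement of the reverse primer must end at
#' (or within `primer_slack` nt of) the 3' end. Matching is exact: the
#' filter requires the full primer sequences.
#'
#' @param seq merged sense-oriented sequence.
#' @param params a `qc_params`.
#' @return logical.
#' @export
has_primers <- function(seq, params) {
  pf <- params$primer_fwd
  pr <- revcomp(params$primer_rev)
  i <- regexpr(pf, seq, fixed = TRUE)
  if (i == -1L || i > params$primer_slack + 1L) return(FALSE)
  j <- gregexpr(pr, seq, fixed = TRUE)[[1]]
  if (j[1] == -1L) return(FALSE)
  end <- max(j) + nchar(pr) - 1L
  end >= nchar(seq) - params$primer_slack
}

#' Apply the four read-level QC filters to paired amplicon reads
#'
#' Filters are applied in the published order — (1) mean Phred of either
#' mate below `min_mean_phred`, (2) forward/reverse pair difference (no
#' exact overlap), (3) fewer than `min_cag_count` CAGs in the merged read,
#' (4) full primer sequences absent — and each removed pair is attributed to
#' the first filter it fails. Kept pairs are returned as merged,
#' sense-oriented sequences.
#'
#' @param pairs data.frame from [read_fastq_pairs()] (columns `id`, `fwd`,
#'   `rev`, `fwd_qual`, `rev_qual`).
#' @param params a `qc_params`.
#' @return list with `sequences` (data.frame `id`, `seq`) and `report` (a
#'   `qc_report`: `n_input`, `n_kept`, `removed_by_filter`).
#' @export
qc_filter <- function(pairs, params) {
  filters <- c("mean_phred", "pair_discordant", "cag_count", "primer")
  removed <- stats::setNames(integer(4), filters)
  keep_id <- character(0); keep_seq <- character(0)
  n <- nrow(pairs)
  for (i in seq_len(n)) {
    if (mean_phred(pairs$fwd_qual[[i]]) < params$min_mean_phred ||
        mean_phred(pairs$rev_qual[[i]]) < params$min_mean_phred) {
      removed["mean_phred"] <- removed["mean_phred"] + 1L
      next
    }
    merged <- merge_pair(pairs$fwd[i], pairs$rev[i], params$min_overlap)
    if (is.na(merged)) {
      removed["pair_discordant"] <- removed["pair_discordant"] + 1L
      next
    }
    if (count_cag(merged) < params$min_cag_count) {
      removed["cag_count"] <- removed["cag_count"] + 1L
      next
    }
    if (!has_primers(merged, params)) {
      removed["primer"] <- removed["primer"] + 1L
      next
    }
    keep_id <- c(keep_id, pairs$id[i])
    keep_seq <- c(keep_seq, merged)
  }
  report <- structure(list(n_input = n, n_kept = length(keep_id),
                           removed_by_filter = as.list(removed)),
                      class = "qc_report")
  list(sequences = data.frame(id = keep_id, seq = keep_seq,
                              stringsAsFactors = FALSE),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d input pairs, %d kept (%.1f%%)\n", x$n_input,
              x$n_kept, if (x$n_input) 100 * x$n_kept / x$n_input else NA))
  for (f in names(x$removed_by_filter))
    cat(sprintf("  removed by %-16s %d\n", paste0(f, ":"),
                x$removed_by_filter[[f]]))
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}
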