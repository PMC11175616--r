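#' The nine trinucleotide conversion types
#'
#' The codon variants tallied when typing conversions in indel-free reads:
#' CAA (the therapeutic conversion), CAG (reference), and the seven other
#' single-codon variants scanned for. The set is deliberately exactly this
#' list; [conversion_type_counts()] accepts an extension.
#' @export
CONVERSION_TYPES <- c("CAA", "CAC", "CAG", "CCG", "CGG", "CTG",
                      "AAG", "GAG", "TAG")

#' Decompose a merged read into repeat-tract codons
#'
#' Locates an anchor at the 3' end of the 5' flank and another at the 5'
#' start of the 3' flank, and returns the codons between them, in frame with
#' the repeat start. Anchors must match exactly; a read in which either
#' anchor cannot be located is a decomposition failure (excluded and
#' counted by the caller). A tract whose nucleotide span is not a multiple
#' of 3 has `codons = NULL` and is a frameshift candidate.
#'
#' @param seq merged sense-oriented sequence.
#' @param template a `locus_template`.
#' @param anchor_len anchor length in nt.
#' @return list with `found` (logical), `nt_span` (integer, NA when not
#'   found) and `codons` (character vector or NULL).
#' @export
decompose_repeat <- function(seq, template, anchor_len = 12L) {
  a5 <- substr(template$flank5, nchar(template$flank5) - anchor_len + 1L,
               nchar(template$flank5))
  a3 <- substr(template$flank3, 1L, anchor_len)
  i <- regexpr(a5, seq, fixed = TRUE)
  if (i == -1L) return(list(found = FALSE, nt_span = NA_integer_, codons = NULL))
  start <- i + anchor_len                       # first repeat base
  j <- regexpr(a3, substr(seq, start, nchar(seq)), fixed = TRUE)
  if (j == -1L) return(list(found = FALSE, nt_span = NA_integer_, codons = NULL))
  span <- j - 1L
  if (span %% 3L != 0L)
    return(list(found = TRUE, nt_span = as.integer(span), codons = NULL))
  tract <- substr(seq, start, start + span - 1L)
  codons <- if (span == 0L) character(0) else
    substring(tract, seq(1L, span, by = 3L), seq(3L, span, by = 3L))
  list(found = TRUE, nt_span = as.integer(span), codons = codons)
}

#' Assign a read to an allele and classify its indel status
#'
#' The read is assigned to the allele with the nearest codon count (ties go
#' to the shorter allele). Status is `none` when counts are equal,
#' `insertion`/`deletion` of k codons when the read differs by whole codons,
#' and `frameshift` when the raw nucleotide span is not a multiple of 3.
#'
#' @param nt_span raw repeat-tract span in nt.
#' @param alleles list of `repeat_allele` objects.
#' @return list `allele` (name), `indel` (status string), `k` (codon
#'   difference, 0 for none/frameshift).
#' @export
classify_indel <- function(nt_span, alleles) {
  stopifnot(length(alleles) >= 1L)
  counts <- vapply(alleles, function(a) length(a$codons), integer(1))
  nm <- vapply(alleles, `[[`, character(1), "name")
  est <- nt_span / 3
  d <- abs(counts - est)
  cand <- which(d == min(d))
  pick <- cand[which.min(counts[cand])]         # ties -> shorter allele
  if (nt_span %% 3L != 0L)
    return(list(allele = nm[pick], indel = "frameshift", k = 0L))
  diff <- as.integer(nt_span / 3 - counts[pick])
  if (diff == 0L) list(allele = nm[pick], indel = "none", k = 0L)
  else if (diff > 0L) list(allele = nm[pick], indel = "insertion", k = diff)
  else list(allele = nm[pick], indel = "deletion", k = -diff)
}

n_interruption_codons <- function(structure) {
  switch(structure, CANONICAL = 2L, DI = 4L, 0L)
}

#' Call conversions on QC-passed reads
#'
#' Decomposes each merged read, assigns it to an allele, classifies indels,
#' and (for indel-free reads) records the CAG sites converted to CAA
#' relative to the assigned allele's reference codons. A read is `clean`
#' when it is indel-free and every codon is CAG or CAA; only clean reads
#' enter per-site and multi-conversion metrics.
#'
#' @param seqs data.frame (`id`, `seq`) from [qc_filter()], or a character
#'   vector of merged sequences.
#' @param template a `locus_template`.
#' @param alleles alleles to assign against (defaults to the template's).
#' @return data.frame of read calls with list-columns `codons` and
#'   `conversion_sites`; attribute `n_failed` counts reads whose anchors
#'   could not be located.
#' @export
call_reads <- function(seqs, template, alleles = template$alleles) {
  if (is.character(seqs))
    seqs <- data.frame(id = paste0("read", seq_along(seqs)), seq = seqs,
                       stringsAsFactors = FALSE)
  stopifnot(length(alleles) >= 1L)
  ref_codons <- lapply(alleles, `[[`, "codons")
  names(ref_codons) <- vapply(alleles, `[[`, character(1), "name")
  n <- nrow(seqs)
  allele <- character(n); indel <- character(n); k <- integer(n)
  clean <- logical(n); nconv <- integer(n)
  codons <- vector("list", n); sites <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    dec <- decompose_repeat(seqs$seq[i], template)
    if (!dec$found) next
    ok[i] <- TRUE
    cl <- classify_indel(dec$nt_span, alleles)
    allele[i] <- cl$allele; indel[i] <- cl$indel; k[i] <- cl$k
    codons[[i]] <- dec$codons
    sites[[i]] <- integer(0)
    if (cl$indel == "none") {
      ref <- ref_codons[[cl$allele]]
      cag_pos <- cag_sites(ref)
      conv <- which(dec$codons[cag_pos] == "CAA")
      sites[[i]] <- conv                       # 1-based CAG indices
      nconv[i] <- length(conv)
      clean[i] <- all(dec$codons %in% c("CAG", "CAA"))
    }
  }
  out <- data.frame(id = seqs$id[ok], allele = allele[ok], indel = indel[ok],
                    indel_codons = k[ok], clean = clean[ok],
                    n_conversions = nconv[ok], stringsAsFactors = FALSE)
  out$codons <- codons[ok]
  out$conversion_sites <- sites[ok]
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' Presence-based conversion type counts
#'
#' For indel-free reads, counts the number of reads containing at least one
#' codon of each type, scanning the tract excluding the assigned allele's
#' terminal CAA-CAG interruption codons (two for canonical, four for
#' duplicated interruption).
#'
#' @param calls output of [call_reads()].
#' @param alleles the allele list used for calling (for interruption
#'   lengths).
#' @param types codon types to tally.
#' @param per_codon if TRUE, count codons instead of reads (off by
#'   default; the published tally is read-presence based).
#' @return named integer vector over `types`.
#' @export
conversion_type_counts <- function(calls, alleles, types = CONVERSION_TYPES,
                                   per_codon = FALSE) {
  nint <- vapply(alleles, function(a) n_interruption_codons(a$structure),
                 integer(1))
  names(nint) <- vapply(alleles, `[[`, character(1), "name")
  counts <- stats::setNames(integer(length(types)), types)
  idx <- which(calls$indel == "none")
  for (i in idx) {
    cod <- calls$codons[[i]]
    drop <- nint[[calls$allele[i]]]
    if (drop > 0L && length(cod) >= drop)
      cod <- cod[seq_len(length(cod) - drop)]
    if (per_codon) {
      tab <- table(factor(cod, levels = types))
      counts <- counts + as.integer(tab)
    } else {
      counts <- counts + as.integer(types %in% cod)
    }
  }
  counts
}

#' Per-site CAG-to-CAA conversion percentages
#'
#' Restricts the numerator to reads of the expected codon count containing
#' only CAG or CAA codons ("clean" reads) and reports, for each CAG site of
#' the reference allele, the percentage of reads with CAA at that site. Two
#' denominators are computed: `pct_all` uses all QC-passed reads assigned to
#' the allele (the headline convention: "x% of all sequence reads have CAA
#' at site k") and `pct_eligible` uses clean reads only. An empty-vector
#' baseline, when supplied, is subtracted from the chosen `pct` column with
#' negatives floored at 0; the raw value is kept in `pct_raw`.
#'
#' @param calls output of [call_reads()].
#' @param allele the `repeat_allele` to summarize.
#' @param ev_baseline optional numeric vector of per-site baseline
#'   percentages (recycled/length-matched to the number of CAG sites).
#' @param denominator `"all"` (default) or `"eligible"`.
#' @return data.frame with columns `site`, `pct_all`, `pct_eligible`,
#'   `pct_raw`, `pct`.
#' @export
per_site_conversion <- function(calls, allele, ev_baseline = NULL,
                                denominator = c("all", "eligible")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(allele, "repeat_allele"))
  sub <- calls[calls$allele == allele$name, , drop = FALSE]
  n_all <- nrow(sub)
  elig <- sub[sub$clean, , drop = FALSE]
  n_elig <- nrow(elig)
  if (n_elig == 0L)
    stop("no eligible (clean) reads for allele ", allele$name, call. = FALSE)
  n_sites <- length(cag_sites(allele$codons))
  hits <- integer(n_sites)
  for (s in unlist(elig$conversion_sites)) hits[s] <- hits[s] + 1L
  out <- data.frame(site = seq_len(n_sites),
                    pct_all = 100 * hits / n_all,
                    pct_eligible = 100 * hits / n_elig)
  out$pct_raw <- if (denominator == "all") out$pct_all else out$pct_eligible
  if (!is.null(ev_baseline)) {
    ev <- rep_len(ev_baseline, n_sites)
    out$pct <- pmax(out$pct_raw - ev, 0)
  } else {
    out$pct <- out$pct_raw
  }
  out
}

#' Duplicated-interruption read fractions
#'
#' `di_fraction` is the percentage of all QC-passed reads whose (in-frame)
#' repeat tract ends in CAA-CAG-CAA-CAG; `di_plus_other_fraction` adds the
#' requirement of at least one further CAA upstream of the doublets
#' (duplicated interruption co-occurring with conversion at another site).
#'
#' @param calls output of [call_reads()].
#' @return named numeric vector `c(di_fraction, di_plus_other_fraction)` in
#'   percent.
#' @export
duplicated_interruption_fractions <- function(calls) {
  n <- nrow(calls)
  if (n == 0L) return(c(di_fraction = 0, di_plus_other_fraction = 0))
  is_di <- vapply(calls$codons, function(cod) {
    !is.null(cod) && length(cod) >= 5L &&
      identical(cod[(length(cod) - 3L):length(cod)],
                c("CAA", "CAG", "CAA", "CAG"))
  }, logical(1))
  di_other <- vapply(seq_along(is_di), function(i) {
    if (!is_di[i]) return(FALSE)
    cod <- calls$codons[[i]]
    any(cod[seq_len(length(cod) - 4L)] == "CAA")
  }, logical(1))
  c(di_fraction = 100 * sum(is_di) / n,
    di_plus_other_fraction = 100 * sum(di_other) / n)
}

#' Multi-conversion histogram
#'
#' Over clean reads (indel-free, CAG/CAA-only), tabulates the number of
#' reads carrying exactly k CAG-to-CAA conversions, irrespective of
#' position; multiple conversions need not be consecutive.
#'
#' @param calls output of [call_reads()].
#' @return named integer vector; names are conversion counts 0..max.
#' @export
multiconversion_histogram <- function(calls) {
  k <- calls$n_conversions[calls$clean]
  if (length(k) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(factor(k, levels = 0:max(k)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Summarize conversion outcomes for one allele
#'
#' @param calls output of [call_reads()].
#' @param allele a `repeat_allele`.
#' @param alleles full allele list used for calling.
#' @return object of class `conversion_summary` with read counts, type
#'   counts, per-site percentages (no EV subtraction), DI fractions,
#'   multi-conversion histogram and indel percentages.
#' @export
conversion_summary <- function(calls, allele, alleles = list(allele)) {
  sub <- calls[calls$allele == allele$name, , drop = FALSE]
  n <- nrow(sub)
  pct <- function(x) if (n) 100 * x / n else 0
  structure(list(
    allele = allele$name,
    n_reads = n,
    type_counts = conversion_type_counts(sub, alleles),
    per_site = if (any(sub$clean)) per_site_conversion(sub, allele) else NULL,
    di = duplicated_interruption_fractions(sub),
    multiconv_hist = multiconversion_histogram(sub),
    indel_pct = pct(sum(sub$indel != "none")),
    inframe_ins_pct = pct(sum(sub$indel == "insertion")),
    inframe_del_pct = pct(sum(sub$indel == "deletion")),
    frameshift_pct = pct(sum(sub$indel == "frameshift"))
  ), class = "conversion_summary")
}

#' @export
print.conversion_summary <- function(x, ...) {
  cat(sprintf("<conversion_summary> allele %s: %d reads, %.1f%% indel (%.1f%% in-frame ins, %.1f%% in-frame del)\n",
              x$allele, x$n_reads, x$indel_pct, x$inframe_ins_pct,
              x$inframe_del_pct))
  cat(sprintf("  DI fraction %.2f%% (with other conversion %.2f%%)\n",
              x$di[["di_fraction"]], x$di[["di_plus_other_fraction"]]))
  if (!is.null(x$per_site)) {
    top <- x$per_site[order(-x$per_site$pct), ][1, ]
    cat(sprintf("  max per-site conversion: %.1f%% at CAG %d\n",
                top$pct, top$site))
  }
  invisible(x)
}

#' Write a conversion summary as JSON
#' @param summary a `conversion_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conversion_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Allele-specific conversion summary with replicate comparison
#'
#' Computes, per replicate and per allele, the conversion efficiency
#' (percent of allele-assigned clean reads converted at `site`, or at any
#' site when `site` is NULL, with all allele-assigned reads as denominator)
#' and the in-frame indel percentages, and compares the two alleles'
#' efficiencies across replicates with a Welch two-sample t-test.
#'
#' @param call_list list of [call_reads()] outputs, one per replicate.
#' @param alleles list of exactly two `repeat_allele`s.
#' @param site optional 1-based CAG index defining the target site.
#' @return list with `per_replicate` (data.frame: replicate, allele,
#'   efficiency, inframe_ins_pct, inframe_del_pct) and `test` (htest or NULL
#'   with a warning when fewer than 2 replicates).
#' @export
allele_specific_summary <- function(call_list, alleles, site = NULL) {
  stopifnot(length(alleles) == 2L)
  rows <- list()
  for (r in seq_along(call_list)) {
    calls <- call_list[[r]]
    for (a in alleles) {
      sub <- calls[calls$allele == a$name, , drop = FALSE]
      n <- nrow(sub)
      conv <- vapply(seq_len(n), function(i) {
        if (!sub$clean[i]) return(FALSE)
        s <- sub$conversion_sites[[i]]
        if (is.null(site)) length(s) > 0L else site %in% s
      }, logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, allele = a$name,
        efficiency = if (n) 100 * sum(conv) / n else NA_real_,
        inframe_ins_pct = if (n) 100 * sum(sub$indel == "insertion") / n else NA_real_,
        inframe_del_pct = if (n) 100 * sum(sub$indel == "deletion") / n else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  per_rep <- do.call(rbind, rows)
  test <- NULL
  if (length(call_list) < 2L) {
    warning("fewer than 2 replicates: allele comparison omitted")
  } else {
    x <- per_rep$efficiency[per_rep$allele == alleles[[1]]$name]
    y <- per_rep$efficiency[per_rep$allele == alleles[[2]]$name]
    test <- stats::t.test(x, y)                  # Welch by default
  }
  list(per_replicate = per_rep, test = test)
}
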