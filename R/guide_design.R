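#' Guide RNA spacer
#'
#' @param name guide label.
#' @param spacer 20-nt protospacer-matching DNA sequence (5' to 3'; the
#'   3'-most base is PAM-proximal).
#' @return an object of class `guide`.
#' @export
guide <- function(name, spacer) {
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L || !grepl("^[ACGT]{20}$", spacer))
    stop("spacer must be exactly 20 nt over A/C/G/T", call. = FALSE)
  structure(list(name = as.character(name), spacer = spacer),
            class = "guide")
}

#' Cytosine base-editor profile
#'
#' Bundles the Cas9 variant's PAM compatibility (ordered patterns with
#' IUPAC N; rank 1 = most favoured) with the deamination activity window,
#' expressed as spacer nucleotide positions counted from the PAM (position 1
#' is PAM-adjacent, position 20 PAM-distal).
#'
#' @param name editor label.
#' @param pam_patterns character vector of 3-nt PAM patterns in rank order.
#' @param window_from_pam integer positions (within 1..20) counted from the
#'   PAM where deamination is efficient.
#' @param note free-text note (e.g. sequence-context preference).
#' @return an object of class `editor_profile`.
#' @export
editor_profile <- function(name, pam_patterns, window_from_pam = 13:17,
                           note = "") {
  window_from_pam <- as.integer(window_from_pam)
  stopifnot(all(window_from_pam >= 1L & window_from_pam <= 20L),
            all(nchar(pam_patterns) == 3L))
  structure(list(name = name, pam_patterns = toupper(pam_patterns),
                 window_from_pam = window_from_pam, note = note),
            class = "editor_profile")
}

#' Built-in editor profiles
#'
#' `editor_be4max()` is NGG-restricted with the BE4 window (13th-17th
#' nucleotide from the PAM). `editor_be4_ng()` and `editor_be4_spg()` accept
#' NGN PAMs but still favour NGG (rank 1). `editor_evo_spg()` models the
#' evoCDA1 deaminase: relaxed PAM plus a widened window (11-19 by default;
#' the true bounds are not quantified, so the window stays configurable).
#'
#' @param window_from_pam activity window override.
#' @return an `editor_profile`.
#' @export
editor_be4max <- function(window_from_pam = 13:17) {
  editor_profile("BE4max", "NGG", window_from_pam)
}

#' @rdname editor_be4max
#' @export
editor_be4_ng <- function(window_from_pam = 13:17) {
  editor_profile("BE4-NG", c("NGG", "NGN"), window_from_pam)
}

#' @rdname editor_be4max
#' @export
editor_be4_spg <- function(window_from_pam = 13:17) {
  editor_profile("BE4-SpG", c("NGG", "NGN"), window_from_pam)
}

#' @rdname editor_be4max
#' @export
editor_evo_spg <- function(window_from_pam = 11:19) {
  editor_profile("evo-SpG", c("NGG", "NGN"), window_from_pam,
                 note = "wide window; efficient in GC context")
}

iupac_to_regex <- function(pat) {
  map <- c(A = "A", C = "C", G = "G", T = "T", N = "[ACGT]",
           R = "[AG]", Y = "[CT]", W = "[AT]", S = "[CG]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]")
  chars <- strsplit(pat, "")[[1]]
  paste0("^", paste(map[chars], collapse = ""), "$")
}

#' Rank a PAM against an editor profile
#'
#' @param pam 3-nt PAM string (read on the protospacer-containing strand,
#'   immediately 3' of the protospacer).
#' @param editor an `editor_profile`.
#' @return integer rank of the first matching PAM pattern (1 = most
#'   favoured) or `NA_integer_` when incompatible.
#' @export
pam_rank <- function(pam, editor) {
  pam <- toupper(pam)
  stopifnot(nchar(pam) == 3L)
  for (i in seq_along(editor$pam_patterns)) {
    if (grepl(iupac_to_regex(editor$pam_patterns[i]), pam)) return(i)
  }
  NA_integer_
}

hamming_positions <- function(a, b) {
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Enumerate hybridization registers of a spacer on a locus
#'
#' Slides the 20-nt spacer over both strands of `locus_seq` and reports
#' every placement with Hamming distance at most `max_mismatch` that leaves
#' room for a 3-nt PAM 3' of the protospacer. On a periodic CTG tract a
#' repeat-composed spacer therefore reports one register per in-frame shift.
#' The mismatch model is substitution-only (no bulges).
#'
#' @param guide a [guide()].
#' @param locus_seq sense-strand DNA string (>= 23 nt).
#' @param max_mismatch maximum Hamming mismatches allowed.
#' @return data.frame with columns `strand` ("sense"/"antisense"), `start`
#'   (0-based offset of the protospacer in that strand's 5'->3' sequence),
#'   `mismatches`, `mismatch_pos_from_pam` (comma-separated distances of
#'   mismatched spacer positions from the PAM; "" if none), `pam`.
#' @export
enumerate_registers <- function(guide, locus_seq, max_mismatch = 0L) {
  stopifnot(inherits(guide, "guide"))
  locus_seq <- toupper(locus_seq)
  if (nchar(locus_seq) < 23L)
    stop("locus sequence shorter than protospacer + PAM", call. = FALSE)
  scan_strand <- function(seq_s, strand) {
    L <- nchar(seq_s)
    starts <- 0:(L - 23L)
    protos <- substring(seq_s, starts + 1L, starts + 20L)
    pams <- substring(seq_s, starts + 21L, starts + 23L)
    spl <- strsplit(protos, "")
    spacer_ch <- strsplit(guide$spacer, "")[[1]]
    mm <- vapply(spl, function(p) sum(p != spacer_ch), integer(1))
    keep <- which(mm <= max_mismatch)
    if (!length(keep)) return(NULL)
    mmpos <- vapply(keep, function(i) {
      d <- 21L - which(spl[[i]] != spacer_ch)  # distance from PAM
      paste(sort(d), collapse = ",")
    }, character(1))
    data.frame(strand = strand, start = starts[keep],
               mismatches = mm[keep], mismatch_pos_from_pam = mmpos,
               pam = pams[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(scan_strand(locus_seq, "sense"),
               scan_strand(revcomp(locus_seq), "antisense"))
  if (is.null(out))
    out <- data.frame(strand = character(), start = integer(),
                      mismatches = integer(),
                      mismatch_pos_from_pam = character(),
                      pam = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Map the editing window of a register onto sense-strand CAG sites
#'
#' Cytosine editing of the antisense strand converts sense CAG to CAA: the
#' edited base is the antisense C that pairs with the third-position G of a
#' sense CAG codon. For an antisense register this returns the 1-based
#' sense-strand CAG indices whose paired antisense C lies at the editor's
#' window positions (13-17 nt from the PAM for BE4-class editors). A
#' sense-strand register cannot produce CAG-to-CAA and returns an empty set
#' with a warning.
#'
#' @param register one row of [enumerate_registers()] output (data.frame or
#'   list with `strand` and `start`).
#' @param editor an `editor_profile`.
#' @param template a `locus_template`.
#' @param allele the `repeat_allele` defining the repeat tract.
#' @return sorted integer vector of 1-based CAG indices (possibly empty).
#' @export
window_cag_sites <- function(register, editor, template, allele) {
  if (register$strand != "antisense") {
    warning("sense-strand register: no CAG-to-CAA chemistry; returning empty set")
    return(integer(0))
  }
  sense <- build_amplicon_reference(template, allele)
  anti <- revcomp(sense)
  L <- nchar(sense)
  f5 <- nchar(template$flank5)
  codons <- allele$codons
  # protospacer position i (1..20, 5'->3') lies 21-i nt from the PAM
  proto_i <- 21L - editor$window_from_pam
  proto_i <- proto_i[proto_i >= 1L & proto_i <= 20L]
  site_pos <- cag_sites(codons)                # codon positions of CAG sites
  sites <- integer(0)
  for (i in proto_i) {
    apos <- register$start + i
    if (apos < 1L || apos > L) next
    if (substr(anti, apos, apos) != "C") next
    spos <- L - apos + 1L                      # paired sense position
    rel <- spos - f5
    if (rel < 1L || rel > 3L * length(codons)) next
    if (rel %% 3L != 0L) next                  # must be a codon third base
    m <- rel %/% 3L
    if (!(m %in% site_pos)) next
    sites <- c(sites, match(m, site_pos))
  }
  sort(unique(sites))
}

#' Predict convertible CAG sites for a guide/editor combination
#'
#' Enumerates registers on the allele's amplicon, drops registers whose PAM
#' is incompatible with the editor, maps each remaining register's activity
#' window onto sense CAG indices, and ranks registers by (PAM rank,
#' mismatch count, PAM-distal mismatch preference). The ranking
#' operationalizes the observation that one PAM-distal mismatch is tolerated
#' in favour of a more robust PAM.
#'
#' @param guide a [guide()].
#' @param editor an `editor_profile`.
#' @param template a `locus_template`.
#' @param allele a `repeat_allele`.
#' @param max_mismatch maximum Hamming mismatches (default 1).
#' @return data.frame of ranked registers with columns of
#'   [enumerate_registers()] plus `pam_rank` and `sites` (comma-separated
#'   predicted 1-based CAG indices); zero rows when no compatible register
#'   exists.
#' @export
predict_edit_sites <- function(guide, editor, template, allele,
                               max_mismatch = 1L) {
  sense <- build_amplicon_reference(template, allele)
  reg <- enumerate_registers(guide, sense, max_mismatch)
  if (!nrow(reg)) return(cbind(reg, pam_rank = integer(0), sites = character(0)))
  reg$pam_rank <- vapply(reg$pam, pam_rank, integer(1), editor = editor)
  reg <- reg[!is.na(reg$pam_rank), , drop = FALSE]
  if (!nrow(reg)) { reg$sites <- character(0); return(reg) }
  reg$sites <- vapply(seq_len(nrow(reg)), function(i) {
    r <- reg[i, ]
    if (r$strand != "antisense") return("")
    paste(window_cag_sites(r, editor, template, allele), collapse = ",")
  }, character(1))
  # tie-break: prefer mismatches far from the PAM (larger minimum distance)
  min_dist <- vapply(reg$mismatch_pos_from_pam, function(s) {
    if (!nzchar(s)) Inf else min(as.numeric(strsplit(s, ",")[[1]]))
  }, numeric(1))
  ord <- order(reg$pam_rank, reg$mismatches, -min_dist)
  reg <- reg[ord, , drop = FALSE]
  rownames(reg) <- NULL
  reg
}
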