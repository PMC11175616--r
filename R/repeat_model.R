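VALID_CODON <- "^[ACGT]{3}$"

#' Repeat allele
#'
#' Represents an HTT-style glutamine-tract allele as an ordered list of
#' codons (the CAG tract plus any CAA interruptions, excluding the
#' downstream CCG-rich proline tract, which belongs to `flank3`). The
#' structure class (canonical / loss of interruption / duplicated
#' interruption / custom) is derived from the codon arrangement, never set
#' by hand.
#'
#' @param codons character vector of uppercase DNA trinucleotides, 5' to 3'
#'   on the sense strand.
#' @param name allele label used in read assignment and reports.
#' @return An object of class `repeat_allele` with elements `codons`,
#'   `structure`, `name`.
#' @seealso [canonical_allele()], [loi_allele()], [di_allele()],
#'   [classify_structure()]
#' @export
repeat_allele <- function(codons, name = "allele") {
  codons <- toupper(as.character(codons))
  if (length(codons) && !all(grepl(VALID_CODON, codons)))
    stop("codons must be length-3 strings over A/C/G/T", call. = FALSE)
  structure(
    list(codons = codons, structure = classify_structure(codons),
         name = as.character(name)),
    class = "repeat_allele"
  )
}

#' @export
print.repeat_allele <- function(x, ...) {
  cat(sprintf("<repeat_allele> %s: %d codons, %s, %d uninterrupted CAG, %d glutamines\n",
              x$name, length(x$codons), x$structure,
              uninterrupted_cag_length(x$codons), glutamine_length(x)))
  invisible(x)
}

#' Convenience constructors for the three human repeat structures
#'
#' `canonical_allele(n)` builds `(CAG)^n` followed by one CAA-CAG doublet,
#' `loi_allele(n)` a bare `(CAG)^n` (loss of interruption), and
#' `di_allele(n)` `(CAG)^n` followed by two CAA-CAG doublets (duplicated
#' interruption). `n` is the uninterrupted CAG length.
#'
#' @param n uninterrupted CAG repeat length (>= 1).
#' @param name allele label.
#' @return a `repeat_allele`.
#' @export
canonical_allele <- function(n, name = sprintf("canonical_%d", n)) {
  stopifnot(n >= 1)
  repeat_allele(c(rep("CAG", n), "CAA", "CAG"), name = name)
}

#' @rdname canonical_allele
#' @export
loi_allele <- function(n, name = sprintf("loi_%d", n)) {
  stopifnot(n >= 1)
  repeat_allele(rep("CAG", n), name = name)
}

#' @rdname canonical_allele
#' @export
di_allele <- function(n, name = sprintf("di_%d", n)) {
  stopifnot(n >= 1)
  repeat_allele(c(rep("CAG", n), "CAA", "CAG", "CAA", "CAG"), name = name)
}

as_codons <- function(x) {
  if (inherits(x, "repeat_allele")) x$codons else toupper(as.character(x))
}

#' Classify the interruption structure of a repeat tract
#'
#' A tract is CANONICAL when it is an uninterrupted CAG run followed by
#' exactly one CAA-CAG doublet, LOI (loss of interruption) when it is pure
#' CAG, DI (duplicated interruption) when the run is followed by exactly two
#' consecutive CAA-CAG doublets, and CUSTOM for any other arrangement
#' (e.g. an internal CAA).
#'
#' @param codons a codon character vector or a `repeat_allele`.
#' @return one of `"CANONICAL"`, `"LOI"`, `"DI"`, `"CUSTOM"`.
#' @export
classify_structure <- function(codons) {
  codons <- as_codons(codons)
  if (length(codons) == 0L) return("CUSTOM")
  if (!all(grepl(VALID_CODON, codons)))
    stop("invalid codon alphabet", call. = FALSE)
  non_cag <- which(codons != "CAG")
  if (length(non_cag) == 0L) return("LOI")
  run <- non_cag[1L] - 1L                      # leading uninterrupted CAG run
  if (run < 1L) return("CUSTOM")
  tail_codons <- codons[(run + 1L):length(codons)]
  if (identical(tail_codons, c("CAA", "CAG"))) return("CANONICAL")
  if (identical(tail_codons, c("CAA", "CAG", "CAA", "CAG"))) return("DI")
  "CUSTOM"
}

#' Glutamine tract length
#'
#' Number of glutamine-encoding codons (CAG or CAA) in the tract. For the
#' three named structures this reproduces the class arithmetic: canonical =
#' CAG + 2, LOI = CAG, DI = CAG + 4, where CAG is the uninterrupted repeat
#' length.
#'
#' @param allele a `repeat_allele` or codon vector.
#' @return integer glutamine count.
#' @export
glutamine_length <- function(allele) {
  codons <- as_codons(allele)
  sum(codons %in% c("CAG", "CAA"))
}

#' Uninterrupted CAG repeat length
#'
#' Length of the longest run of consecutive CAG codons; the quantity that
#' determines age-at-onset, as opposed to the encoded polyglutamine length.
#'
#' @param codons a codon vector or `repeat_allele`.
#' @return integer run length (0 for an empty tract).
#' @export
uninterrupted_cag_length <- function(codons) {
  codons <- as_codons(codons)
  if (length(codons) == 0L) return(0L)
  r <- rle(codons == "CAG")
  m <- r$lengths[r$values]
  if (length(m) == 0L) 0L else max(m)
}

#' Indexable CAG conversion sites of a repeat tract
#'
#' Positions (into the codon list) of the CAG codons a conversion site index
#' can address: every CAG codon except one immediately preceded by CAA,
#' which is the CAG of a CAA-CAG interruption doublet and not counted (a
#' canonical allele of 43 uninterrupted CAG has exactly 43 sites, the
#' "42nd CAG" convention).
#'
#' @param codons codon vector or `repeat_allele`.
#' @return integer codon positions, 5' to 3'.
#' @export
cag_sites <- function(codons) {
  codons <- as_codons(codons)
  idx <- which(codons == "CAG")
  prev <- c("", codons)[idx]          # codon 5' of each CAG ("" at the start)
  idx[prev != "CAA"]
}

#' Apply an in-silico CAG-to-CAA conversion
#'
#' Replaces the `site`-th CAG codon (1-based, counted 5' to 3' over CAG
#' codons only, skipping interruptions — the "42nd CAG" convention) with
#' CAA. Glutamine length and codon count are unchanged; the structure class
#' is re-derived.
#'
#' @param allele a `repeat_allele`.
#' @param site 1-based CAG index from the 5' end of the sense strand.
#' @return the edited `repeat_allele`.
#' @export
apply_conversion <- function(allele, site) {
  stopifnot(inherits(allele, "repeat_allele"))
  site <- as.integer(site)
  cag_idx <- cag_sites(allele$codons)
  if (length(site) != 1L || is.na(site) || site < 1L || site > length(cag_idx))
    stop(sprintf("site %s out of range: allele has %d CAG codons",
                 paste(site, collapse = ","), length(cag_idx)), call. = FALSE)
  codons <- allele$codons
  codons[cag_idx[site]] <- "CAA"
  repeat_allele(codons, name = sprintf("%s_c%d", allele$name, site))
}

#' Canonical-equivalent effective CAG length
#'
#' Uninterrupted CAG length plus the structure-class offset estimated from
#' patient onset data: loss-of-interruption carriers behave as if they had
#' extra CAGs (+3 by default) and duplicated-interruption carriers as if
#' they had one less (-1), canonical alleles carry no offset.
#'
#' @param allele a `repeat_allele`.
#' @param offsets named numeric vector mapping structure classes to signed
#'   CAG-equivalent offsets.
#' @return numeric effective CAG length.
#' @export
effective_cag <- function(allele, offsets = c(LOI = 3, DI = -1)) {
  stopifnot(inherits(allele, "repeat_allele"))
  cls <- allele$structure
  off <- if (cls %in% names(offsets)) {
    unname(offsets[[cls]])
  } else if (cls == "CANONICAL") {
    0
  } else {
    stop(sprintf("no offset supplied for structure class %s", cls),
         call. = FALSE)
  }
  uninterrupted_cag_length(allele$codons) + off
}

#' Locus template
#'
#' The amplicon context of the repeat: 5' flank (ending immediately before
#' the first repeat codon), 3' flank (beginning with the first CCG of the
#' proline-rich tract), the MiSeq primer pair, and the alleles expected in
#' the sample.
#'
#' @param flank5,flank3 DNA strings (sense strand).
#' @param primer_fwd forward primer; must match within the first bases of
#'   `flank5`.
#' @param primer_rev reverse primer; its reverse complement must occur in
#'   `flank3`.
#' @param alleles list of `repeat_allele` objects.
#' @return an object of class `locus_template`.
#' @export
locus_template <- function(flank5, flank3, primer_fwd, primer_rev,
                           alleles = list()) {
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  primer_fwd <- toupper(primer_fwd); primer_rev <- toupper(primer_rev)
  stopifnot(nzchar(flank5), nzchar(flank3))
  p <- regexpr(primer_fwd, flank5, fixed = TRUE)
  if (p == -1L || p > 5L)
    stop("primer_fwd must match near the start of flank5", call. = FALSE)
  if (!grepl(revcomp(primer_rev), flank3, fixed = TRUE))
    stop("reverse complement of primer_rev must occur in flank3",
         call. = FALSE)
  if (!all(vapply(alleles, inherits, logical(1), "repeat_allele")))
    stop("alleles must be repeat_allele objects", call. = FALSE)
  names(alleles) <- vapply(alleles, `[[`, character(1), "name")
  structure(list(flank5 = flank5, flank3 = flank3, primer_fwd = primer_fwd,
                 primer_rev = primer_rev, alleles = alleles),
            class = "locus_template")
}

#' @export
print.locus_template <- function(x, ...) {
  cat(sprintf("<locus_template> flank5 %dnt | repeat | flank3 %dnt; %d allele(s): %s\n",
              nchar(x$flank5), nchar(x$flank3), length(x$alleles),
              paste(names(x$alleles), collapse = ", ")))
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param s DNA string.
#' @return the reverse complement, uppercase.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Build the sense-strand amplicon reference for an allele
#'
#' @param template a `locus_template`.
#' @param allele a `repeat_allele`.
#' @return DNA string `flank5 + codons + flank3`.
#' @export
build_amplicon_reference <- function(template, allele) {
  stopifnot(inherits(template, "locus_template"),
            inherits(allele, "repeat_allele"))
  paste0(template$flank5, paste(allele$codons, collapse = ""),
         template$flank3)
}

#' Export amplicon references as FASTA
#'
#' @param template a `locus_template`.
#' @param path output FASTA file.
#' @param alleles alleles to export (defaults to the template's).
#' @return `path`, invisibly.
#' @export
write_amplicon_fasta <- function(template, path, alleles = template$alleles) {
  seqs <- vapply(alleles, function(a) build_amplicon_reference(template, a),
                 character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- vapply(alleles, `[[`, character(1), "name")
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' The HTT CAG-repeat locus template
#'
#' Flanks anchored on the published MiSeq/fragment-analysis primers: the 5'
#' flank ends at the base immediately preceding the first repeat CAG and the
#' 3' flank starts with the first CCG of the proline-rich tract and ends at
#' the reverse-primer binding site.
#'
#' @param alleles list of `repeat_allele`s carried by the sample; defaults
#'   to the HEK293 16/17-CAG canonical pair.
#' @return a `locus_template`.
#' @export
htt_template <- function(alleles = list(canonical_allele(16),
                                        canonical_allele(17))) {
  locus_template(
    flank5 = "ATGAAGGCCTTCGAGTCCCTCAAGTCCTTC",
    flank3 = "CCGCCACCGCCGCCGCCGCCGCCGCCTCCTCAGCTTCCTCAGCC",
    primer_fwd = "ATGAAGGCCTTCGAGTCCC",
    primer_rev = "GGCTGAGGAAGCTGAGGA",
    alleles = alleles
  )
}

#' Read a locus/guide/editor configuration from YAML
#'
#' The config carries `locus` (flanks + primers), `alleles` (name, cag,
#' structure in canonical/loi/di), and optional `guides` (name, spacer).
#'
#' @param path YAML file.
#' @return list with elements `template` (a `locus_template`) and `guides`
#'   (list of [guide()] objects, possibly empty).
#' @export
read_locus_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mk <- function(a) {
    switch(tolower(a$structure),
           canonical = canonical_allele(a$cag, name = a$name),
           loi = loi_allele(a$cag, name = a$name),
           di = di_allele(a$cag, name = a$name),
           stop("unknown allele structure in config: ", a$structure))
  }
  alleles <- lapply(cfg$alleles, mk)
  tpl <- locus_template(cfg$locus$flank5, cfg$locus$flank3,
                        cfg$locus$primer_fwd, cfg$locus$primer_rev, alleles)
  guides <- lapply(cfg$guides, function(g) guide(g$name, g$spacer))
  list(template = tpl, guides = guides)
}
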