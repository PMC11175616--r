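#' Evaluate code under a local, restorable RNG seed
#'
#' Every simulator routes its randomness through this helper so a single
#' integer seed fully determines its output while the caller's RNG state is
#' left untouched.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

OTHER_VARIANT_TYPES <- setdiff(CONVERSION_TYPES, c("CAG", "CAA"))

apply_base_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  L <- nchar(seq)
  n_err <- stats::rbinom(1L, L, rate)
  if (n_err == 0L) return(seq)
  pos <- sample.int(L, n_err)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

sim_quals <- function(L, mean, sd) {
  pmin(40L, pmax(2L, as.integer(round(stats::rnorm(L, mean, sd)))))
}

#' Simulate paired amplicon reads with configurable editing outcomes
#'
#' Draws `n_pairs` amplicons from the template's alleles, applies per-site
#' CAG-to-CAA conversions, optional non-CAA codon variants and whole-codon
#' indels (plus a frameshift class emulating the basal apparent-indel load
#' of repeat sequencing), then emits forward/reverse mates as exact reverse
#' complements with independent per-base substitution errors. Discordant
#' pairs receive extra reverse-mate-only substitutions. A truth table
#' records every read's allele, conversion sites, indel class and
#' discordance label.
#'
#' @param template a `locus_template` whose alleles are sampled.
#' @param n_pairs number of read pairs.
#' @param allele_mix named proportions over template allele names (default
#'   uniform); must sum to 1.
#' @param per_site_caa named numeric vector of conversion probabilities by
#'   1-based CAG site (applied to every allele), or a list keyed by allele
#'   name.
#' @param other_variant_rate per-codon probability of a non-CAA variant
#'   codon (drawn uniformly from the seven non-CAG/CAA types).
#' @param indel_rate per-read probability of an indel.
#' @param indel_type_weights weights over insertion / deletion / frameshift.
#' @param indel_codon_probs distribution of the indel size in codons.
#' @param base_error_rate per-base substitution error probability, applied
#'   independently to each mate.
#' @param discordant_pair_rate probability of injecting reverse-mate-only
#'   substitutions.
#' @param phred_mean,phred_sd per-base quality profile.
#' @param low_quality_rate probability that a pair is emitted with
#'   low-quality bases (mean Phred below the QC threshold).
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `pairs` (data.frame compatible with [qc_filter()]) and
#'   `truth` (data.frame: id, allele, conversion_sites, n_conversions,
#'   indel, indel_codons, discordant, low_quality).
#' @export
simulate_reads <- function(template, n_pairs, allele_mix = NULL,
                           per_site_caa = NULL, other_variant_rate = 0,
                           indel_rate = 0.10,
                           indel_type_weights = c(insertion = 0.45,
                                                  deletion = 0.45,
                                                  frameshift = 0.10),
                           indel_codon_probs = c(0.7, 0.2, 0.1),
                           base_error_rate = 0.001,
                           discordant_pair_rate = 0,
                           phred_mean = 35, phred_sd = 3,
                           low_quality_rate = 0, seed = 1L) {
  stopifnot(inherits(template, "locus_template"),
            length(template$alleles) >= 1L)
  probs <- c(per_site_caa, other_variant_rate, indel_rate, base_error_rate,
             discordant_pair_rate, low_quality_rate)
  if (is.list(per_site_caa)) probs <- c(unlist(per_site_caa),
                                        other_variant_rate, indel_rate,
                                        base_error_rate,
                                        discordant_pair_rate,
                                        low_quality_rate)
  if (any(probs < 0 | probs > 1))
    stop("all rates must be probabilities in [0, 1]", call. = FALSE)
  anames <- names(template$alleles)
  if (is.null(allele_mix))
    allele_mix <- stats::setNames(rep(1 / length(anames), length(anames)),
                                  anames)
  if (abs(sum(allele_mix) - 1) > 1e-8)
    stop("allele_mix proportions must sum to 1", call. = FALSE)
  site_probs <- function(allele_name) {
    if (is.null(per_site_caa)) return(numeric(0))
    p <- if (is.list(per_site_caa)) per_site_caa[[allele_name]] else per_site_caa
    if (is.null(p)) numeric(0) else p
  }
  with_seed(seed, {
    ids <- sprintf("sim%06d", seq_len(n_pairs))
    rows <- vector("list", n_pairs)
    truth <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      aname <- sample(anames, 1L, prob = allele_mix[anames])
      ref <- template$alleles[[aname]]
      codons <- ref$codons
      cag_pos <- cag_sites(ref$codons)
      sp <- site_probs(aname)
      conv <- integer(0)
      for (s in seq_along(sp)) {
        site <- if (!is.null(names(sp))) as.integer(names(sp)[s]) else s
        if (site <= length(cag_pos) && stats::runif(1) < sp[s]) {
          codons[cag_pos[site]] <- "CAA"
          conv <- c(conv, site)
        }
      }
      if (other_variant_rate > 0) {
        hit <- which(stats::runif(length(codons)) < other_variant_rate)
        for (p in hit) codons[p] <- sample(OTHER_VARIANT_TYPES, 1L)
      }
      indel <- "none"; k <- 0L; fs_cut <- FALSE
      if (stats::runif(1) < indel_rate) {
        indel <- sample(names(indel_type_weights), 1L,
                        prob = indel_type_weights)
        if (indel == "insertion") {
          k <- sample(seq_along(indel_codon_probs), 1L,
                      prob = indel_codon_probs)
          at <- sample(seq_along(codons), 1L)
          codons <- append(codons, rep("CAG", k), after = at)
        } else if (indel == "deletion") {
          k <- min(sample(seq_along(indel_codon_probs), 1L,
                          prob = indel_codon_probs), length(codons) - 1L)
          at <- sample(seq_len(length(codons) - k + 1L), 1L)
          codons <- codons[-(at:(at + k - 1L))]
        } else {
          fs_cut <- TRUE
        }
      }
      tract <- paste(codons, collapse = "")
      if (fs_cut) {
        cut <- sample.int(nchar(tract), 1L)
        tract <- paste0(substr(tract, 1L, cut - 1L),
                        substr(tract, cut + 1L, nchar(tract)))
      }
      amplicon <- paste0(template$flank5, tract, template$flank3)
      fwd <- apply_base_errors(amplicon, base_error_rate)
      rev <- apply_base_errors(revcomp(amplicon), base_error_rate)
      discordant <- stats::runif(1) < discordant_pair_rate
      if (discordant) {
        ch <- strsplit(rev, "")[[1]]
        pos <- sample.int(length(ch), 3L)
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               ch[p]), 1L)
        rev <- paste(ch, collapse = "")
      }
      low_q <- stats::runif(1) < low_quality_rate
      qmean <- if (low_q) 12 else phred_mean
      rows[[i]] <- list(id = ids[i], fwd = fwd, rev = rev,
                        fwd_qual = sim_quals(nchar(fwd), qmean, phred_sd),
                        rev_qual = sim_quals(nchar(rev), qmean, phred_sd))
      truth[[i]] <- data.frame(
        id = ids[i], allele = aname,
        conversion_sites = paste(conv, collapse = ","),
        n_conversions = length(conv), indel = indel, indel_codons = k,
        discordant = discordant, low_quality = low_q,
        stringsAsFactors = FALSE)
    }
    pairs <- data.frame(id = ids,
                        fwd = vapply(rows, `[[`, character(1), "fwd"),
                        rev = vapply(rows, `[[`, character(1), "rev"),
                        stringsAsFactors = FALSE)
    pairs$fwd_qual <- lapply(rows, `[[`, "fwd_qual")
    pairs$rev_qual <- lapply(rows, `[[`, "rev_qual")
    list(pairs = pairs, truth = do.call(rbind, truth))
  })
}

#' Write simulated pairs as R1/R2 FASTQ (Phred+33) plus a truth table
#'
#' @param sim output of [simulate_reads()].
#' @param r1,r2 FASTQ output paths.
#' @param truth_csv optional truth-table CSV path.
#' @return invisibly, `c(r1, r2)`.
#' @export
write_fastq_pairs <- function(sim, r1, r2, truth_csv = NULL) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(vapply(quals, function(v)
      intToUtf8(v + 33L), character(1)))
    Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                                qualities = q)
  }
  wr(sim$pairs$fwd, sim$pairs$fwd_qual, sim$pairs$id, r1)
  wr(sim$pairs$rev, sim$pairs$rev_qual, sim$pairs$id, r2)
  if (!is.null(truth_csv))
    utils::write.csv(sim$truth, truth_csv, row.names = FALSE)
  invisible(c(r1, r2))
}

#' Simulate an age-at-onset cohort with structure-class offsets
#'
#' Onset for each record is `expected_onset(model, cag + offset(class)) +
#' Normal(0, residual_sd)`: a loss-of-interruption carrier with true offset
#' +3 behaves like a canonical carrier with three more CAGs. Class sizes
#' default to the published cohort (n = 21 LOI, n = 69 DI) with a canonical
#' reference arm.
#'
#' @param model an `onset_model`.
#' @param n_per_class named counts per structure class.
#' @param cag_range integer CAG lengths sampled uniformly.
#' @param class_offsets true signed CAG-equivalent offsets.
#' @param residual_sd residual onset SD in years.
#' @param seed integer seed.
#' @return data.frame (`id`, `cag`, `structure`, `onset`) with the
#'   generating configuration in attribute `truth`.
#' @export
simulate_cohort <- function(model = onset_model(),
                            n_per_class = c(CANONICAL = 564, LOI = 21,
                                            DI = 69),
                            cag_range = 40:50,
                            class_offsets = c(CANONICAL = 0, LOI = 3,
                                              DI = -1),
                            residual_sd = 6, seed = 1L) {
  stopifnot(all(n_per_class >= 1L),
            all(names(n_per_class) %in% names(class_offsets)))
  # guard: every shifted CAG must stay in the model's support
  if (model$type == "table") {
    need <- as.character(outer(cag_range, class_offsets[names(n_per_class)],
                               `+`))
    if (!all(need %in% names(model$table)))
      stop("cag_range + offsets leaves the onset table's support",
           call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(names(n_per_class), function(cls) {
      n <- n_per_class[[cls]]
      cag <- sample(cag_range, n, replace = TRUE)
      onset <- expected_onset(model, cag + class_offsets[[cls]]) +
        stats::rnorm(n, 0, residual_sd)
      data.frame(id = paste0(tolower(cls), "_", seq_len(n)), cag = cag,
                 structure = cls, onset = onset, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(class_offsets = class_offsets,
                               residual_sd = residual_sd, model = model)
    out
  })
}

#' Simulate a fragment-analysis trace with a geometric expansion tail
#'
#' Builds a modal peak at `main_cag` plus expansion peaks at +1..+`max_delta`
#' repeat units whose heights decay geometrically:
#' `height(+d) = main_height * tail_frac * tail_decay^(d-1)`. `tail_frac =
#' 0` gives a single-peak (fully stabilized) trace. Optional sub-threshold
#' noise peaks are scattered left of the modal allele. The analytic
#' expansion index implied by the configuration (at the given threshold) is
#' recorded as truth.
#'
#' @param main_cag modal repeat length (repeat units).
#' @param tail_frac height of the +1 peak relative to the modal peak (>= 0;
#'   the mean-drift dial of the tail).
#' @param tail_decay geometric decay of successive expansion peaks (0, 1).
#' @param max_delta largest simulated expansion, repeat units.
#' @param n_noise_peaks number of sub-threshold contraction-side noise
#'   peaks.
#' @param noise_height_frac noise peak height ceiling, relative to modal
#'   (must stay below `threshold_frac`).
#' @param main_height modal peak height (fluorescence units).
#' @param threshold_frac threshold used for the analytic truth index.
#' @param sample_id sample label.
#' @param seed integer seed (noise peaks only).
#' @return list with `trace` (a `peak_trace`) and `truth` (list with
#'   `expansion_index`).
#' @export
simulate_trace <- function(main_cag, tail_frac = 0.3, tail_decay = 0.5,
                           max_delta = 10L, n_noise_peaks = 0L,
                           noise_height_frac = 0.05, main_height = 10000,
                           threshold_frac = 0.10, sample_id = "sim",
                           seed = 1L) {
  stopifnot(tail_frac >= 0, tail_decay > 0, tail_decay < 1,
            noise_height_frac < threshold_frac)
  pos <- main_cag; h <- main_height
  if (tail_frac > 0) {
    d <- seq_len(max_delta)
    hd <- main_height * tail_frac * tail_decay^(d - 1)
    pos <- c(pos, main_cag + d); h <- c(h, hd)
  }
  with_seed(seed, {
    if (n_noise_peaks > 0L) {
      npos <- main_cag - sample(1:15, n_noise_peaks)
      nh <- stats::runif(n_noise_peaks, 0, noise_height_frac * main_height)
      pos <- c(pos, npos); h <- c(h, nh)
    }
    trace <- peak_trace(pos, h, main_allele = main_cag,
                        sample_id = sample_id)
    # analytic truth at the stated threshold, evaluated on the same height
    # values placed in the trace (noise peaks sit below the threshold)
    if (tail_frac > 0) {
      hd <- main_height * tail_frac * tail_decay^(seq_len(max_delta) - 1)
      keep_d <- which(hd >= threshold_frac * main_height)
    } else {
      hd <- numeric(0); keep_d <- integer(0)
    }
    hk <- hd[keep_d]
    tot <- main_height + sum(hk)
    truth_idx <- sum(hk / tot * keep_d)
    list(trace = trace, truth = list(expansion_index = truth_idx))
  })
}

#' Simulate instability samples for the treatment regression
#'
#' Generates mouse-like covariates (tail CAG around 110, age in weeks, sex,
#' experimental batch) and draws each liver expansion index from a linear
#' model with a known treatment effect, so the regression estimator can be
#' tested against the generating coefficients. Group sizes default to the
#' published design (16 base-editor-treated vs 15 PBS).
#'
#' @param n_be,n_pbs group sizes.
#' @param treatment_effect true BE-vs-PBS effect on the index (repeat
#'   units).
#' @param beta_cag,beta_age true covariate slopes.
#' @param sex_effect,batch_effect true nuisance effects (male vs female,
#'   batch B vs A).
#' @param intercept model intercept.
#' @param noise_sd residual SD of the index.
#' @param seed integer seed.
#' @return data.frame of samples with covariates and `expansion_index`;
#'   generating coefficients in attribute `truth`.
#' @export
simulate_instability_samples <- function(n_be = 16L, n_pbs = 15L,
                                         treatment_effect = -0.5,
                                         beta_cag = 0.08, beta_age = 0.15,
                                         sex_effect = 0.2,
                                         batch_effect = 0.3,
                                         intercept = -6, noise_sd = 0.4,
                                         seed = 1L) {
  with_seed(seed, {
    n <- n_be + n_pbs
    treatment <- c(rep("BE", n_be), rep("PBS", n_pbs))
    tail_cag <- round(stats::rnorm(n, 110, 3))
    age <- sample(18:23, n, replace = TRUE)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    batch <- sample(c("A", "B"), n, replace = TRUE)
    idx <- intercept + treatment_effect * (treatment == "BE") +
      beta_cag * tail_cag + beta_age * age +
      sex_effect * (sex == "male") + batch_effect * (batch == "B") +
      stats::rnorm(n, 0, noise_sd)
    out <- data.frame(sample_id = sprintf("m%02d", seq_len(n)),
                      treatment = treatment, tail_cag = tail_cag,
                      age = age, sex = sex, batch = batch,
                      expansion_index = idx, stringsAsFactors = FALSE)
    attr(out, "truth") <- list(treatment_effect = treatment_effect,
                               beta_cag = beta_cag, beta_age = beta_age,
                               sex_effect = sex_effect,
                               batch_effect = batch_effect,
                               intercept = intercept, noise_sd = noise_sd)
    out
  })
}
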