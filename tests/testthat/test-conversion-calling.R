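test_that("repeat decomposition finds the tract in frame and fails off-locus", {
  tpl <- hek_template()
  al <- tpl$alleles[[1]]
  amp <- build_amplicon_reference(tpl, al)
  dec <- decompose_repeat(amp, tpl)
  expect_true(dec$found)
  expect_equal(length(dec$codons), 18L)
  expect_identical(dec$codons[17:18], c("CAA", "CAG"))

  ed <- apply_conversion(al, 2)
  dec2 <- decompose_repeat(build_amplicon_reference(tpl, ed), tpl)
  expect_identical(dec2$codons[2], "CAA")
  expect_identical(dec2$codons[-2], dec$codons[-2])

  expect_false(decompose_repeat(strrep("ACGT", 40), tpl)$found)

  # a 1-nt deletion inside the tract is an in-frame failure (frameshift)
  fs <- paste0(tpl$flank5, substr(strrep("CAG", 18), 1, 53), tpl$flank3)
  dfs <- decompose_repeat(fs, tpl)
  expect_true(dfs$found)
  expect_null(dfs$codons)
  expect_equal(dfs$nt_span %% 3L, 2L)
})

test_that("indel classification assigns nearest allele with ties to the shorter", {
  alleles <- list(canonical_allele(16), canonical_allele(17))
  expect_identical(classify_indel(19L * 3L, alleles),
                   list(allele = "canonical_17", indel = "none", k = 0L))
  a18 <- list(canonical_allele(16))   # 18 codons
  expect_identical(classify_indel(19L * 3L, a18)$indel, "insertion")
  expect_identical(classify_indel(19L * 3L, a18)$k, 1L)
  expect_identical(classify_indel(50L, a18)$indel, "frameshift")

  # nearest-length oracle over all read lengths 15..60 codons against the
  # 18-codon normal / 53-codon mutant pair; ties go to the shorter allele
  pair <- list(canonical_allele(16, name = "normal"),
               canonical_allele(51, name = "mutant"))
  for (len in 15:60) {
    got <- classify_indel(3L * len, pair)
    d16 <- abs(len - 18L); d51 <- abs(len - 53L)
    want <- if (d16 <= d51) "normal" else "mutant"
    expect_identical(got$allele, want)
    expect_equal(got$k, min(d16, d51))
  }
  expect_identical(classify_indel(52L * 3L, pair),
                   list(allele = "mutant", indel = "deletion", k = 1L))
})

test_that("conversion typing is presence-based and skips the interruption doublet", {
  tpl <- hek_template()
  al <- canonical_allele(16)
  ref <- build_amplicon_reference(tpl, al)
  mk <- function(codons) paste0(tpl$flank5, paste(codons, collapse = ""),
                                tpl$flank3)
  # 100 reference reads: only CAG is present (the terminal CAA-CAG is not
  # scanned, so reference reads contribute no CAA count)
  calls <- call_reads(rep(ref, 100), tpl, list(al))
  tc <- conversion_type_counts(calls, list(al))
  expect_equal(unname(tc["CAG"]), 100L)
  expect_equal(sum(tc[setdiff(names(tc), "CAG")]), 0L)

  # injected per-type reads are counted once per read regardless of codons
  codons <- al$codons
  one_caa <- codons; one_caa[3] <- "CAA"
  two_caa <- codons; two_caa[c(2, 5)] <- "CAA"
  one_ctg <- codons; one_ctg[4] <- "CTG"
  seqs <- c(rep(mk(one_caa), 10), rep(mk(two_caa), 4), rep(mk(one_ctg), 6),
            rep(ref, 80))
  calls <- call_reads(seqs, tpl, list(al))
  tc <- conversion_type_counts(calls, list(al))
  expect_equal(unname(tc["CAA"]), 14L)
  expect_equal(unname(tc["CTG"]), 6L)
  expect_equal(unname(tc["CAG"]), 100L)
  # per-codon mode counts codons, not reads
  tcc <- conversion_type_counts(calls, list(al), per_codon = TRUE)
  expect_equal(unname(tcc["CAA"]), 10L + 8L)
})

test_that("per-site percentages reproduce the worked 27.7% definition and EV flooring", {
  tpl <- hek_template()
  al <- canonical_allele(16)
  mk <- function(codons) paste0(tpl$flank5, paste(codons, collapse = ""),
                                tpl$flank3)
  conv2 <- al$codons; conv2[2] <- "CAA"
  seqs <- c(rep(mk(conv2), 277), rep(build_amplicon_reference(tpl, al), 723))
  calls <- call_reads(seqs, tpl, list(al))
  ps <- per_site_conversion(calls, al)
  expect_equal(ps$pct[ps$site == 2], 27.7)
  expect_equal(sum(ps$pct[ps$site != 2]), 0)

  expect_equal(per_site_conversion(calls, al,
                                   ev_baseline = rep(1.2, 16))$pct[2],
               27.7 - 1.2)
  floored <- per_site_conversion(calls, al, ev_baseline = rep(30, 16))
  expect_true(all(floored$pct == 0))
  expect_equal(floored$pct_raw[2], 27.7)

  none <- calls[0, ]
  expect_error(per_site_conversion(none, al), "eligible")
})

test_that("duplicated-interruption fractions use all reads as denominator", {
  tpl <- hek_template()
  al <- canonical_allele(16)
  mk <- function(codons) paste0(tpl$flank5, paste(codons, collapse = ""),
                                tpl$flank3)
  di_cod <- apply_conversion(al, 15)$codons      # ends CAA-CAG-CAA-CAG
  di_plus <- di_cod; di_plus[2] <- "CAA"
  seqs <- c(rep(mk(di_cod), 5), rep(mk(di_plus), 2),
            rep(build_amplicon_reference(tpl, al), 993))
  calls <- call_reads(seqs, tpl, list(al))
  fr <- duplicated_interruption_fractions(calls)
  expect_equal(unname(fr["di_fraction"]), 0.7)
  expect_equal(unname(fr["di_plus_other_fraction"]), 0.2)
  expect_gte(fr[["di_fraction"]], fr[["di_plus_other_fraction"]])

  expect_equal(unname(duplicated_interruption_fractions(calls[0, ])),
               c(0, 0))
})

test_that("multi-conversion histogram bins reads by conversion count", {
  tpl <- hek_template()
  al <- canonical_allele(16)
  mk <- function(sites) {
    codons <- al$codons; codons[sites] <- "CAA"
    paste0(tpl$flank5, paste(codons, collapse = ""), tpl$flank3)
  }
  seqs <- c(rep(mk(integer(0)), 50), rep(mk(2), 30), rep(mk(c(1, 3, 5)), 7))
  calls <- call_reads(seqs, tpl, list(al))
  h <- multiconversion_histogram(calls)
  expect_equal(unname(h[c("0", "1", "2", "3")]), c(50L, 30L, 0L, 7L))
  # codon-count identity: sum over sites equals sum k * hist(k)
  ps <- per_site_conversion(calls, al, denominator = "eligible")
  n_elig <- sum(calls$clean)
  expect_equal(sum(ps$pct_eligible / 100 * n_elig),
               sum(as.integer(names(h)) * h))
})

test_that("pipeline recovers injected conversion, DI and multi-conversion truth", {
  tpl <- hek51_template()
  p_inject <- c(`1` = 0.05, `2` = 0.25, `3` = 0.10, `16` = 0.02)
  sim <- simulate_reads(tpl, n_pairs = 4000, per_site_caa = p_inject,
                        indel_rate = 0.10, base_error_rate = 0.001,
                        discordant_pair_rate = 0.01, seed = 101)
  qc <- qc_filter(sim$pairs, default_qc(tpl))
  calls <- call_reads(qc$sequences, tpl)
  truth <- sim$truth[match(calls$id, sim$truth$id), ]
  expect_identical(calls$allele, truth$allele)  # unambiguous assignment

  for (al in tpl$alleles) {
    ps <- per_site_conversion(calls, al, denominator = "eligible")
    n_elig <- sum(calls$allele == al$name & calls$clean)
    for (s in names(p_inject)) {
      p <- p_inject[[s]]
      se <- sqrt(p * (1 - p) / n_elig)
      expect_lt(abs(ps$pct_eligible[as.integer(s)] / 100 - p), 3 * se)
    }
  }

  # conversion calls agree with truth labels on kept clean reads
  clean <- calls$clean
  got_sites <- vapply(calls$conversion_sites[clean], paste,
                      character(1), collapse = ",")
  expect_identical(got_sites, truth$conversion_sites[clean])

  # zero-rate control: no conversions, no variant types, flat histogram
  sim0 <- simulate_reads(tpl, n_pairs = 300, indel_rate = 0,
                         base_error_rate = 0, seed = 5)
  calls0 <- call_reads(qc_filter(sim0$pairs, default_qc(tpl))$sequences, tpl)
  tc0 <- conversion_type_counts(calls0, tpl$alleles)
  expect_equal(sum(tc0[setdiff(names(tc0), "CAG")]), 0L)
  expect_equal(names(multiconversion_histogram(calls0)), "0")
  ps0 <- per_site_conversion(calls0, tpl$alleles[[1]])
  expect_true(all(ps0$pct == 0))
})

test_that("allele-specific summary compares efficiencies across replicates", {
  tpl <- hek51_template()
  mkrep <- function(p_mut, p_norm, seed) {
    sim <- simulate_reads(tpl, n_pairs = 600,
                          per_site_caa = list(mutant_51 = c(`2` = p_mut),
                                              normal_17 = c(`2` = p_norm)),
                          indel_rate = 0.05, base_error_rate = 0,
                          seed = seed)
    call_reads(qc_filter(sim$pairs, default_qc(tpl))$sequences, tpl)
  }
  reps <- list(mkrep(0.10, 0.13, 21), mkrep(0.10, 0.13, 22),
               mkrep(0.10, 0.13, 23))
  res <- allele_specific_summary(reps, tpl$alleles, site = 2L)
  expect_equal(nrow(res$per_replicate), 6L)
  eff <- res$per_replicate
  m_norm <- mean(eff$efficiency[eff$allele == "normal_17"])
  m_mut <- mean(eff$efficiency[eff$allele == "mutant_51"])
  expect_gt(m_norm, m_mut)   # higher conversion on the non-expanded allele
  expect_s3_class(res$test, "htest")

  expect_warning(one <- allele_specific_summary(reps[1], tpl$alleles,
                                                site = 2L),
                 "replicates")
  expect_null(one$test)
})

test_that("allele comparison holds its nominal size under equal conversion", {
  # constructive null: both alleles converted at the same rate; the
  # replicate-level Welch comparison should reject at roughly the nominal
  # 5% level
  alleles <- list(canonical_allele(17, name = "normal_17"),
                  canonical_allele(51, name = "mutant_51"))
  fake_calls <- function(k_norm, k_mut, n) {
    mk <- function(name, k) {
      df <- data.frame(allele = name, clean = TRUE,
                       indel = "none", stringsAsFactors = FALSE)
      df <- df[rep(1L, n), ]
      df$conversion_sites <- c(rep(list(2L), k),
                               rep(list(integer(0)), n - k))
      df
    }
    rbind(mk("normal_17", k_norm), mk("mutant_51", k_mut))
  }
  set.seed(77)
  n <- 200L; p <- 0.10; nsim <- 300L
  rejected <- 0L
  for (i in seq_len(nsim)) {
    reps <- lapply(1:3, function(r)
      fake_calls(rbinom(1, n, p), rbinom(1, n, p), n))
    res <- allele_specific_summary(reps, alleles, site = 2L)
    if (res$test$p.value < 0.05) rejected <- rejected + 1L
  }
  rate <- rejected / nsim
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})
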