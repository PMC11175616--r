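test_that("register enumeration matches the brute-force scan exactly", {
  set.seed(23)
  for (i in 1:15) {
    L <- sample(30:120, 1)
    locus <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
    g <- guide("rand", paste(sample(c("A", "C", "G", "T"), 20,
                                    replace = TRUE), collapse = ""))
    for (mm in c(0L, 2L, 4L)) {
      got <- enumerate_registers(g, locus, mm)
      want <- brute_registers(g$spacer, locus, mm)
      expect_equal(got[c("strand", "start", "mismatches", "pam")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("a repeat-composed spacer registers at every in-frame shift of a CTG tract", {
  # sense (CAG)x30 tract -> antisense (CTG)x30; spacer = 6 CTG units + "CT"
  locus <- paste0("ATATATA", strrep("CAG", 30), "TATATAT")
  g <- guide("ctg", paste0(strrep("CTG", 6), "CT"))
  reg <- enumerate_registers(g, locus, 0L)
  anti <- reg[reg$strand == "antisense", ]
  want <- brute_registers(g$spacer, locus, 0L)
  expect_equal(nrow(anti), sum(want$strand == "antisense"))
  expect_true(nrow(anti) > 1)
  expect_true(all(diff(sort(anti$start)) == 3))  # one register per 3-nt shift
})

test_that("spacer with no acceptable match yields no registers", {
  g <- guide("none", strrep("AT", 10))
  reg <- enumerate_registers(g, strrep("CAG", 30), 0L)
  expect_equal(nrow(reg), 0L)
  expect_error(enumerate_registers(g, "CAGCAGCAG", 0L), "shorter")
})

test_that("the printed front-end gRNA 2 spacer has a perfect antisense register with 2 flank bases PAM-proximal", {
  tpl <- hek_template()
  sense <- build_amplicon_reference(tpl, tpl$alleles[[2]])
  reg <- enumerate_registers(guide_front2(), sense, 0L)
  expect_equal(nrow(reg), 1L)
  expect_identical(reg$strand, "antisense")
  expect_equal(reg$mismatches, 0L)
  expect_identical(reg$pam, "AGG")
  # the two PAM-proximal spacer bases (GA) come from the upstream flank:
  # the protospacer runs 2 nt past the antisense CTG tract
  anti <- revcomp(sense)
  run_end <- regexpr("GAAGGACTTG", anti, fixed = TRUE) - 1L
  expect_equal(reg$start + 20L, as.integer(run_end + 2L))
})

test_that("PAM ranking follows the editor's ordered pattern list", {
  be4 <- editor_be4max()
  expect_equal(pam_rank("AGG", be4), 1L)
  expect_true(is.na(pam_rank("AGC", be4)))
  spg <- editor_be4_spg()
  expect_equal(pam_rank("TGA", spg), 2L)   # NGN compatible, NGG favoured
  expect_equal(pam_rank("TGG", spg), 1L)
})

test_that("the BE4 window maps front-end registers onto CAG sites {1,2} and {4,5}", {
  tpl <- hek_template()
  be4 <- editor_be4max()
  for (al in tpl$alleles) {
    sense <- build_amplicon_reference(tpl, al)
    r1 <- enumerate_registers(guide_front1(), sense, 0L)
    r2 <- enumerate_registers(guide_front2(), sense, 0L)
    expect_equal(window_cag_sites(r1[1, ], be4, tpl, al), c(1L, 2L))
    expect_equal(window_cag_sites(r2[1, ], be4, tpl, al), c(4L, 5L))
  }
})

test_that("sense-strand registers return an empty site set with a warning", {
  tpl <- hek_template()
  al <- tpl$alleles[[1]]
  fake <- data.frame(strand = "sense", start = 5L)
  expect_warning(s <- window_cag_sites(fake, editor_be4max(), tpl, al),
                 "sense")
  expect_length(s, 0L)
})

test_that("a register entirely within flank sequence predicts no sites", {
  tpl <- hek_template()
  al <- tpl$alleles[[1]]
  sense <- build_amplicon_reference(tpl, al)
  anti <- revcomp(sense)
  # protospacer fully inside the antisense copy of flank3 (start 0)
  g <- guide("flank", substr(anti, 1, 20))
  reg <- enumerate_registers(g, sense, 0L)
  reg <- reg[reg$strand == "antisense" & reg$start == 0L, ]
  expect_equal(window_cag_sites(reg[1, ], editor_be4max(), tpl, al),
               integer(0))
})

test_that("window size is bounded and shifts by +1 CAG per 3-nt register shift", {
  tpl <- hek_template()
  al <- canonical_allele(30)
  be4 <- editor_be4max()
  wmax <- ceiling(length(be4$window_from_pam) / 3) + 1
  sense <- build_amplicon_reference(tpl, al)
  anti <- revcomp(sense)
  run_start <- regexpr(strrep("CTG", 5), anti, fixed = TRUE)
  base <- data.frame(strand = "antisense", start = as.integer(run_start) + 2L)
  s0 <- window_cag_sites(base, be4, tpl, al)
  expect_lte(length(s0), wmax)
  for (k in 1:4) {
    sk <- window_cag_sites(transform(base, start = start + 3L * k),
                           be4, tpl, al)
    expect_lte(length(sk), wmax)
    expect_equal(sk, s0 - k)  # register moves 3' on antisense = 5' on sense
  }
})

test_that("predict_edit_sites ranks by PAM, mismatches, and PAM-distal preference", {
  tpl <- hek_template()
  al <- tpl$alleles[[2]]
  be4 <- editor_be4max()

  top1 <- predict_edit_sites(guide_front1(), be4, tpl, al, max_mismatch = 0L)
  expect_identical(top1$sites[1], "1,2")
  top2 <- predict_edit_sites(guide_front2(), be4, tpl, al, max_mismatch = 0L)
  expect_identical(top2$sites[1], "4,5")

  # pure-CTG guide: its perfect registers all have CTG-phase (non-NGG) PAMs,
  # so an NGG-only editor makes no prediction at 0 mismatches
  none <- predict_edit_sites(guide_polyctg(), be4, tpl, al,
                             max_mismatch = 0L)
  expect_equal(nrow(none), 0L)

  # a one-PAM-distal-mismatch variant of the gRNA 2 spacer: the perfect
  # registers have incompatible PAMs, but the 1-mismatch junction register
  # keeps its NGG PAM and becomes the prediction
  g_mm <- guide("mm", paste0("A", substr(guide_front2()$spacer, 2, 20)))
  pred <- predict_edit_sites(g_mm, be4, tpl, al, max_mismatch = 1L)
  expect_gt(nrow(pred), 0L)
  expect_identical(pred$pam[1], "AGG")
  expect_equal(pred$mismatches[1], 1L)
  expect_identical(pred$sites[1], "4,5")

  # with an NGN editor, a rank-1-PAM register with one mismatch outranks a
  # rank-2-PAM register with none
  spg <- editor_be4_spg()
  pred2 <- predict_edit_sites(g_mm, spg, tpl, al, max_mismatch = 1L)
  expect_equal(pred2$pam_rank[1], 1L)
  expect_equal(pred2$mismatches[1], 1L)
  perfect_rows <- pred2[pred2$mismatches == 0L, ]
  expect_true(all(perfect_rows$pam_rank > 1L))
})
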