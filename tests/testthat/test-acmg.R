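test_that("evidence tokens parse to code, strength and points", {
  e <- parse_evidence(c("PVS1", "PVS1_strong", "PS4_moderate", "PM2", "PP1",
                        "PP1_strong"))
  expect_equal(e$strength, c("very_strong", "strong", "moderate", "moderate",
                             "supporting", "strong"))
  expect_equal(e$points, c(8, 4, 2, 2, 1, 4))
  expect_error(parse_evidence("BA1"), "unrecognised")
})

test_that("PVS1 follows the dosage-sensitivity ladder", {
  meta <- function(lof = FALSE, hi = "not_curated", oe = NA, ttn = FALSE) {
    gene_meta_table(gene = "G1", definitive_for = "HCM", lof_mechanism = lof,
                    haploinsufficiency_score = hi, lof_oe = oe, is_ttn = ttn)
  }
  expect_equal(assign_pvs1(meta(lof = TRUE), "frameshift_ptc"), "PVS1")
  expect_equal(assign_pvs1(meta(hi = "3"), "frameshift_ptc"), "PVS1")
  expect_equal(assign_pvs1(meta(hi = "2"), "frameshift_ptc"), "PVS1_strong")
  expect_equal(assign_pvs1(meta(ttn = TRUE), "frameshift_ptc"), "PVS1_strong")
  expect_equal(assign_pvs1(meta(hi = "1"), "frameshift_ptc"), "PVS1_moderate")
  expect_equal(assign_pvs1(meta(oe = 0.2), "frameshift_ptc"), "PVS1_supporting")
  expect_null(assign_pvs1(meta(oe = 0.5), "frameshift_ptc"))
  expect_null(assign_pvs1(meta(oe = 0.35), "frameshift_ptc")) # strict cut
  # non-LoF consequence earns nothing; predicted LoF substitutes
  expect_null(assign_pvs1(meta(lof = TRUE), "in_frame_change"))
  expect_equal(assign_pvs1(meta(lof = TRUE), "none", predicted_lof = TRUE),
               "PVS1")
})

test_that("PS4 and PP1 are step functions at the printed thresholds", {
  ps4 <- vapply(0:30, function(k) {
    x <- assign_ps4(k); if (is.null(x)) "none" else x
  }, "")
  expect_equal(unique(ps4[1:2]), "none")         # 0-1
  expect_equal(unique(ps4[3:6]), "PS4_supporting") # 2-5
  expect_equal(unique(ps4[7:15]), "PS4_moderate")  # 6-14
  expect_equal(unique(ps4[16:31]), "PS4")          # 15+
  expect_equal(length(rle(ps4)$values), 4)

  pp1 <- vapply(0:30, function(k) {
    x <- assign_pp1(k); if (is.null(x)) "none" else x
  }, "")
  expect_equal(unique(pp1[1:3]), "none")          # 0-2
  expect_equal(unique(pp1[4:5]), "PP1")           # 3-4
  expect_equal(unique(pp1[6:7]), "PP1_moderate")  # 5-6
  expect_equal(unique(pp1[8:31]), "PP1_strong")   # 7+
  expect_equal(length(rle(pp1)$values), 4)
})

test_that("functional evidence maps frame outcomes to PS3/PM4", {
  expect_equal(assign_functional("intron_retention", "frameshift_ptc"), "PS3")
  expect_equal(assign_functional("exon_skip", "in_frame_change"), "PM4")
  expect_null(assign_functional("no_change", "none"))
  expect_warning(got <- assign_functional("unreported_consequence", "none"),
                 "unreported")
  expect_null(got)
})

test_that("PM2 and PP3 honour rarity and RNA supersession", {
  expect_setequal(assign_pm2_pp3(TRUE, 0, 2), c("PM2", "PP3"))
  expect_setequal(assign_pm2_pp3(TRUE, NA, 2), c("PM2", "PP3"))
  # RNA evidence withholds PP3
  expect_equal(assign_pm2_pp3(TRUE, 0, 2, has_rna_evidence = TRUE), "PM2")
  # common variant gets neither PM2 nor (without tools) PP3
  expect_length(assign_pm2_pp3(FALSE, 200, 0), 0)
  # rare but repeatedly seen in controls: no PM2
  expect_equal(assign_pm2_pp3(TRUE, 12, 1), "PP3")
})

test_that("the point combiner bands points into classes", {
  expect_equal(combine_acmg(c("PS3", "PM2"))$cls, "likely_pathogenic")
  expect_equal(combine_acmg(c("PS3", "PM2"))$points, 6)
  expect_equal(combine_acmg(c("PM2", "PM4", "PS4_supporting"))$cls, "VUS")
  expect_equal(combine_acmg(c("PS4", "PM2", "PM4"))$cls, "likely_pathogenic")
  expect_equal(combine_acmg(character(0))$cls, "VUS")
  expect_equal(combine_acmg(c("PVS1", "PM2"))$cls, "pathogenic")
})

test_that("the categorical combiner reproduces the classical rule set", {
  expect_equal(combine_acmg(c("PVS1", "PS3"), "categorical")$cls, "pathogenic")
  expect_equal(combine_acmg(c("PVS1", "PM2"), "categorical")$cls,
               "likely_pathogenic")
  expect_equal(combine_acmg(c("PS3", "PM2", "PM4"), "categorical")$cls,
               "likely_pathogenic")
  expect_equal(combine_acmg(c("PM2", "PP3"), "categorical")$cls, "VUS")
  expect_equal(combine_acmg(c("PS3", "PS4"), "categorical")$cls, "pathogenic")
})

test_that("adding evidence never lowers the class", {
  set.seed(41)
  pool <- c("PVS1", "PVS1_strong", "PS3", "PS4", "PS4_moderate",
            "PS4_supporting", "PM2", "PM4", "PP1", "PP1_moderate",
            "PP1_strong", "PP3")
  rank <- c(VUS = 1, likely_pathogenic = 2, pathogenic = 3)
  for (i in 1:60) {
    base <- sample(pool, sample(0:4, 1))
    extra <- sample(setdiff(pool, base), 1)
    for (comb in c("points", "categorical")) {
      c0 <- combine_acmg(base, comb)$cls
      c1 <- combine_acmg(unique(c(base, extra)), comb)$cls
      expect_gte(rank[[c1]], rank[[c0]])
    }
  }
})

test_that("RNA reclassification drops PP3, adds the functional code, labels the move", {
  # PTC outcome upgrades a PM2+PP3 VUS to LP via PS3
  r <- reclassify_with_rna(c("PM2", "PP3"), "exon_extension", "frameshift_ptc")
  expect_equal(r$before$cls, "VUS")
  expect_equal(r$after$cls, "likely_pathogenic")
  expect_setequal(r$tokens_after, c("PM2", "PS3"))
  expect_equal(r$transition, "upgrade")

  # in-frame skip on an already-LP variant: no change
  r <- reclassify_with_rna(c("PP1_strong", "PM2", "PS4_supporting"),
                           "exon_skip", "in_frame_change")
  expect_equal(r$after$cls, "likely_pathogenic")
  expect_equal(r$transition, "no_change")
  expect_true("PM4" %in% r$tokens_after)

  # a no-change outcome strips PP3 and leaves a VUS a VUS
  r <- reclassify_with_rna(c("PM2", "PP3"), "no_change", "none")
  expect_equal(r$tokens_after, "PM2")
  expect_equal(r$transition, "no_change")
})

test_that("classify_variants assigns and combines evidence over a cohort", {
  meta <- mini_gene_meta()
  obs <- dplyr::bind_rows(
    # essential donor GT in a LoF-mechanism gene, absent from controls:
    # PVS1 + PM2 + PP3 -> pathogenic
    make_obs(participant_id = "H1", hgvs_c = "c.927+1G>A", mes_ref = 9,
             mes_alt = 1, mes_delta = -8, spliceai = 0.9, proband_count = 1),
    # +5 donor variant with RNA-confirmed PTC skip: VUS -> LP
    make_obs(participant_id = "L1", disease = "LQTS", gene = "KCNQ1",
             transcript = "NM_000218.3", hgvs_c = "c.477+5G>A",
             mes_delta = -5.37, ada = 0.99, rf = 0.97, spliceai = 0.23,
             functional_kind = "exon_skip", functional_length_nt = 91,
             proband_count = 1)
  )
  v <- prioritise(obs, meta)
  cls <- classify_variants(v, meta)
  expect_equal(nrow(cls), 2)
  h1 <- cls[cls$gene == "MYBPC3", ]
  expect_equal(h1$cls, "pathogenic")
  expect_true(grepl("PVS1", h1$evidence))
  l1 <- cls[cls$gene == "KCNQ1", ]
  expect_equal(l1$cls, "VUS")
  expect_equal(l1$cls_after, "likely_pathogenic")
  expect_equal(l1$transition, "upgrade")
  expect_false(grepl("PP3", l1$evidence_after))
})
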