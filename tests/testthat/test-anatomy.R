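test_that("HGVS c. parsing extracts coding position, intronic offset and edit", {
  p <- parse_hgvs_offset(c("c.477+5G>A", "c.1224-80G>A", "c.100G>A"))
  expect_equal(p$coding_pos, c(477L, 1224L, 100L))
  expect_equal(p$intron_offset, c(5L, -80L, 0L))
  expect_equal(p$edit, c("G>A", "G>A", "G>A"))
  expect_true(all(p$parseable))

  # free-text spacing as transcribed from reports
  p2 <- parse_hgvs_offset("c.477+5 G > A")
  expect_equal(p2$intron_offset, 5L)

  # unparseable strings are flagged, never silently dropped
  bad <- parse_hgvs_offset(c("p.Glu849Gly", "c.?", NA))
  expect_equal(nrow(bad), 3)
  expect_false(any(bad$parseable))
})

test_that("ranged deletions are summarised at the most splice-proximal nucleotide", {
  # fully intronic del reaching towards the donor site
  p <- parse_hgvs_offset("c.477+1_477+4del")
  expect_equal(p$intron_offset, 1L)
  # del spanning the junction keeps the exonic edge
  p <- parse_hgvs_offset("c.475_477+2del")
  expect_equal(p$intron_offset, 0L)
  # exonic del
  p <- parse_hgvs_offset("c.100_102del")
  expect_equal(p$intron_offset, 0L)
  expect_equal(p$coding_pos, 100L)
  # dup with sequence
  p <- parse_hgvs_offset("c.1458-7dupC")
  expect_equal(p$intron_offset, -7L)
})

test_that("region classification follows the donor/acceptor windows", {
  cls <- classify_region(c(1L, -7L, -80L, 5L, -20L, -21L, 7L, 6L, -1L, -2L, 2L))
  expect_equal(cls$region,
               c("donor_site", "acceptor_site", "deep_intronic", "donor_site",
                 "acceptor_site", "deep_intronic", "deep_intronic",
                 "donor_site", "acceptor_site", "acceptor_site", "donor_site"))
  expect_equal(cls$essential_dinucleotide,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, TRUE, TRUE))

  # exonic variants classify by distance to the nearest exon boundary
  edge <- classify_region(rep(0L, 5),
                          exon_boundary_distance = c(-1L, -3L, 1L, 3L, NA))
  expect_equal(edge$region, c("donor_site", "donor_site", "acceptor_site",
                              "acceptor_site", "exonic_other"))
  expect_equal(edge$exon_edge, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_false(any(edge$essential_dinucleotide))
})

test_that("region classification partitions every parsed offset", {
  offsets <- c(-300:-1, 1:300)
  cls <- classify_region(offsets)
  expect_false(any(is.na(cls$region)))
  expect_true(all(cls$region %in% c("donor_site", "acceptor_site",
                                    "deep_intronic")))
  # each offset lands in exactly one region; window boundaries are exact
  expect_equal(sum(cls$region == "donor_site"), 6)
  expect_equal(sum(cls$region == "acceptor_site"), 20)
  exonic <- classify_region(rep(0L, 61), exon_boundary_distance = c(-30:30))
  expect_false(any(is.na(exonic$region)))
})

test_that("mechanism inference separates site loss from gain", {
  expect_equal(infer_mechanism("donor_site"), "site_loss")
  expect_equal(infer_mechanism("acceptor_site", mes_alt = 9), "site_loss")
  # deep intronic with a qualifying created-site score
  expect_equal(infer_mechanism("deep_intronic", mes_alt = 7.96), "site_gain")
  expect_equal(infer_mechanism("exonic_other", spliceai = 0.94), "site_gain")
  # no qualifying gain signal
  expect_equal(infer_mechanism("exonic_other", mes_alt = 3, spliceai = 0.2),
               "ambiguous")
  expect_equal(infer_mechanism("deep_intronic"), "ambiguous")
})

test_that("frame arithmetic matches the studied splicing outcomes", {
  # 91 bp exon skip -> frameshift + PTC
  expect_equal(frame_consequence("exon_skip", 91)$frame, "frameshift_ptc")
  # 75 bp exon skip -> in-frame deletion of 25 amino acids
  f75 <- frame_consequence("exon_skip", 75)
  expect_equal(f75$frame, "in_frame_change")
  expect_equal(f75$aa_change, 25)
  # 78 bp inclusion -> in-frame insertion of 26 amino acids
  f78 <- frame_consequence("new_exon_inclusion", 78)
  expect_equal(f78$frame, "in_frame_change")
  expect_equal(f78$aa_change, 26)
  # 5 bp extension -> premature stop
  expect_equal(frame_consequence("exon_extension", 5)$frame, "frameshift_ptc")
  # intron retention is PTC even in frame, unless asserted stop-free
  expect_equal(frame_consequence("intron_retention", 90)$frame, "frameshift_ptc")
  expect_equal(frame_consequence("intron_retention", 90,
                                 assume_stop_free = TRUE)$frame,
               "in_frame_change")
  expect_equal(frame_consequence("exon_skip", 0)$frame, "none")
  expect_equal(frame_consequence("no_change")$frame, "none")
  expect_error(frame_consequence("exon_skip", NA), "affected_length_nt")
})

test_that("frame consequence alternates with period 3", {
  for (k in 1:30) {
    f1 <- frame_consequence("exon_skip", k)$frame
    f2 <- frame_consequence("exon_skip", k + 3)$frame
    expect_equal(f1, f2)
  }
})

test_that("the six studied variants map to their splice regions", {
  t1 <- table1_scores()
  df <- variant_table(
    participant_id = t1$fam,
    disease = c("LQTS", "LQTS", "HCM", "HCM", "CPVT", "SUD"),
    gene = t1$gene, transcript = t1$transcript, hgvs_c = t1$hgvs_c,
    # c.781 G>A at the first nucleotide of exon 6; c.63793 G>A at the last
    # nucleotide of exon 307
    exon_boundary_distance = c(NA, 1, NA, NA, NA, -1),
    mes_ref = t1$mes_ref, mes_alt = t1$mes_alt, mes_delta = t1$mes_delta,
    ada = t1$ada, rf = t1$rf, spliceai = t1$spliceai
  )
  ann <- annotate_anatomy(df)
  expect_equal(
    ann$region,
    c("donor_site",     # KCNQ1 c.477+5
      "acceptor_site",  # KCNQ1 c.781 first exon nucleotide
      "deep_intronic",  # MYBPC3 c.1224-80
      "acceptor_site",  # MYBPC3 c.1458-7
      "donor_site",     # RYR2 c.848+1
      "donor_site")     # TTN c.63793 last exon nucleotide
  )
  expect_equal(ann$exon_edge, c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(ann$essential_dinucleotide,
               c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(ann$mechanism[3], "site_gain")
  expect_equal(ann$mechanism[5], "site_loss")
})
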