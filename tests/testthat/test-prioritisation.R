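test_that("rarity filter applies overall, sub-population and allele-count rules", {
  expect_true(frequency_filter(0, 0, list(af_amr = 0)))
  # one sub-population above threshold fails the variant
  expect_false(frequency_filter(5e-5, af_subpops = list(af_amr = 2e-4)))
  # allele count boundary: <=15 passes, 16 fails
  expect_true(frequency_filter(5e-5, allele_count_controls = 15))
  expect_false(frequency_filter(5e-5, allele_count_controls = 16))
  # boundary AF is a strict inequality
  expect_false(frequency_filter(1e-4))
  # missing frequency = absent from controls = pass
  expect_true(frequency_filter(NA_real_))
  expect_error(frequency_filter(-0.1), "negative")
})

test_that("region filter mirrors exome target regions in burden mode", {
  expect_true(region_filter(-52, "burden_75bp"))
  expect_true(region_filter(75, "burden_75bp"))
  expect_false(region_filter(-80, "burden_75bp"))
  expect_false(region_filter(76, "burden_75bp"))
  expect_true(region_filter(-80, "discovery"))
  expect_true(region_filter(0, "burden_75bp"))
  expect_true(region_filter(0, "discovery"))
})

test_that("tool calls reproduce the printed score rows under the thresholds", {
  t1 <- table1_scores()
  got <- tool_calls(t1$mes_ref, t1$mes_alt, t1$mes_delta, t1$ada, t1$rf,
                    t1$spliceai, t1$mechanism)
  for (i in seq_len(nrow(t1))) {
    expect_setequal(got[[i]], t1$expected_tools[[i]])
  }
  # all scores missing flags nothing
  expect_length(tool_calls(mechanism = "site_loss")[[1]], 0)
  # boundary values fail the strict thresholds
  expect_length(tool_calls(mes_delta = -4, ada = 0.6, rf = 0.6, spliceai = 0.5,
                           mechanism = "site_loss")[[1]], 0)
  # gain with no reference site: increase reduces to the created-site score
  expect_equal(tool_calls(mes_alt = 4.5, mechanism = "site_gain")[[1]], "MES")
  expect_length(tool_calls(mes_alt = 4.5, mes_ref = 1,
                           mechanism = "site_gain")[[1]], 0)
})

test_that("prioritisation gates on phenotype, rarity, region, exclusion and tools", {
  meta <- mini_gene_meta()

  # the excluded Oceanian TNNT2 acceptor variant
  excl <- make_obs(gene = "TNNT2", transcript = "NM_001276345.2",
                   hgvs_c = "c.601-1G>A", spliceai = 0.95)
  v <- prioritise(excl, meta)
  expect_false(v$candidate)
  expect_equal(v$failed_filters[[1]], "exclusion_list")

  # phenotype concordance: MYBPC3 is not a BrS gene
  disc <- make_obs(disease = "BrS")
  v <- prioritise(disc, meta)
  expect_false(v$candidate)
  expect_true("phenotype" %in% v$failed_filters[[1]])

  # SUD participants are screened against every panel gene
  sud <- make_obs(disease = "SUD")
  expect_true(prioritise(sud, meta)$candidate)

  # a clean candidate flagged by SpliceAI alone
  ok <- prioritise(make_obs(spliceai = 0.9), meta)
  expect_true(ok$candidate)
  expect_equal(ok$tools_flagging[[1]], "SpliceAI")
  expect_length(ok$failed_filters[[1]], 0)

  # common variant fails frequency; deep intronic fails burden-mode region
  common <- make_obs(af_overall = 0.01, allele_count_controls = NA_real_)
  expect_true("frequency" %in% prioritise(common, meta)$failed_filters[[1]])
  deep <- make_obs(hgvs_c = "c.1224-80G>A", mes_alt = 7.96, spliceai = 0.94)
  expect_true(prioritise(deep, meta, mode = "discovery")$candidate)
  expect_false(prioritise(deep, meta, mode = "burden_75bp")$candidate)

  expect_error(prioritise(make_obs(gene = "NOTAGENE"), meta), "NOTAGENE")
})

test_that("raising any tool threshold never grows the candidate set", {
  sim <- simulate_cohort(sim_config(seed = 5))
  base <- prioritise(sim$variants, sim$gene_meta)
  for (tweak in list(list(ada = 0.9), list(rf = 0.9), list(spliceai = 0.8),
                     list(mes_loss_delta = 6, mes_gain_min = 6,
                          mes_gain_delta = 6))) {
    th <- do.call(default_thresholds, tweak)
    strict <- prioritise(sim$variants, sim$gene_meta, thresholds = th)
    expect_true(all(base$candidate | !strict$candidate))
  }
})

test_that("unique-variant tallies never exceed carrier tallies", {
  cfg <- sim_config(seed = 9, recurrence = 0.5)
  sim <- simulate_cohort(cfg)
  v <- prioritise(sim$variants, sim$gene_meta)
  uv <- unique_variants(v)
  expect_lte(nrow(uv), nrow(v))
  per_gene <- dplyr::count(uv, gene)
  per_gene_carriers <- dplyr::count(v, gene)
  merged <- dplyr::left_join(per_gene, per_gene_carriers, by = "gene")
  expect_true(all(merged$n.x <= merged$n.y))
  # recurrence produced at least one shared variant
  expect_true(any(uv$n_carriers > 1))
})

test_that("concordance tally splits canonical and non-canonical variants", {
  t1 <- table1_scores()
  df <- variant_table(
    participant_id = t1$fam,
    disease = c("LQTS", "LQTS", "HCM", "HCM", "CPVT", "SUD"),
    gene = t1$gene, transcript = t1$transcript, hgvs_c = t1$hgvs_c,
    exon_boundary_distance = c(NA, 1, NA, NA, NA, -1),
    af_overall = 0, allele_count_controls = 0,
    mes_ref = t1$mes_ref, mes_alt = t1$mes_alt, mes_delta = t1$mes_delta,
    ada = t1$ada, rf = t1$rf, spliceai = t1$spliceai
  )
  meta <- mini_gene_meta()
  v <- prioritise(df, meta)
  expect_true(all(v$candidate))
  tall <- concordance_tally(v)
  # five canonical-site variants: two flagged by 4 tools, two by 3, one by
  # 2; one deep intronic variant flagged by MES and SpliceAI
  expect_equal(tall$canonical$n_variants, c(0L, 1L, 2L, 2L))
  expect_equal(tall$non_canonical$n_variants[tall$non_canonical$pattern == "both"], 1L)

  # single variant flagged by all four
  one <- prioritise(make_obs(hgvs_c = "c.10+1G>A", mes_ref = 9, mes_alt = 1,
                             mes_delta = -8, ada = 0.9, rf = 0.9,
                             spliceai = 0.9), meta)
  h <- concordance_tally(one)
  expect_equal(h$canonical$n_variants, c(0L, 0L, 0L, 1L))

  # empty input -> all-zero histograms
  empty <- concordance_tally(v[0, ])
  expect_true(all(empty$canonical$n_variants == 0))
  expect_true(all(empty$non_canonical$n_variants == 0))
})
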