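test_that("the synthetic catalog is valid and its columns are distinguishable", {
  cat0 <- synthetic_signature_catalog()
  expect_s3_class(cat0, "signature_catalog")
  expect_equal(colSums(cat0$probs), setNames(rep(1, 3), cat0$names),
               tolerance = 1e-9)
  expect_true(all(cat0$probs >= 0))
  ## pairwise cosines low enough for refitting to separate them
  cs <- combn(3, 2, function(ij) {
    cosine_similarity(cat0$probs[, ij[1]], cat0$probs[, ij[2]])
  })
  expect_true(all(cs < 0.5))
})

test_that("signature sampling is deterministic, channel-consistent and n-exact", {
  cat0 <- synthetic_signature_catalog()
  d1 <- sample_mutations_from_signatures(cat0, c(0.7, 0.2, 0.1), 500,
                                         "S1", seed = 11)
  d2 <- sample_mutations_from_signatures(cat0, c(0.7, 0.2, 0.1), 500,
                                         "S1", seed = 11)
  expect_identical(d1$counts, d2$counts)
  expect_identical(as.data.frame(d1$records), as.data.frame(d2$records))
  expect_equal(sum(d1$counts), 500L)
  expect_equal(nrow(d1$records), 500L)
  ## records materialize their channel: context middle base equals ref and
  ## the per-channel tallies match the true draw
  recs <- as_cohort(d1$records, sample_sheet("S1", "CASE"))
  expect_true(all(substr(recs$tri_context, 2, 2) == recs$ref))
  mat <- as_sbs96_matrix(build_sbs96_matrix(recs))
  expect_equal(as.integer(mat["S1", ]), as.integer(d1$counts))
  ## n = 0 gives an empty record set
  empty <- sample_mutations_from_signatures(cat0, c(1, 0, 0), 0, "S1")
  expect_equal(nrow(empty$records), 0L)
  ## a degenerate one-channel distribution puts everything in that channel
  deg <- matrix(0, 96, 1, dimnames = list(sbs96_channels(), "DEG"))
  deg["A[C>A]A", 1] <- 1
  dd <- sample_mutations_from_signatures(signature_catalog(deg), 1, 50, "S1",
                                         seed = 3)
  expect_equal(unname(dd$counts["A[C>A]A"]), 50L)
})

test_that("sampled channel frequencies converge to the mixture distribution", {
  cat0 <- synthetic_signature_catalog()
  mix <- c(0.84, 0.10, 0.06)
  p <- as.numeric(cat0$probs %*% mix)
  tv <- vapply(1:5, function(s) {
    d <- sample_mutations_from_signatures(cat0, mix, 5000, "S1", seed = s)
    0.5 * sum(abs(d$counts / sum(d$counts) - p))
  }, numeric(1))
  expect_lt(mean(tv), 0.05)
})

test_that("refitting closes the loop on sampled mixtures", {
  cat0 <- synthetic_signature_catalog()
  for (seed in 1:10) {
    two <- signature_catalog(cat0$probs[, 1:2])
    d <- sample_mutations_from_signatures(two, c(0.7, 0.3), 5000, "S1",
                                          seed = seed)
    fit <- refit_exposures(d$counts, two)
    expect_equal(unname(fit$percents), c(70, 30), tolerance = 3 / 30)
    expect_lt(max(abs(unname(fit$percents) - c(70, 30))), 3)
  }
})

test_that("exposure estimates tighten as the mutation count grows", {
  cat0 <- synthetic_signature_catalog()
  mix <- c(0.84, 0.10, 0.06)
  err <- vapply(c(500, 2000, 8000), function(n) {
    errs <- vapply(1:5, function(s) {
      d <- sample_mutations_from_signatures(cat0, mix, n, "S1",
                                            seed = 1000 + s)
      fit <- refit_exposures(d$counts, cat0)
      max(abs(fit$percents / 100 - mix))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.03)
})

test_that("generated cohorts are deterministic and honor the dbSNP fraction", {
  cfg <- sim_config(n_case = 3, n_control = 2, mutations_per_sample = 100,
                    seed = 7)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(s1$case), as.data.frame(s2$case))
  expect_identical(as.data.frame(s1$control), as.data.frame(s2$control))
  expect_identical(s1$truth$channel_counts, s2$truth$channel_counts)

  ## dbsnp_fraction = 1 with no plantings: nothing survives the novel stage
  all_known <- generate_cohort(
    sim_config(n_case = 2, n_control = 2, mutations_per_sample = 50,
               dbsnp_fraction = 1, seed = 8)
  )
  expect_true(all(!is.na(all_known$case$dbsnp_id)))
  expect_equal(nrow(filter_known_polymorphisms(all_known$case)), 0L)
})

test_that("the funnel recovers exactly the planted driver structure", {
  cfg <- sim_config(
    mutations_per_sample = 300,
    planted_drivers = list(
      list(gene = "GENEX", n_case_samples = 3, consequence = "MISSENSE"),
      list(gene = "GENEY", n_case_samples = 1, consequence = "MISSENSE"),
      list(gene = "GENEZ", n_case_samples = 2, consequence = "SYNONYMOUS"),
      list(gene = "GENEW", n_case_samples = 2, consequence = "INDEL")
    ),
    planted_reported_genes = "GENER",
    seed = 33
  )
  sim <- generate_cohort(cfg)
  rep <- run_funnel(sim$case, sim$control, sim$drivers, sim$reported)
  expect_setequal(as.character(rep$final_genes), c("GENEX", "GENEW"))
  expect_setequal(as.character(rep$final_genes),
                  as.character(sim$truth$expected_final))
  ## the manifest's planted map names the mutated case samples
  expect_length(sim$truth$planted[["GENEX"]], 3L)
})

test_that("the published mutation fixture matches its printed counts", {
  tab4 <- table4_fixture()
  expect_equal(nrow(tab4), 37L)  # per-sample expansion of 28 mutations
  expect_equal(dplyr::n_distinct(paste(tab4$gene, tab4$hgvs_c)), 28L)
  expect_equal(dplyr::n_distinct(tab4$gene), 14L)
  expect_equal(nrow(table4_fixture(expand = FALSE)), 28L)

  gnaq <- tab4[tab4$gene == "GNAQ", ]
  expect_setequal(gnaq$sample_id, c("KT80", "KT721", "KT79"))
  expect_setequal(unique(gnaq$hgvs_c), c("c.169A>T", "c.263A>T"))
  expect_equal(unique(gnaq$hgvs_p[gnaq$hgvs_c == "c.169A>T"]), "p.K57*")

  hox <- tab4[tab4$gene == "HOXD13", ]
  expect_equal(unique(hox$chrom), "2")
  expect_equal(unique(hox$pos), 176957650L)

  ## KT80 and KT721 are one patient
  expect_equal(
    unique(tab4$patient_id[tab4$sample_id %in% c("KT80", "KT721")]),
    "KT80_KT721"
  )
  ## the fixture's genes are exactly the published final list, and a subset
  ## of the 17 case-unique genes
  expect_setequal(unique(tab4$gene), as.character(table4_genes()))
  expect_true(all(table4_genes() %in% table3_genes()))
})

test_that("recurrence over the fixture distinguishes sample and patient units", {
  tab4 <- classify_variants(table4_fixture())
  ## CARD11 is recurrent across KT80/KT721 samples but they are one patient
  card <- tab4[tab4$gene == "CARD11", ]
  expect_setequal(as.character(recurrence_filter(card)), "CARD11")
  expect_length(
    recurrence_filter(card, config = funnel_config(recurrence_unit = "PATIENT")),
    0L
  )
  ## HOXD13 is recurrent under both units
  hox <- tab4[tab4$gene == "HOXD13", ]
  expect_setequal(
    as.character(recurrence_filter(
      hox, config = funnel_config(recurrence_unit = "PATIENT")
    )),
    "HOXD13"
  )
})
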