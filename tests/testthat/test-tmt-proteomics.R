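test_that("channel median normalization equalizes medians and is idempotent", {
  pep <- data.frame(peptide_id = paste0("p", 1:3),
                    protein_id = "prot1",
                    mascot_score = 50, isolation_interference = 0,
                    abundance_a = c(5, 10, 15),
                    abundance_b = c(10, 20, 30))
  out <- normalize_channels(pep)
  # channel medians were {10, 20}; grand median 15: channel b halved
  # relative to channel a up to the common rescale
  expect_equal(out$abundance_b, out$abundance_a)
  expect_equal(stats::median(out$abundance_a), 15)
  expect_identical(normalize_channels(out), out)
  # equal medians already: identity
  pep2 <- pep
  pep2$abundance_b <- pep2$abundance_a
  expect_equal(normalize_channels(pep2), pep2)
  pep$abundance_a <- 0
  expect_error(normalize_channels(pep), "abundance_a")
})

test_that("Mascot/interference filter keeps exactly the passing rows", {
  pep <- peptide_filter_fixture()
  kept <- filter_peptides(pep)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$peptide_id, c("pep1", "pep2"))
  # boundary row (score 25, interference 30) is retained: both inclusive
  expect_true("pep2" %in% kept$peptide_id)
  expect_equal(attr(kept, "filter_counts"), c(kept = 2, dropped = 3))
  empty <- pep[0, ]
  expect_warning(res_empty <- filter_peptides(empty), "all peptides")
  expect_equal(nrow(res_empty), 0)
  # relaxing thresholds never loses rows
  expect_gte(nrow(filter_peptides(pep, min_mascot = 20,
                                  max_interference = 40)), nrow(kept))
})

test_that("protein rollup sums channels and counts peptides correctly", {
  pep <- data.frame(
    peptide_id = c("a1", "a2", "a2", "b1"),
    protein_id = c("protA", "protA", "protA", "protB"),
    mascot_score = 50, isolation_interference = 0,
    abundance_x = c(3, 7, 2, 5)
  )
  prot <- rollup_proteins(pep, rp_list = "protB")
  a <- prot[prot$protein_id == "protA", ]
  expect_equal(a$abundance_x, 12)
  # duplicated peptide sequence: TotPep counts rows, UniPep distinct ids
  expect_equal(a$tot_pep, 3)
  expect_equal(a$uni_pep, 2)
  expect_false(a$is_ribosomal)
  expect_true(prot$is_ribosomal[prot$protein_id == "protB"])
  # conservation per channel
  expect_equal(sum(prot$abundance_x), sum(pep$abundance_x))
  # unmapped peptides dropped with a message
  pep$protein_id[4] <- ""
  expect_message(rollup_proteins(pep, rp_list = character(0)), "no protein")
})

test_that("rp_fraction applies the strict eligibility gate to both sums", {
  prot <- data.frame(
    protein_id = c("RPL1", "RPS2", "ACT1", "MARGINAL"),
    is_ribosomal = c(TRUE, TRUE, FALSE, TRUE),
    tot_pep = c(5, 4, 6, 2),    # MARGINAL fails TotPep > 2
    uni_pep = c(3, 3, 4, 2),
    abundance_c1 = c(10, 20, 70, 1000),
    abundance_c2 = c(5, 5, 40, 1000)
  )
  rf <- rp_fraction(prot, reference_channel = "c1")
  expect_equal(rf$rp_fraction, c(30 / 100, 10 / 50))
  expect_equal(rf$normalized_log2, c(0, log2((10 / 50) / (30 / 100))))
  # at the boundary TotPep = 3 the protein becomes eligible
  prot$tot_pep[4] <- 3
  rf2 <- rp_fraction(prot, "c1")
  expect_gt(rf2$rp_fraction[1], rf$rp_fraction[1])
  expect_error(rp_fraction(prot, "c9"), "reference channel")
})

test_that("fractions {0.20, 0.10} give normalized log2 {0, -1}", {
  prot <- data.frame(protein_id = c("RPL1", "OTHER"),
                     is_ribosomal = c(TRUE, FALSE),
                     tot_pep = 5, uni_pep = 3,
                     abundance_t1 = c(20, 80),
                     abundance_t2 = c(10, 90))
  rf <- rp_fraction(prot, "t1")
  expect_equal(rf$rp_fraction, c(0.20, 0.10))
  expect_equal(rf$normalized_log2, c(0, -1))
})

test_that("zero-noise synthetic TMT recovers true fractions exactly", {
  sc <- three_channel_scenario(tmt_cv = 0)
  tm <- make_tmt(sc, n_proteins = 120)
  expect_equal(tm$truth$rp_fraction, c(0.20, 0.15, 0.10))
  pep <- normalize_channels(filter_peptides(tm$peptides))
  prot <- rollup_proteins(pep, rp_list = tm$rp_names)
  rf <- rp_fraction(prot, reference_channel = "0h")
  expect_equal(rf$rp_fraction, tm$truth$rp_fraction, tolerance = 1e-12)
  # conservation: protein channel sums match the filtered peptide sums
  for (ch in tmt_channels(pep))
    expect_equal(sum(prot[[ch]]), sum(pep[[ch]]))
  expect_true(all(rf$rp_fraction >= 0 & rf$rp_fraction <= 1))
})

test_that("peptide report survives a CSV round trip with column remapping", {
  tm <- make_tmt(arrest_scenario(t_grid = c(0, 1), seed = 9L),
                 n_proteins = 20)
  path <- tempfile(fileext = ".csv")
  df <- tm$peptides
  names(df)[names(df) == "mascot_score"] <- "Ions.Score"
  utils::write.csv(df, path, row.names = FALSE)
  back <- read_peptides(path, column_map = c(mascot_score = "Ions.Score"))
  expect_equal(back$mascot_score, tm$peptides$mascot_score,
               tolerance = 1e-12)
  expect_error(read_peptides(path), "lacks columns")
})
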