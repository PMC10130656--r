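test_that("viability normalization to the reference timepoint", {
  counts <- data.frame(timepoint_h = c(2, 6, 9),
                       colonies = c(280, 250, 140))
  out <- viability(counts)
  expect_equal(out$viability, c(1, 250 / 280, 0.5))
  expect_equal(unique(out$plated), 300)
  # 0-h reference supported for designs normalized to the shift
  counts0 <- data.frame(timepoint_h = c(0, 2), colonies = c(300, 270))
  out0 <- viability(counts0, reference_timepoint = 0)
  expect_equal(out0$viability, c(1, 0.9))
  expect_error(viability(counts, reference_timepoint = 0), "not present")
  expect_warning(viability(data.frame(timepoint_h = 2, colonies = 400)),
                 "exceeds")
  # replicate rows averaged with half-range dispersion
  rep2 <- data.frame(timepoint_h = c(2, 2, 9, 9),
                     colonies = c(280, 300, 120, 160))
  outr <- viability(rep2)
  expect_equal(outr$n_replicates, c(2, 2))
  expect_equal(outr$dispersion[2], (160 / 300 - 120 / 300) / 2)
})

test_that("ESR-size correlation on monotone and anti-coupled data", {
  tab <- data.frame(iESR = 1:8, mean_volume_fl = (1:8)^2)
  out <- esr_size_correlation(tab, n_boot = 100)
  expect_equal(out$estimate, 1)
  anti <- data.frame(iESR = 1:8, mean_volume_fl = -(1:8))
  expect_equal(esr_size_correlation(anti, n_boot = 100)$estimate, -1)
  expect_error(esr_size_correlation(tab[1:3, ], n_boot = 100),
               "at least 4")
  pear <- esr_size_correlation(tab, method = "pearson", n_boot = 100)
  expect_lt(pear$estimate, 1)
})

test_that("shuffled pairings give small correlations whose CI covers zero", {
  set.seed(71)
  covered <- vapply(1:20, function(i) {
    tab <- data.frame(iESR = stats::rnorm(20),
                      mean_volume_fl = stats::rnorm(20))
    out <- esr_size_correlation(tab, n_boot = 200, seed = i)
    out$ci_lo <= 0 && out$ci_hi >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("pipeline runs end to end on generated files and joins cleanly", {
  sc <- quiet_scenario(t_grid = c(0, 1, 3, 6, 9), seed = 77L)
  dir <- withr::local_tempdir()
  paths <- write_scenario_data(sc, dir, n_genes = 1000, n_proteins = 80,
                               n_cells = 400, n_tracks = 25)
  sheet <- scenario_sample_sheet(sc, paths)
  rep <- run_pipeline(sheet, config = list(n_boot = 100,
                                           tmt_reference_channel = "1h",
                                           viability_reference_h = 0))
  expect_s3_class(rep, "arrest_report")
  expect_length(rep$errors, 0)
  cm <- rep$cross_modality
  # exactly one row per condition x timepoint in the sheet
  expect_equal(nrow(cm), 5)
  expect_false(any(duplicated(cm[, c("condition", "timepoint_h")])))
  expect_true(all(c("iESR", "rESR", "rp_fraction", "mean_volume_fl",
                    "median_d_eff_um2s", "viability") %in% names(cm)))
  expect_true(all(is.finite(cm$iESR)))
  # qualitative arrest signature at zero noise
  expect_true(all(diff(cm$iESR) > 0))
  expect_true(all(diff(cm$rESR) < 0))
  expect_true(all(diff(cm$rp_fraction) < 0))
  expect_gt(rep$correlation$estimate, 0.9)
})

test_that("stage failures are isolated and recorded", {
  sc <- quiet_scenario(t_grid = c(0, 1, 2, 4), seed = 78L)
  dir <- withr::local_tempdir()
  paths <- write_scenario_data(sc, dir, n_genes = 1000, n_proteins = 60,
                               n_cells = 300, n_tracks = 15)
  writeLines("garbage,not,a,peptide,table", paths$peptides)
  sheet <- scenario_sample_sheet(sc, paths)
  rep <- run_pipeline(sheet, config = list(n_boot = 50,
                                           tmt_reference_channel = "1h",
                                           viability_reference_h = 0))
  expect_named(rep$errors, "tmt")
  expect_null(rep$rp_fractions)
  expect_true(all(is.na(rep$cross_modality$rp_fraction)) ||
                !"rp_fraction" %in% names(rep$cross_modality))
  # the other modalities still produced their columns
  expect_true(all(is.finite(rep$cross_modality$mean_volume_fl)))
  expect_true(all(is.finite(rep$cross_modality$iESR)))
})

test_that("empty or malformed sample sheets are rejected", {
  expect_error(run_pipeline(data.frame()), "sample sheet")
  expect_error(run_pipeline(data.frame(sample = character(0),
                                       condition = character(0),
                                       timepoint_h = numeric(0))),
               "sample sheet")
})

test_that("reruns of the same pipeline are identical and the manifest is written", {
  sc <- quiet_scenario(t_grid = c(0, 2, 5, 9), seed = 79L)
  dir <- withr::local_tempdir()
  paths <- write_scenario_data(sc, dir, n_genes = 1000, n_proteins = 60,
                               n_cells = 300, n_tracks = 15)
  sheet <- scenario_sample_sheet(sc, paths)
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  cfg <- list(n_boot = 100, tmt_reference_channel = "0h")
  rep1 <- run_pipeline(sheet, config = cfg, out_dir = out1)
  rep2 <- run_pipeline(sheet, config = cfg, out_dir = out2)
  expect_identical(rep1$cross_modality, rep2$cross_modality)
  expect_identical(rep1$correlation, rep2$correlation)
  # written stage tables are byte-identical across reruns
  for (f in list.files(out1)) {
    if (f == "manifest.json") next
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  expect_true(file.exists(file.path(out1, "manifest.json")))
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$n_samples, 4)
})
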