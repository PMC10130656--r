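test_that("scenario validation rejects malformed latent parameters", {
  expect_error(arrest_scenario(plateau_volume = 10, v0 = 60), "plateau")
  expect_error(arrest_scenario(esr_strength = function(t) t), "\\[0, 1\\]")
  expect_error(arrest_scenario(rp_fraction0 = 1.2))
  expect_error(arrest_scenario(noise = list(bogus = 1)), "unknown noise")
  expect_error(make_expression(quiet_scenario(),
                               n_genes = 1000,
                               iesr_set = c("gene0001"),
                               resr_set = c("gene0001")), "disjoint")
  expect_error(make_expression(quiet_scenario(), n_genes = -5), "positive")
})

test_that("identical seed and scenario give bit-identical synthetic data", {
  sc1 <- arrest_scenario(seed = 42L)
  sc2 <- arrest_scenario(seed = 42L)
  expect_identical(make_expression(sc1, n_genes = 1200),
                   make_expression(sc2, n_genes = 1200))
  expect_identical(make_tmt(sc1, n_proteins = 60),
                   make_tmt(sc2, n_proteins = 60))
  expect_identical(make_volume_histograms(sc1, n_cells = 500),
                   make_volume_histograms(sc2, n_cells = 500))
  expect_identical(make_trajectories(sc1, n_tracks = 5, n_frames = 50),
                   make_trajectories(sc2, n_tracks = 5, n_frames = 50))
  expect_identical(make_viability(sc1), make_viability(sc2))
  # a different seed must actually change the draws
  sc3 <- arrest_scenario(seed = 43L)
  expect_false(identical(make_expression(sc1, n_genes = 1200)$expression,
                         make_expression(sc3, n_genes = 1200)$expression))
})

test_that("latent coupling is monotone: rp fraction falls, diffusion rises", {
  sc <- arrest_scenario(rp_decline = 0.5)
  tr <- scenario_truth(sc)
  expect_true(all(diff(tr$esr_strength) > 0))
  expect_true(all(diff(tr$rp_fraction) < 0))
  expect_true(all(diff(tr$diffusion_um2s) > 0))
  expect_true(all(diff(tr$volume_fl) >= 0))
  expect_true(all(tr$volume_fl <= sc$plateau_volume))
})

test_that("TPM columns sum to one million", {
  ex <- make_expression(arrest_scenario(seed = 5L), n_genes = 1500)
  expect_equal(colSums(ex$expression$values),
               rep(1e6, ncol(ex$expression$values)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ESR shift moves set genes in opposite directions", {
  # same seed, s pinned to 0 vs 1: the iESR projection must rise and the
  # baseline (s = 0) case must look like an unshifted draw
  sc0 <- quiet_scenario(t_grid = 0, esr_strength = function(t) rep(0, length(t)))
  sc1 <- quiet_scenario(t_grid = 0, esr_strength = function(t) rep(1, length(t)))
  e0 <- make_expression(sc0, n_genes = 2000)
  e1 <- make_expression(sc1, n_genes = 2000)
  p0 <- project_gene_sets(preprocess_tpm(e0$expression), e0$gene_sets,
                          alpha = 0)
  p1 <- project_gene_sets(preprocess_tpm(e1$expression), e1$gene_sets,
                          alpha = 0)
  expect_gt(p1$projection[p1$gene_set == "iESR"],
            p0$projection[p0$gene_set == "iESR"])
  expect_lt(p1$projection[p1$gene_set == "rESR"],
            p0$projection[p0$gene_set == "rESR"])
  # at s = 0 an ESR set scores like a random set of the same size
  set.seed(99)
  rand_set <- sample(rownames(e0$expression$values), 300)
  pr <- ssgsea_projection(preprocess_tpm(e0$expression)$values[, 1],
                          rand_set, alpha = 0)
  expect_lt(abs(p0$projection[p0$gene_set == "iESR"] - pr$projection),
            60)  # both near zero relative to the s=1 projection (~490)
})

test_that("volume generator: capped exponential and exact monodisperse bins", {
  sc <- quiet_scenario(t_grid = c(0, 9), v0 = 100, doubling_time = 90,
                       plateau_volume = Inf)
  expect_equal(scenario_volume(sc), c(100, 6400))
  vh <- make_volume_histograms(sc, n_cells = 100)
  # zero dispersion: all mass in the single bin holding the true volume
  expect_equal(vh$histograms[["9h"]],
               data.frame(bin_volume_fl = 6400, count = 100))
  expect_equal(sapply(vh$histograms, mean_volume), c(`0h` = 100, `9h` = 6400))
})

test_that("trajectory generator: D = 0 freezes particles, noise adds jitter", {
  sc <- quiet_scenario(t_grid = 0, diffusion0 = 0)
  tj <- make_trajectories(sc, n_tracks = 3, n_frames = 20)
  expect_true(all(tj$tracks$x_um == 0) && all(tj$tracks$y_um == 0))
  scn <- arrest_scenario(t_grid = 0, diffusion0 = 0,
                         noise = list(localization = 0.03), seed = 2L)
  tjn <- make_trajectories(scn, n_tracks = 3, n_frames = 20)
  expect_gt(stats::sd(tjn$tracks$x_um), 0)
  expect_error(make_trajectories(sc, n_tracks = 0, n_frames = 20))
})

test_that("tracking dropout truncates tracks but never below 10 frames", {
  sc <- arrest_scenario(t_grid = 0, seed = 3L)
  tj <- make_trajectories(sc, n_tracks = 50, n_frames = 100, dropout = 0.5)
  len <- table(tj$tracks$track_id)
  expect_true(any(len < 100))
  expect_true(all(len >= 10))
})

test_that("viability generator: deterministic mode arithmetic and default plating", {
  sc <- quiet_scenario(t_grid = c(0, 1, 2))
  vi <- make_viability(sc, survival = function(t) c(1, 0.9, 0.5))
  expect_equal(vi$counts$colonies, c(300, 270, 150))
  expect_equal(unique(vi$counts$plated), 300)
  # survival == 1 in deterministic mode returns exactly the plated count
  vi1 <- make_viability(sc, survival = function(t) rep(1, length(t)))
  expect_equal(vi1$counts$colonies, rep(300, 3))
  expect_error(make_viability(sc, survival = function(t) rep(1.5, length(t))))
})

test_that("filter-fail fraction behaves binomially over seeds", {
  fail_frac <- 0.2
  n_dropped <- vapply(1:15, function(seed) {
    sc <- arrest_scenario(t_grid = c(0, 1), seed = seed)
    tm <- make_tmt(sc, n_proteins = 100, fail_fraction = fail_frac)
    kept <- filter_peptides(tm$peptides)
    nrow(tm$peptides) - nrow(kept)
  }, numeric(1))
  n_total <- vapply(1:15, function(seed) {
    sc <- arrest_scenario(t_grid = c(0, 1), seed = seed)
    nrow(make_tmt(sc, n_proteins = 100, fail_fraction = fail_frac)$peptides)
  }, numeric(1))
  # pooled dropped count within 3 sigma of the binomial expectation
  n <- sum(n_total)
  expect_lt(abs(sum(n_dropped) - n * fail_frac),
            3 * sqrt(n * fail_frac * (1 - fail_frac)))
  # and a zero fail fraction drops nothing
  tm0 <- make_tmt(arrest_scenario(t_grid = 0), n_proteins = 50,
                  fail_fraction = 0)
  expect_equal(nrow(filter_peptides(tm0$peptides)), nrow(tm0$peptides))
})
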