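test_that("the generator is bitwise deterministic given its seed", {
  cfg <- sim_config(n_samples = 40, seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(s1$alignment, f1); write_fasta(s2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  write_sample_table(s1$samples, f1); write_sample_table(s2$samples, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(aln_strings(s1$dloop), aln_strings(s2$dloop))
  # a different seed changes the data
  s3 <- simulate_dataset(sim_config(n_samples = 40, seed = 78))
  expect_false(identical(aln_strings(s1$alignment),
                         aln_strings(s3$alignment)))
})

test_that("zero within-group diversity degenerates to identical sequences", {
  cfg <- sim_config(n_samples = 30, n_groups = 2, within_theta = 0,
                    basin_effect = 0, seed = 5)
  sim <- simulate_dataset(cfg, dloop = FALSE)
  for (g in unique(sim$samples$phylogroup)) {
    rows <- aln_strings(sim$alignment)[
      sim$samples$seq_name[sim$samples$phylogroup == g]]
    expect_identical(length(unique(rows)), 1L)
  }
  surf <- diversity_surface(sim$samples, sim$alignment, radius_km = 2000,
                            min_samples = 2)
  expect_true(all(surf$pi == 0))
})

test_that("between-group divergence hits its target within sampling error", {
  cfg <- sim_config(n_samples = 120, n_groups = 2, seed = 31)
  sim <- simulate_dataset(cfg, dloop = FALSE)
  a <- unclass(sim$alignment)[
    sim$samples$seq_name[sim$samples$phylogroup == "A"], ]
  b <- unclass(sim$alignment)[
    sim$samples$seq_name[sim$samples$phylogroup == "B"], ]
  got <- between_group_p_distance(a, b)
  se <- sqrt(0.0116 * (1 - 0.0116) / 752)
  expect_lt(abs(got - 0.0116), 3 * se)
})

test_that("simulated D-loop strips to its core and concatenates to full length", {
  cfg <- sim_config(seed = 9)
  sim <- simulate_dataset(cfg)
  expect_identical(aln_length(sim$alignment), 752L)
  expect_identical(aln_length(sim$dloop), 450L)
  core <- eliminate_gap_positions(sim$dloop)
  expect_identical(aln_length(core), 272L)
  cc <- concatenate_alignments(list(cytb = sim$alignment, dloop = core))
  expect_identical(aln_length(cc$alignment), 1024L)
  # samples lacking a D-loop are padded with N over its columns
  missing_dloop <- setdiff(aln_names(sim$alignment), aln_names(sim$dloop))
  expect_gt(length(missing_dloop), 0)
  tail_block <- substring(aln_strings(cc$alignment)[missing_dloop], 753,
                          1024)
  expect_true(all(tail_block == strrep("N", 272)))
})

test_that("groups overlap only inside the contact band", {
  cfg <- sim_config(n_samples = 200, n_groups = 2, contact_band_km = 30,
                    seed = 13)
  sim <- simulate_dataset(cfg, dloop = FALSE)
  lon_a <- sim$samples$lon[sim$samples$phylogroup == "A"]
  lon_b <- sim$samples$lon[sim$samples$phylogroup == "B"]
  # ranges overlap (a contact zone exists) ...
  expect_gt(max(lon_a), min(lon_b))
  # ... but only by about the contact-band width
  km_per_deg <- 111.32 * cos(40 * pi / 180)
  overlap_km <- (max(lon_a) - min(lon_b)) * km_per_deg
  expect_lt(overlap_km, 31)
})

test_that("injected sub-km duplicates leave downstream results unchanged", {
  cfg <- sim_config(n_samples = 60, seed = 23)
  sim <- simulate_dataset(cfg, dloop = FALSE)
  base <- dedup_by_haplotype(sim$samples, sim$alignment, min_km = 1)$kept

  set.seed(99)
  dup_idx <- sample(seq_len(nrow(base)), 10)
  dups <- base[dup_idx, ]
  dups$id <- paste0(dups$id, "_dup")
  dups$lat <- dups$lat + runif(10, -0.004, 0.004)  # < 1 km jitter
  aug <- rbind(sim$samples, dups)
  kept2 <- dedup_by_haplotype(aug, sim$alignment, min_km = 1)$kept

  expect_identical(sort(kept2$id), sort(base$id))
  s1 <- diversity_surface(base, sim$alignment, radius_km = 100,
                          min_samples = 3)
  s2 <- diversity_surface(kept2, sim$alignment, radius_km = 100,
                          min_samples = 3)
  expect_equal(s2[order(s2$sample_id), ], s1[order(s1$sample_id), ],
               ignore_attr = TRUE)
})

test_that("raster simulation honors noise, no-data borders and determinism", {
  cfg <- sim_config(seed = 41)
  rs <- simulate_rasters(cfg, n_models = 3, noise_sd = 0)
  # zero noise: all models identical, consensus saturates inside the area
  expect_equal(rs$rasters[[1]]$grid, rs$rasters[[2]]$grid)
  pv <- rs$presence$true_suitability
  bins <- lapply(rs$rasters, function(r)
    percentile_threshold(r, pv, pct = 90)$raster)
  cons <- consensus_raster(bins)
  inside <- cons$grid[!is.na(cons$grid)]
  expect_true(all(inside %in% c(0, 3)))
  # border no-data propagates end to end
  expect_true(all(is.na(cons$grid[1, ])))
  expect_true(all(is.na(cons$grid[, 1])))

  rs2 <- simulate_rasters(cfg, n_models = 3, noise_sd = 0)
  expect_identical(rs2$presence, rs$presence)
  expect_identical(rs2$true_center, rs$true_center)
})

test_that("noisy-model consensus still covers the true optimum", {
  hits <- vapply(1:30, function(s) {
    rs <- simulate_rasters(sim_config(seed = 600 + s), n_models = 3)
    pv <- rs$presence$true_suitability
    bins <- lapply(rs$rasters, function(r)
      percentile_threshold(r, pv, pct = 75)$raster)
    cons <- consensus_raster(bins)
    g <- cons$grid
    row <- ceiling((rs$true_field$yll + nrow(g) * rs$true_field$cellsize -
                      rs$true_center["lat"]) / rs$true_field$cellsize)
    col <- ceiling((rs$true_center["lon"] - rs$true_field$xll) /
                     rs$true_field$cellsize)
    isTRUE(g[row, col] >= 2)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("grid snapping keeps one point per cell", {
  pts <- data.frame(lat = c(40, 40.001, 40.3, 40.3005),
                    lon = c(-3, -3.0005, -3, -3))
  thin <- snap_to_grid(pts, cell_km = 1)
  expect_identical(nrow(thin), 2L)
  # idempotent
  expect_identical(snap_to_grid(thin, cell_km = 1), thin)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(sim_config(seed = 1, basin_effect = 1),
               class = "parameter_error")
  expect_error(sim_config(seed = 1, n_samples = 1, n_groups = 2),
               class = "parameter_error")
  expect_error(sim_config(), class = "parameter_error")  # seed mandatory
  expect_error(sim_config(seed = 1, dloop_core = 500, dloop_length = 450),
               class = "parameter_error")
})
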