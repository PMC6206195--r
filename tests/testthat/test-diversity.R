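test_that("p-distance handles missing data by pairwise deletion", {
  expect_equal(pairwise_p_distance("ACGT", "ACGT"), 0)
  expect_equal(pairwise_p_distance("ACGT", "ACGA"), 0.25)
  # N site dropped: 3 comparable sites, 1 difference
  expect_equal(pairwise_p_distance("ACGN", "ACTA"), 1 / 3)
  expect_error(pairwise_p_distance("NNNN", "ACGT"),
               class = "undefined_distance_error")
  expect_error(pairwise_p_distance("ACG", "ACGT"),
               class = "alignment_shape_error")
})

test_that("small worked examples match hand enumeration", {
  rows <- c("ACGT", "ACGA", "ACCA")
  expect_equal(nucleotide_diversity(rows), mean(c(0.25, 0.50, 0.25)))
  # duplicating both members of a pair: 4 cross pairs at p, 2 at 0
  p <- pairwise_p_distance("ACGT", "ACCA")
  expect_equal(nucleotide_diversity(c("ACGT", "ACGT", "ACCA", "ACCA")),
               4 * p / 6)
  expect_equal(nucleotide_diversity(rep("ACGT", 5)), 0)

  expect_equal(watterson_theta(c("ACGT", "ACGA")), 1 / (1 * 4))
  expect_equal(watterson_theta(rows), 2 / (1.5 * 4))
  expect_equal(watterson_theta(c("ACGT", "ACGT")), 0)

  expect_equal(haplotype_diversity(c("ACGT", "ACGT")), 0)
  expect_equal(haplotype_diversity(c("ACGT", "ACGA")), 1)
  expect_equal(haplotype_diversity(c("AA", "AA", "AT", "AT")),
               (4 / 3) * (1 - 0.5))

  expect_equal(between_group_p_distance("ACGT", "ACGT"), 0)
  expect_equal(between_group_p_distance("ACGT", c("ACGA", "ACCA")),
               mean(c(0.25, 0.5)))
  expect_equal(between_group_p_distance(c("ACGA", "ACCA"), "ACGT"),
               between_group_p_distance("ACGT", c("ACGA", "ACCA")))

  expect_error(nucleotide_diversity("ACGT"),
               class = "insufficient_sample_error")
  expect_error(between_group_p_distance(character(0), "ACGT"),
               class = "insufficient_sample_error")
})

test_that("estimators match brute-force enumeration on random alignments", {
  set.seed(31)
  for (rep in 1:120) {
    m <- random_alignment(sample(2:10, 1), sample(4:50, 1),
                          p_missing = sample(c(0, 0.05, 0.15), 1))
    # skip draws where some pair shares no comparable site
    ok <- tryCatch({ nucleotide_diversity(m); TRUE },
                   error = function(e) FALSE)
    if (!ok) next
    expect_equal(nucleotide_diversity(m), oracle_pi(m), tolerance = 1e-12)
    th <- tryCatch(watterson_theta(m), error = function(e) NA)
    if (!is.na(th)) expect_equal(th, oracle_theta_w(m), tolerance = 1e-12)
    expect_equal(haplotype_diversity(m), oracle_hap_div(m),
                 tolerance = 1e-12)
    half <- sample(nrow(m), max(1, nrow(m) %/% 2))
    expect_equal(between_group_p_distance(m[half, , drop = FALSE],
                                          m[-half, , drop = FALSE]),
                 oracle_between(m[half, , drop = FALSE],
                                m[-half, , drop = FALSE]),
                 tolerance = 1e-12)
    # row-order invariance of pi
    expect_equal(nucleotide_diversity(m[sample(nrow(m)), ]),
                 nucleotide_diversity(m), tolerance = 1e-12)
  }
})

test_that("distance models agree with ape and obey the JC69 correction", {
  set.seed(32)
  for (rep in 1:10) {
    m <- random_alignment(sample(3:8, 1), 200, p_missing = 0.02)
    aln <- dna_alignment(m)
    dna <- ape::as.DNAbin(tolower(unclass(aln)))
    p_ape <- ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE,
                           as.matrix = TRUE)
    expect_equal(distance_matrix(aln, "p"), p_ape, tolerance = 1e-12)

    pm <- distance_matrix(aln, "p")
    ok_jc <- all(pm[upper.tri(pm)] < 0.74)
    if (ok_jc) {
      jc <- distance_matrix(aln, "JC69")
      # monotone correction: JC69 >= p for p in (0, 3/4)
      expect_true(all(jc[upper.tri(jc)] >= pm[upper.tri(pm)] - 1e-12))
      expect_equal(jc[upper.tri(jc)],
                   (-3 / 4) * log(1 - (4 / 3) * pm[upper.tri(pm)]),
                   tolerance = 1e-9)
      k80 <- distance_matrix(aln, "K80")
      expect_true(all(is.finite(k80)))
    }
  }
  expect_equal(pairwise_p_distance("ACGT", "ACGT"), 0)
  ident <- dna_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  for (mod in c("p", "JC69", "K80")) {
    expect_true(all(distance_matrix(ident, mod) == 0))
  }
})

test_that("saturated pairs raise a saturation error under JC69", {
  aln <- dna_alignment(c(a = "AAAA", b = "CCCC"))  # p = 1 >= 3/4
  expect_error(distance_matrix(aln, "JC69"), class = "saturation_error")
})

test_that("pi and Watterson's theta share an expectation under neutral equilibrium", {
  # coalescent descent, one panmictic group, no basin structure
  reps <- vapply(1:250, function(s) {
    cfg <- sim_config(n_samples = 10, n_groups = 1, seq_length = 500,
                      within_theta = 0.01, basin_effect = 0,
                      genealogy = "coalescent", seed = 9000 + s)
    sim <- simulate_dataset(cfg, dloop = FALSE)
    c(nucleotide_diversity(sim$alignment), watterson_theta(sim$alignment))
  }, numeric(2))
  rel <- abs(mean(reps[1, ]) - mean(reps[2, ])) / mean(reps[2, ])
  expect_lt(rel, 0.10)
})

test_that("distance matrices round-trip their TSV serialization", {
  set.seed(33)
  aln <- dna_alignment(random_alignment(4, 60, 0))
  d <- distance_matrix(aln)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE)
  expect_equal(as.matrix(back), d, tolerance = 1e-12)
})
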