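test_that("a fixed 4x4 toy matrix reproduces hand-computed sums of squares", {
  # 4 samples, 2 groups of 2; distances chosen for easy hand arithmetic
  d <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d["s1", "s2"] <- d["s2", "s1"] <- 1
  d["s3", "s4"] <- d["s4", "s3"] <- 2
  d["s1", "s3"] <- d["s3", "s1"] <- 4
  d["s1", "s4"] <- d["s4", "s1"] <- 4
  d["s2", "s3"] <- d["s3", "s2"] <- 4
  d["s2", "s4"] <- d["s4", "s2"] <- 4
  g <- c("x", "x", "y", "y")
  # by hand: SS_total = (1 + 4 + 16*4)/4 = 17.25
  #          SS_within = 1/2 + 4/2 = 2.5 ; SS_among = 14.75
  #          MS_among = 14.75, MS_within = 1.25, n_c = 2
  #          sigma2_among = 6.75, phi = 6.75/8
  res <- amova_oneway(d, g, n_perm = 0)
  expect_equal(res$ss_total, 17.25)
  expect_equal(res$ss_within, 2.5)
  expect_equal(res$ss_among, 14.75)
  expect_equal(res$sigma2_within, 1.25)
  expect_equal(res$sigma2_among, 6.75)
  expect_equal(res$phi_st, 6.75 / 8)
  expect_equal(pct_variation(res), 100 * 6.75 / 8)
})

test_that("maximal structure yields phi = 1 and 100% among-group variation", {
  aln <- dna_alignment(c(x1 = "AAAA", x2 = "AAAA", y1 = "GGGG",
                         y2 = "GGGG"))
  res <- amova_oneway(distance_matrix(aln), c("x", "x", "y", "y"),
                      n_perm = 0)
  expect_equal(res$sigma2_within, 0)
  expect_equal(res$phi_st, 1)
  expect_equal(pct_variation(res), 100)
})

test_that("sums of squares are conserved and match direct arithmetic", {
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(6:20, 1)
    k <- sample(2:4, 1)
    pts <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(pts))
    g <- sample(paste0("g", 1:k), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    res <- amova_oneway(d, g, n_perm = 0)
    expect_lt(abs(res$ss_among + res$ss_within - res$ss_total), 1e-9)
    want <- oracle_amova_ss(d, g)
    expect_equal(res$ss_total, unname(want["total"]), tolerance = 1e-12)
    expect_equal(res$ss_within, unname(want["within"]), tolerance = 1e-12)
  }
})

test_that("SS and derived components agree with vegan's adonis2 partition", {
  set.seed(52)
  for (rep in 1:20) {
    n <- sample(8:24, 1)
    k <- sample(2:4, 1)
    g <- factor(sample(paste0("g", 1:k), n, replace = TRUE))
    if (length(unique(g)) < 2) next
    d <- dist(matrix(rnorm(n * 4), n))
    ref <- vegan::adonis2(d ~ g, permutations = 0)
    res <- amova_oneway(as.matrix(d), as.character(g), n_perm = 0)
    expect_equal(res$ss_among, ref$SumOfSqs[1], tolerance = 1e-9)
    expect_equal(res$ss_within, ref$SumOfSqs[2], tolerance = 1e-9)
    expect_equal(res$ss_total, ref$SumOfSqs[3], tolerance = 1e-9)
    # derive sigma2 and phi independently from vegan's SS by the
    # method-of-moments definitions
    sizes <- table(g)
    n_c <- (n - sum(sizes^2) / n) / (length(sizes) - 1)
    msa <- ref$SumOfSqs[1] / (length(sizes) - 1)
    msw <- ref$SumOfSqs[2] / (n - length(sizes))
    s2a <- (msa - msw) / n_c
    expect_equal(res$sigma2_among, s2a, tolerance = 1e-9)
    expect_equal(res$phi_st, s2a / (s2a + msw), tolerance = 1e-9)
  }
})

test_that("phi is invariant under uniform distance rescaling", {
  set.seed(53)
  d <- as.matrix(dist(matrix(rnorm(30), 10)))
  g <- rep(c("a", "b"), each = 5)
  r1 <- amova_oneway(d, g, n_perm = 0)
  r2 <- amova_oneway(3.7 * d, g, n_perm = 0)
  expect_equal(r1$phi_st, r2$phi_st, tolerance = 1e-12)
  expect_equal(pct_variation(r1), pct_variation(r2), tolerance = 1e-12)
})

test_that("permutation p-values are seed-reproducible and seed-sensitive", {
  set.seed(54)
  d <- as.matrix(dist(matrix(rnorm(36), 12)))
  g <- rep(c("a", "b", "c"), each = 4)
  r1 <- amova_oneway(d, g, n_perm = 199, seed = 7)
  r2 <- amova_oneway(d, g, n_perm = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  ps <- vapply(1:30, function(s)
    amova_oneway(d, g, n_perm = 99, seed = s)$p_value, numeric(1))
  expect_gt(length(unique(ps)), 1)
  expect_true(all(ps >= 1 / 100 & ps <= 1))
})

test_that("degenerate groupings and bad inputs are rejected", {
  d <- as.matrix(dist(matrix(rnorm(12), 4)))
  expect_error(amova_oneway(d, rep("a", 4), n_perm = 0),
               class = "degenerate_grouping_error")
  expect_error(amova_oneway(d, c("a", "a", "b", "b"), n_perm = -1),
               class = "parameter_error")
  expect_error(amova_oneway(d[1:2, 1:2], c("a", "b"), n_perm = 0),
               class = "parameter_error")
  # identical sequences in both groups: both components zero
  z <- matrix(0, 4, 4)
  expect_error(amova_oneway(z, c("a", "a", "b", "b"), n_perm = 0),
               class = "undefined_percentage_error")
})

test_that("AMOVA result tables serialize with all fields", {
  d <- as.matrix(dist(matrix(rnorm(30), 10)))
  res <- amova_oneway(d, rep(c("a", "b"), each = 5), n_perm = 99)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_amova_table(res, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_true(all(c("phi_st", "pct_among", "p_value") %in% tab$field))
  expect_equal(as.numeric(tab$value[tab$field == "phi_st"]), res$phi_st,
               tolerance = 1e-9)
})
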