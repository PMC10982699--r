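test_that("windowed bias reproduces the (W-C)/(W+C) arithmetic and NaN policy", {
  g <- toy_genome(c(chrI = 4000))
  o <- origin_set("chrI", 2000, "o1", g)
  # 30 W and 10 C fragments blanketing the profile region uniformly
  fr <- make_frags(g, rep("chrI", 40), rep(500, 40), rep(3500, 40),
                   rep(c("W", "C"), c(30, 10)))
  cov <- coverage_from_fragments(fr, g)
  b <- windowed_bias(cov, o, radius = 1000, window = 100, step = 100)
  expect_true(all(abs(b - 0.5) < 1e-12))

  fr2 <- make_frags(g, rep("chrI", 20), rep(500, 20), rep(3500, 20),
                    rep(c("W", "C"), each = 10))
  b2 <- windowed_bias(coverage_from_fragments(fr2, g), o,
                      radius = 1000, window = 100, step = 100)
  expect_true(all(b2 == 0))

  empty <- coverage_from_fragments(
    make_frags(g, character(), numeric(), numeric(), character()), g)
  b0 <- windowed_bias(empty, o, radius = 1000, window = 100, step = 100)
  expect_true(all(is.nan(b0)))
})

test_that("windowed bias equals an independent double-loop implementation exactly", {
  g <- toy_genome(c(chrI = 6000, chrII = 6000))
  o <- origin_set(c("chrI", "chrII"), c(3000, 2500), c("o1", "o2"), g)
  set.seed(53)
  fr <- rbind(random_frags(g, 400, chrom = "chrI"),
              random_frags(g, 350, chrom = "chrII"))
  attr(fr, "sample_id") <- "s"; attr(fr, "mark") <- "BrdU"
  attr(fr, "genotype_label") <- "WT"
  class(fr) <- c("fragment_set", "data.frame")
  cov <- coverage_from_fragments(fr, g)
  got <- windowed_bias(cov, o, radius = 1500, window = 100, step = 50)
  want <- naive_windowed_bias(cov, o, radius = 1500, window = 100, step = 50)
  expect_equal(got, want, tolerance = 0)
  # windows sliding past the chromosome end are NaN, not clamped
  got_edge <- windowed_bias(cov, o, radius = 4000, window = 100, step = 500)
  expect_true(all(is.nan(got_edge["o2", as.numeric(colnames(got_edge)) > 3400])))
})

test_that("finite bias values always lie in [-1, 1] on random fragment sets", {
  set.seed(61)
  for (k in 1:5) {
    g <- toy_genome(c(chrX = 5000))
    o <- origin_set("chrX", 2500, "o", g)
    fr <- random_frags(g, sample(c(5, 50, 500), 1), chrom = "chrX")
    b <- windowed_bias(coverage_from_fragments(fr, g), o, radius = 2000,
                       window = sample(c(25, 100), 1), step = 37)
    fin <- b[is.finite(b)]
    expect_true(all(fin >= -1 & fin <= 1))
  }
})

test_that("BrdU subtraction is elementwise with NaN propagation and congruence checks", {
  m1 <- matrix(c(0.5, NaN, 0.2, -0.1), 2, 2,
               dimnames = list(c("a", "b"), c(-50, 50)))
  m2 <- matrix(c(0.1, 0.2, NaN, -0.3), 2, 2,
               dimnames = list(c("a", "b"), c(-50, 50)))
  d <- subtract_brdu(m1, m2)
  expect_equal(d["a", "-50"], 0.4)
  expect_equal(d["b", "50"], 0.2)
  expect_true(is.nan(d["b", "-50"]) && is.nan(d["a", "50"]))
  expect_true(all(subtract_brdu(m1, m1)[is.finite(m1)] == 0))
  expect_error(subtract_brdu(m1, m2[, 1, drop = FALSE]), "not congruent")
})

test_that("aggregation reports mean, 2xSE halfwidth and finite-n per bin", {
  m <- matrix(c(0.2, 0.4, NaN, NaN, 0.3, NaN), nrow = 2, byrow = FALSE,
              dimnames = list(c("a", "b"), c(-100, 0, 100)))
  attr(m, "bin_centers") <- c(-100, 0, 100)
  agg <- aggregate_bias(m)
  expect_equal(agg$mean[1], 0.3)
  expect_equal(agg$halfwidth[1], 2 * sd(c(0.2, 0.4)) / sqrt(2))
  expect_true(is.nan(agg$mean[2]))          # all-NaN column
  expect_equal(agg$n, c(2, 0, 1))
  expect_true(is.nan(agg$mean[3]))          # single value: below the n >= 2 floor
})

test_that("side-resolved folding excludes the origin-proximal zone and flags NaN sides", {
  centers <- seq(-1000, 1000, by = 100)
  m <- matrix(rep(ifelse(centers > 0, 0.6, ifelse(centers < 0, -0.6, 0)),
                  each = 3), nrow = 3,
              dimnames = list(c("a", "b", "c"), centers))
  attr(m, "bin_centers") <- centers
  m["c", ] <- 0
  sr <- side_resolved_bias(m, exclude = 300)
  expect_equal(sr$folded[sr$origin_id == "a"], 0.6)
  expect_equal(sr$folded[sr$origin_id == "c"], 0)

  m["b", centers < -300] <- NaN
  expect_warning(sr2 <- side_resolved_bias(m, exclude = 300), "dropped")
  expect_false("b" %in% sr2$origin_id)
})

test_that("heatmap rows sort by descending folded bias with stable id tie-break", {
  s <- small_sim(genotype_params("g", 0.75, 1), n_origins = 3, cells = 15,
                 seed = 402)
  prof <- bias_profile(s$covs$g.H3K4me3, s$covs$g.BrdU, s$geo$origins,
                       radius = 3000, replicated_halfwidth = 5000)
  prof$folded$folded <- c(0.1, 0.5, -0.2)   # force known folded values
  hm <- bias_heatmap_matrix(prof)
  expect_equal(rownames(hm),
               prof$folded$origin_id[c(2, 1, 3)])
  prof$folded$folded <- c(0.4, 0.4, 0.4)    # ties: stable by origin id
  hm2 <- bias_heatmap_matrix(prof)
  expect_equal(rownames(hm2), sort(prof$folded$origin_id))
  # round trip through the matrix TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(hm, path)
  expect_equal(read_matrix_tsv(path), hm, ignore_attr = "bin_centers")
})

test_that("normalized profiles are antisymmetric around the origin in expectation", {
  s <- small_sim(genotype_params("g", 0.7, 1), n_origins = 16, cells = 80,
                 reads = 0.4, brdu = 1, seed = 501)
  prof <- bias_profile(s$covs$g.H3K4me3, s$covs$g.BrdU, s$geo$origins,
                       replicated_halfwidth = s$cfg$replicated_halfwidth)
  resid <- prof$folded$left + prof$folded$right   # 0 under antisymmetry
  se <- sd(resid) / sqrt(length(resid))
  expect_lt(abs(mean(resid)), 3 * se + 1e-3)
})

test_that("bias profiles refuse mismatched genotypes unless overridden", {
  s <- small_sim(list(genotype_params("a", 0.5, 1), genotype_params("b", 0.5, 1)),
                 n_origins = 2, cells = 5, reads = 0.1, brdu = 0.2, seed = 88)
  expect_error(bias_profile(s$covs$a.H3K4me3, s$covs$b.BrdU, s$geo$origins,
                            radius = 2000), "mismatch")
  expect_s3_class(bias_profile(s$covs$a.H3K4me3, s$covs$b.BrdU, s$geo$origins,
                               radius = 2000, allow_mismatch = TRUE),
                  "bias_profile")
})
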