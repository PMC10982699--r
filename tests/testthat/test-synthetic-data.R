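geo1 <- sim_genome(n_origins = 1, origin_spacing = 20000, margin = 10000)

test_that("nucleosome slots sit at (k+1/2)*spacing strictly inside the fork reach", {
  cfg <- simulation_config(geo1$genome, geo1$origins,
                           replicated_halfwidth = 400, nucleosome_spacing = 160)
  pos <- geo1$origins$pos[1]
  expect_equal(place_nucleosomes(cfg, pos) - pos, c(-240, -80, 80, 240))

  cfg2 <- simulation_config(geo1$genome, geo1$origins,
                            replicated_halfwidth = 70, nucleosome_spacing = 160)
  expect_length(place_nucleosomes(cfg2, pos), 0L)

  expect_error(simulation_config(geo1$genome, geo1$origins,
                                 nucleosome_spacing = 0), "spacing")
})

test_that("fork geometry maps daughters to genomic strands and mirrors across the origin", {
  expect_equal(nascent_strand_of("leading", "right"), "W")
  expect_equal(nascent_strand_of("leading", "left"), "C")
  expect_equal(nascent_strand_of("lagging", "right"), "C")
  expect_equal(nascent_strand_of("lagging", "left"), "W")
  expect_error(nascent_strand_of("leading", "up"), "side")
  expect_error(nascent_strand_of("top", "left"), "daughter")
})

test_that("segregation deposits exactly one tetramer per daughter and honors boundary parameters", {
  centers <- seq(100, 2000, by = 160)
  set.seed(1)
  dep <- segregate_histones(centers, "right", genotype_params("x", 1, 1))
  expect_equal(nrow(dep), 2L * length(centers))
  # conservation: per center, one leading and one lagging tetramer
  tally <- table(dep$center, dep$daughter)
  expect_true(all(tally == 1))
  expect_true(all(dep$histone_class[dep$daughter == "leading"] == "parental"))
  expect_true(all(dep$histone_class[dep$daughter == "lagging"] == "new"))

  dep0 <- segregate_histones(centers, "left", genotype_params("x", 0.5, 0))
  expect_true(all(dep0$histone_class == "new"))
})

test_that("empirical leading-parental fraction matches r*p within 3 binomial SE at 1e5 centers", {
  n <- 1e5; p <- 0.8; r <- 1
  set.seed(123)
  dep <- segregate_histones(seq_len(n), "right", genotype_params("x", p, r))
  lead_par <- mean(dep$histone_class[dep$daughter == "leading"] == "parental")
  se <- sqrt(r * p * (1 - r * p) / n)
  expect_lt(abs(lead_par - r * p), 3 * se)

  # population tallies are the pooled-cells equivalent of the same draw
  set.seed(124)
  pp <- espanr:::segregate_population(seq_len(2000), "right",
                                      genotype_params("y", 0.6, 0.7), cells = 50)
  # parental + new per center and daughter always sums to the cell count
  agg <- aggregate(n_tetramers ~ center + daughter, data = pp, FUN = sum)
  expect_true(all(agg$n_tetramers == 50))
  frac_lead <- sum(pp$n_tetramers[pp$daughter == "leading" &
                                  pp$histone_class == "parental"]) / (2000 * 50)
  se2 <- sqrt(0.7 * 0.6 * (1 - 0.42) / (2000 * 50))
  expect_lt(abs(frac_lead - 0.42), 3 * se2)
})

test_that("emitted fragments follow the deposition strands and depth parameters", {
  geo <- sim_genome(n_origins = 2, origin_spacing = 20000, margin = 10000)
  cfg <- simulation_config(geo$genome, geo$origins, cells_per_sample = 20,
                           reads_per_nucleosome = 1, brdu_reads_per_bp = 0.5,
                           seed = 5)
  params <- genotype_params("allLead", p_lead = 1, r_recycle = 1)
  set.seed(11)
  dep <- espanr:::build_depositions(cfg, params)
  frags <- emit_fragments(dep, cfg, "H3K4me3", params)
  # with p_lead = 1, r = 1 every parental fragment right of its origin is W, left is C
  origin_of <- geo$origins$pos[ifelse(frags$start < 20000, 1, 2)]
  mid <- (frags$start + frags$end) / 2
  expect_true(all(frags$strand[mid > origin_of] == "W"))
  expect_true(all(frags$strand[mid < origin_of] == "C"))

  # reads_per_nucleosome = 0 gives an empty set
  cfg0 <- simulation_config(geo$genome, geo$origins, reads_per_nucleosome = 0,
                            cells_per_sample = 5)
  expect_equal(nrow(emit_fragments(dep, cfg0, "H3K4me3", params)), 0L)

  expect_error(emit_fragments(dep, cfg, "H3K27me3", params), "arg")
})

test_that("BrdU input is strand-symmetric and Watson thinning scales W counts", {
  geo <- sim_genome(n_origins = 4, origin_spacing = 25000, margin = 12000)
  cfg <- simulation_config(geo$genome, geo$origins, brdu_reads_per_bp = 2, seed = 5)
  params <- genotype_params("WT", 0.5, 1)
  set.seed(21)
  brdu <- emit_fragments(NULL, cfg, "BrdU", params)
  nW <- sum(brdu$strand == "W"); nC <- sum(brdu$strand == "C")
  expect_lt(abs(nW - nC) / sqrt(nW + nC), 3)   # Poisson symmetry

  cfg8 <- simulation_config(geo$genome, geo$origins, brdu_reads_per_bp = 2,
                            strand_recovery_w = 0.8, seed = 5)
  set.seed(21)
  brdu8 <- emit_fragments(NULL, cfg8, "BrdU", params)
  nW8 <- sum(brdu8$strand == "W"); nC8 <- sum(brdu8$strand == "C")
  expect_lt(abs(nW8 / nC8 - 0.8), 3 * 0.8 * sqrt(1 / nW8 + 1 / nC8))
})

test_that("simulated experiments are deterministic under a fixed seed", {
  g <- genotype_params("g1", 0.7, 0.9)
  s1 <- small_sim(g, n_origins = 3, cells = 10, seed = 314)
  s2 <- small_sim(g, n_origins = 3, cells = 10, seed = 314)
  expect_identical(s1$samples, s2$samples)
  s3 <- small_sim(g, n_origins = 3, cells = 10, seed = 315)
  expect_false(identical(s1$samples, s3$samples))
})

test_that("the manifest records the closed-form expectations of each genotype", {
  gts <- list(genotype_params("sym", 0.5, 1),
              genotype_params("lead8", 0.8, 1),
              genotype_params("weak", 0.5, 0.4))
  s <- small_sim(gts, n_origins = 2, cells = 5, reads = 0.1, brdu = 0.05)
  m <- s$manifest
  expect_equal(m$expected_parental_bias, c(0, 0.6, 0))
  expect_equal(m$expected_density_leading, c(0.5, 0.8, 0.2))
  expect_equal(m$expected_density_lagging, c(0.5, 0.2, 0.2))
  # new-histone bias r(1-2p)/(2-r)
  expect_equal(m$expected_new_bias, c(0, -0.6, 0))
})

test_that("a bias radius beyond the fork reach raises a recorded warning", {
  geo <- sim_genome(n_origins = 2, origin_spacing = 25000, margin = 12000)
  cfg <- simulation_config(geo$genome, geo$origins, replicated_halfwidth = 2000,
                           cells_per_sample = 5, reads_per_nucleosome = 0.1,
                           brdu_reads_per_bp = 0.05, seed = 2)
  expect_warning(
    res <- simulate_experiment(cfg, genotype_params("WT", 0.5, 1),
                               marks = "H3K4me3", analysis_radius = 10000),
    "exceeds")
  expect_match(res$manifest$note[1], "exceeds")
})

test_that("left- and right-side strand distributions mirror each other", {
  g <- genotype_params("m", 0.7, 1)
  s <- small_sim(g, n_origins = 8, cells = 60, reads = 0.4, seed = 77)
  fr <- s$samples$m.H3K4me3
  origins <- s$geo$origins
  idx <- findInterval((fr$start + fr$end) / 2,
                      origins$pos - s$cfg$replicated_halfwidth)
  side <- ifelse((fr$start + fr$end) / 2 > origins$pos[idx], "right", "left")
  fW_right <- mean(fr$strand[side == "right"] == "W")
  fC_left <- mean(fr$strand[side == "left"] == "C")
  n <- min(sum(side == "right"), sum(side == "left"))
  expect_lt(abs(fW_right - fC_left), 4 * sqrt(2 * 0.7 * 0.3 / n))
})
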