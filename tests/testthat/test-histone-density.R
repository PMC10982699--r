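test_that("the BrdU coefficient is exact under proportionality and zero without signal", {
  g <- toy_genome(c(chrI = 12000))
  set.seed(71)
  brdu_fr <- random_frags(g, 800, min_len = 100, max_len = 200)
  brdu <- coverage_from_fragments(brdu_fr, g)
  # doubling every fragment doubles coverage exactly -> c = 2
  esp_fr <- make_frags(g, rep(brdu_fr$chrom, 2), rep(brdu_fr$start, 2),
                       rep(brdu_fr$end, 2), rep(brdu_fr$strand, 2),
                       mark = "H3K4me3")
  esp <- coverage_from_fragments(esp_fr, g)
  for (cl in c("leading", "lagging")) {
    co <- fit_brdu_coefficient(esp, brdu, "chrI", 6000, cl)
    expect_equal(as.numeric(co), 2)
    expect_gt(attr(co, "n_bins"), 30)
  }
  empty <- coverage_from_fragments(
    make_frags(g, character(), numeric(), numeric(), character(),
               mark = "H3K4me3"), g)
  expect_equal(as.numeric(fit_brdu_coefficient(empty, brdu, "chrI", 6000, "leading")), 0)
  expect_warning(
    co_na <- fit_brdu_coefficient(brdu, empty, "chrI", 6000, "leading"),
    "unreplicated")
  expect_true(is.na(co_na))
})

test_that("the coefficient equals the closed form sum(e*b)/sum(b^2) on random fixtures", {
  set.seed(73)
  for (k in 1:4) {
    g <- toy_genome(c(chrI = 12000))
    brdu <- coverage_from_fragments(random_frags(g, 600), g)
    esp <- coverage_from_fragments(random_frags(g, sample(100:700, 1),
                                                mark = "H3K4me3"), g)
    for (cl in c("leading", "lagging")) {
      got <- as.numeric(fit_brdu_coefficient(esp, brdu, "chrI", 6000, cl))
      want <- naive_coefficient(esp, brdu, "chrI", 6000, cl)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("densities scale linearly with eSPAN coverage", {
  g <- toy_genome(c(chrI = 12000))
  set.seed(79)
  brdu <- coverage_from_fragments(random_frags(g, 500), g)
  esp_fr <- random_frags(g, 400, mark = "H3K4me3")
  esp <- coverage_from_fragments(esp_fr, g)
  esp3_fr <- make_frags(g, rep(esp_fr$chrom, 3), rep(esp_fr$start, 3),
                        rep(esp_fr$end, 3), rep(esp_fr$strand, 3),
                        mark = "H3K4me3")
  esp3 <- coverage_from_fragments(esp3_fr, g)
  c1 <- as.numeric(fit_brdu_coefficient(esp, brdu, "chrI", 6000, "leading"))
  c3 <- as.numeric(fit_brdu_coefficient(esp3, brdu, "chrI", 6000, "leading"))
  expect_equal(c3, 3 * c1, tolerance = 1e-12)
})

test_that("density tables require matched per-genotype BrdU samples", {
  s <- small_sim(list(genotype_params("a", 0.5, 1), genotype_params("b", 0.8, 1)),
                 n_origins = 4, cells = 20, seed = 83)
  tab <- density_table(list(
    list(genotype = "a", espan = s$covs$a.H3K4me3, brdu = s$covs$a.BrdU),
    list(genotype = "b", espan = s$covs$b.H3K4me3, brdu = s$covs$b.BrdU)),
    s$geo$origins)
  expect_equal(nrow(tab), 4 * 2 * 2)   # origins x strand classes x genotypes
  expect_true(all(tab$density >= 0))

  expect_error(density_table(list(
    list(genotype = "a", espan = s$covs$a.H3K4me3, brdu = s$covs$a.BrdU),
    list(genotype = "b", espan = s$covs$b.H3K4me3, brdu = s$covs$a.BrdU)),
    s$geo$origins), "share a BrdU sample")

  expect_error(density_table(list(
    list(genotype = "a", espan = s$covs$a.H3K4me3)),
    s$geo$origins), "missing a BrdU")
})

test_that("fold changes divide by the matched reference measurement", {
  tab <- data.frame(
    origin_id = rep(c("o1", "o2"), 2),
    strand_class = "leading",
    genotype = rep(c("WT", "mut"), each = 2),
    density = c(0.6, 0, 0.3, 0.4),
    n_bins = 40, fold_change = NA_real_)
  class(tab) <- c("density_table", "data.frame")
  expect_warning(fc <- fold_change(tab, "WT"), "zero reference")
  expect_equal(fc$fold_change[fc$genotype == "mut" & fc$origin_id == "o1"], 0.5)
  expect_true(is.nan(fc$fold_change[fc$genotype == "mut" & fc$origin_id == "o2"]))
  expect_equal(fc$fold_change[fc$genotype == "WT" & fc$origin_id == "o1"], 1)
  expect_error(fold_change(tab, "nope"), "not in table")

  fc$density[fc$genotype == "mut"] <- fc$density[fc$genotype == "WT"]
  fc2 <- suppressWarnings(fold_change(fc, "WT"))
  expect_true(all(fc2$fold_change[is.finite(fc2$fold_change)] == 1))
})

test_that("Welch comparisons behave at the boundaries and reject tiny groups", {
  tab <- data.frame(
    origin_id = rep(paste0("o", 1:5), 2), strand_class = "leading",
    genotype = rep(c("a", "b"), each = 5),
    density = rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 2),
    n_bins = 40, fold_change = NA_real_)
  class(tab) <- c("density_table", "data.frame")
  r <- compare_density(tab, "a", "b", "leading")
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$n_a, 5)
  expect_error(compare_density(tab[tab$genotype == "a", ], "a", "b", "leading"),
               ">= 2 origins")
})

test_that("the t-test separates shifted density distributions decisively", {
  set.seed(97)
  a <- rnorm(162, 0.5, 0.05); b <- rnorm(162, 0.2, 0.05)
  expect_lt(t.test(a, b)$p.value, 1e-6)
})

test_that("long-format export is one row per measurement and round-trips", {
  s <- small_sim(genotype_params("WT", 0.5, 1), n_origins = 5, cells = 15,
                 seed = 89)
  tab <- density_table(list(
    list(genotype = "WT", espan = s$covs$WT.H3K4me3, brdu = s$covs$WT.BrdU)),
    s$geo$origins)
  tab <- fold_change(tab, "WT")
  path <- withr::local_tempfile(fileext = ".tsv")
  density_violin_export(tab, path)
  back <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(back), 5 * 2)
  expect_equal(back$density, tab$density)

  empty <- tab[0, ]
  class(empty) <- c("density_table", "data.frame")
  density_violin_export(empty, path)
  expect_equal(length(readLines(path)), 1L)   # header only
})

test_that("parental plus new-histone density is conserved across genotypes", {
  gts <- list(genotype_params("WT", 0.5, 1), genotype_params("mut", 0.85, 0.6))
  s <- small_sim(gts, marks = c("H3K4me3", "H3K56ac"), n_origins = 10,
                 cells = 120, reads = 0.4, brdu = 1.5, seed = 109)
  totals <- sapply(c("WT", "mut"), function(g) {
    tabs <- lapply(c("H3K4me3", "H3K56ac"), function(mk) {
      density_table(list(list(genotype = g,
                              espan = s$covs[[paste0(g, ".", mk)]],
                              brdu = s$covs[[paste0(g, ".BrdU")]])),
                    s$geo$origins)
    })
    sapply(c("leading", "lagging"), function(cl) {
      mean(tabs[[1]]$density[tabs[[1]]$strand_class == cl]) +
        mean(tabs[[2]]$density[tabs[[2]]$strand_class == cl])
    })
  })
  # per strand class, parental + new read mass is capacity: equal across genotypes
  expect_lt(abs(totals["leading", "WT"] / totals["leading", "mut"] - 1), 0.05)
  expect_lt(abs(totals["lagging", "WT"] / totals["lagging", "mut"] - 1), 0.05)
})
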