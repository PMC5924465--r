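mold <- get_code_table("mold")

test_that("base composition is exact on toy sequences", {
  expect_equal(composition(MitoGenome("a", "ATAT", TRUE))$AT_percent, 100)
  comp <- composition(MitoGenome("b", "ACGT", TRUE))
  expect_true(all(comp$percent[c("A", "C", "G", "T")] == 25))
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)
})

test_that("generated genomes hit the requested AT content", {
  for (seed in 1:3) {
    gx <- generate_genome(genome_spec(seed = seed), paste0("c", seed))
    comp <- composition(gx$genome)
    expect_lt(abs(comp$AT_percent - 84), 1.5)
    expect_gt(comp$T_percent, 50)
  }
})

test_that("codon usage separates starts, stops and internal codons", {
  g <- MitoGenome("m", "ATGAAATAA", FALSE)
  ann <- AnnotationSet("m", list(GeneFeature("nad3", 0, 9, "+", "protein")))
  cu <- codon_usage(ann, g, mold)
  expect_equal(unname(cu$starts["ATG"]), 1L)
  expect_equal(unname(cu$stops["TAA"]), 1L)
  expect_equal(cu$codon$percent[cu$codon$codon == "AAA"], 100)
  expect_equal(cu$total_codons, 1L)
})

test_that("codon counts add up across genes and match feature lengths", {
  gx <- generate_genome(compact_spec(19), "cu")
  cu <- codon_usage(gx$annotation, gx$genome, mold)
  expect_equal(sum(cu$codon$percent), 100, tolerance = 1e-9)
  led <- gx$ledger$features
  prot <- led[led$kind == "protein", ]
  total_codons <- sum((prot$end - prot$start) %/% 3L)
  expect_equal(cu$total_codons + sum(cu$starts) + sum(cu$stops),
               total_codons)
  # incomplete stops get their own category
  g2 <- MitoGenome("ic", "ATGAAAAAGT", FALSE)
  ann2 <- AnnotationSet("ic", list(
    GeneFeature("nad2", 0, 10, "+", "protein", has_incomplete_stop = TRUE)))
  cu2 <- codon_usage(ann2, g2, mold)
  expect_equal(unname(cu2$stops["T."]), 1L)
})

test_that("non-coding accounting is exact on a constructed layout", {
  set.seed(4)
  g <- random_genome("toy", 1000)
  ann <- AnnotationSet("toy", list(
    GeneFeature("cox1", 0, 900, "+", "protein"),
    GeneFeature("urf1", 920, 980, "+", "URF")))
  ncp <- summarize_noncoding(ann, g)
  expect_equal(ncp$nc_without_urfs, 40L)   # URF counted as coding
  expect_equal(ncp$nc_with_urfs, 100L)     # URF counted as non-coding
  expect_equal(ncp$longest_with$bp, 100L)
  expect_equal(ncp$longest_with$flanks, c("cox1", "cox1"))
  expect_equal(ncp$longest_without$bp, 20L)

  # wall-to-wall coverage leaves nothing
  full <- AnnotationSet("toy", list(GeneFeature("cox1", 0, 1000)))
  ncp2 <- summarize_noncoding(full, g)
  expect_equal(ncp2$nc_with_urfs, 0L)
  expect_equal(ncp2$nc_without_urfs, 0L)

  # single feature on a circle: one tract wrapping the origin
  one <- AnnotationSet("toy", list(GeneFeature("cox1", 100, 200)))
  ncp3 <- summarize_noncoding(one, g)
  expect_equal(ncp3$nc_with_urfs, g$length - 100L)
  expect_equal(ncp3$longest_with$bp, 900L)   # one tract wrapping the origin
  expect_equal(ncp3$n_nc_gt_with, 1L)
})

test_that("NC conservation holds across synthetic layouts", {
  for (seed in 21:24) {
    gx <- generate_genome(compact_spec(seed), "nc")
    ncp <- summarize_noncoding(gx$annotation, gx$genome)
    led <- gx$ledger$features
    urf_bp <- sum(led$end[led$kind == "URF"] - led$start[led$kind == "URF"])
    expect_equal(ncp$nc_with_urfs, ncp$nc_without_urfs + urf_bp)
    coding_bp <- sum(led$end - led$start)
    expect_equal(coding_bp + ncp$nc_without_urfs, gx$genome$length)
  }
})

test_that("non-coding proportions reproduce the published display values", {
  expect_equal(round(nc_percent(930, 11574), 1), 8.0)
  expect_equal(round(nc_percent(429, 11016), 1), 3.9)
  expect_equal(nc_percent(0, 100), 0)
})

test_that("the size~NC correlation matches a two-pass computation", {
  nc <- published_nc_stats()
  r <- size_nc_correlation(nc[, c("genome_length", "nc_with_urfs")])
  expect_equal(r, brute_pearson(nc$genome_length, nc$nc_with_urfs),
               tolerance = 1e-12)
  expect_equal(round(r, 2), 0.99)
  # perfectly linear points
  expect_equal(size_nc_correlation(cbind(1:5, 2 * (1:5) + 3)), 1)
  # random points vs the textbook formula
  set.seed(12)
  x <- rnorm(4); y <- rnorm(4)
  expect_equal(size_nc_correlation(cbind(x, y)), brute_pearson(x, y),
               tolerance = 1e-12)
  # affine rescaling leaves r untouched
  expect_equal(size_nc_correlation(cbind(10 + 3 * x, y)),
               size_nc_correlation(cbind(x, y)), tolerance = 1e-12)
  expect_error(size_nc_correlation(cbind(rep(1, 4), y)), "constant")
})

test_that("repeat hits equal the brute-force oracle on random linear strings", {
  set.seed(31)
  for (i in 1:25) {
    L <- sample(80:300, 1)
    # low alphabet diversity so repeats actually occur
    sq <- paste(sample(c("A", "T"), L, TRUE, prob = c(0.35, 0.65)),
                collapse = "")
    g <- MitoGenome(paste0("r", i), sq, is_circular = FALSE)
    min_unit <- sample(6:10, 1)
    got <- find_perfect_repeats(g, min_unit = min_unit)
    want <- brute_repeats(sq, min_unit)
    got_map <- lapply(got, `[[`, "positions")
    names(got_map) <- vapply(got, `[[`, "", "unit")
    expect_equal(got_map[order(names(got_map))],
                 want[order(names(want))])
  }
})

test_that("low-complexity repeats are recognized and filtered", {
  g <- MitoGenome("polyA", strrep("A", 100), is_circular = TRUE)
  expect_length(find_perfect_repeats(g, min_unit = 20,
                                     filter_low_complexity = TRUE), 0L)
  hits <- find_perfect_repeats(g, min_unit = 20)
  expect_true(all(vapply(hits, `[[`, FALSE, "low_complexity")))
  # a genome with no repeated substring of the minimum size
  g2 <- MitoGenome("uniq", "ACGTACGGTTCAGACCTGAAGGCTAATCCGT", FALSE)
  expect_length(find_perfect_repeats(g2, min_unit = 12), 0L)
})

test_that("a planted 84 bp duplication is found with its exact unit", {
  gx <- generate_genome(genome_spec(
    seed = 11, planted_repeat = list(unit_len = 84, separation = 8200)),
    "rep84")
  hits <- find_perfect_repeats(gx$genome, min_unit = 21,
                               filter_low_complexity = TRUE)
  expect_gte(length(hits), 1L)
  expect_equal(hits[[1]]$unit_length, 84L)   # sorted longest-first
  expect_equal(hits[[1]]$positions, gx$ledger$planted_repeat$positions)
  expect_equal(hits[[1]]$separation, gx$ledger$planted_repeat$separation)
  expect_false(hits[[1]]$low_complexity)
})
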