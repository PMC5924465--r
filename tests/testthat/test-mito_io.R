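test_that("FASTA reading handles minimal, empty and multi-record files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "ATGC"), f)
  gs <- read_fasta(f)
  expect_length(gs, 1L)
  expect_equal(gs[[1]]$length, 4L)
  expect_false(gs[[1]]$is_circular)

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_length(read_fasta(empty), 0L)

  writeLines(c(">g1 circular", "acgt", ">g2", "ttaa"), f)
  gs <- read_fasta(f)
  expect_equal(gs[[1]]$sequence, "ACGT")
  expect_true(gs[[1]]$is_circular)
  expect_equal(gs[[2]]$sequence, "TTAA")

  writeLines(c(">bad", "ACGX"), f)
  expect_error(read_fasta(f), "illegal character")
})

test_that("FASTA write/read round trip is the identity", {
  set.seed(42)
  f <- withr::local_tempfile(fileext = ".fa")
  gs <- lapply(1:5, function(i) random_genome(paste0("g", i), 50 + 37 * i,
                                              circular = i %% 2 == 0))
  write_fasta(gs, f)
  back <- read_fasta(f)
  expect_equal(lapply(back, unclass), lapply(gs, unclass))
})

test_that("GenBank locations convert exactly between 1-based and internal", {
  # plain span
  expect_equal(ctenomito:::parse_gb_location("1..9", 100),
               list(start = 0L, end = 9L, strand = "+"))
  # origin-spanning join on a 100 bp circle
  loc <- ctenomito:::parse_gb_location("join(95..100,1..10)", 100)
  expect_equal(loc$start, 94L)
  expect_equal(loc$end, 110L)
  expect_error(ctenomito:::parse_gb_location("order(1..5)", 100),
               "unresolvable")
})

test_that("GenBank round trip preserves sequence and coordinates exactly", {
  set.seed(7)
  g <- random_genome("toy", 200)
  ann <- AnnotationSet("toy", list(
    GeneFeature("cox1", 10, 100, "+", "protein"),
    GeneFeature("rns", 120, 180, "+", "rRNA")))
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, ann, f)
  back <- read_genbank(f)
  expect_identical(back$genome$sequence, g$sequence)
  expect_true(back$genome$is_circular)
  expect_equal(lapply(back$annotation$features, unclass),
               lapply(ann$features, unclass))

  # origin-spanning feature emitted as join() and re-parsed identically;
  # the wrapped subsequence equals the two concatenated pieces
  ann2 <- AnnotationSet("toy", list(GeneFeature("cob", 180, 230, "+",
                                                "protein")))
  write_genbank(g, ann2, f)
  back2 <- read_genbank(f)
  expect_true(any(grepl("join(181..200,1..30)", readLines(f), fixed = TRUE)))
  f2 <- back2$annotation$features[[1]]
  expect_equal(c(f2$start, f2$end), c(180L, 230L))
  expect_identical(extract_feature_sequence(back2$genome, f2),
                   paste0(substr(g$sequence, 181, 200),
                          substr(g$sequence, 1, 30)))

  # empty annotation still yields a valid flatfile
  write_genbank(g, AnnotationSet("toy", list()), f)
  expect_length(read_genbank(f)$annotation$features, 0L)
})

test_that("incomplete stop codons survive a GenBank round trip", {
  g <- MitoGenome("v", strrep("ACGT", 30), is_circular = TRUE)
  ann <- AnnotationSet("v", list(
    GeneFeature("nad2", 0, 50, "+", "protein", has_incomplete_stop = TRUE)))
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, ann, f)
  expect_true(read_genbank(f)$annotation$features[[1]]$has_incomplete_stop)
})

test_that("GenBank and FASTA round trips are lossless over random genomes", {
  set.seed(11)
  fgb <- withr::local_tempfile(fileext = ".gb")
  ffa <- withr::local_tempfile(fileext = ".fa")
  for (i in 1:200) {
    L <- sample(60:400, 1)
    g <- random_genome(paste0("r", i), L, circular = i %% 2 == 0)
    s <- sample(0:(L - 20), 1)
    e <- if (g$is_circular) s + sample(10:(L - 1), 1)
         else sample((s + 10):L, 1)
    feats <- list(GeneFeature("cox1", s, e, "+", "protein"))
    write_genbank(g, AnnotationSet(g$id, feats), fgb)
    back <- read_genbank(fgb)
    expect_identical(back$genome$sequence, g$sequence)
    expect_equal(lapply(back$annotation$features, unclass),
                 lapply(feats, unclass))
    write_fasta(g, ffa)
    expect_identical(read_fasta(ffa)[[1]]$sequence, g$sequence)
  }
})

test_that("written GenBank is parsed identically by an independent reader", {
  set.seed(3)
  g <- random_genome("xcheck", 150)
  ann <- AnnotationSet("xcheck", list(
    GeneFeature("cox1", 5, 80, "+", "protein"),
    GeneFeature("rnl", 90, 140, "+", "rRNA")))
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, ann, f)
  script <- paste(
    "import sys",
    "from Bio import SeqIO",
    "r = SeqIO.read(sys.argv[1], 'genbank')",
    "print(str(r.seq))",
    "for ft in r.features:",
    "    if ft.type in ('CDS', 'rRNA'):",
    "        print(ft.qualifiers['gene'][0], int(ft.location.start),",
    "              int(ft.location.end))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(f)),
                 stdout = TRUE, stderr = FALSE)
  expect_identical(out[1], g$sequence)
  expect_identical(out[2], "cox1 5 80")
  expect_identical(out[3], "rnl 90 140")
})

test_that("feature sequences wrap, reverse-complement and respect topology", {
  circ <- MitoGenome("c", "ACGT", is_circular = TRUE)
  expect_identical(extract_feature_sequence(
    circ, GeneFeature("x", 2, 6, "+", "protein")), "GTAC")
  lin <- MitoGenome("l", "ACGT", is_circular = FALSE)
  expect_identical(extract_feature_sequence(
    lin, GeneFeature("x", 0, 4, "-", "protein")), "ACGT")  # palindrome
  expect_error(extract_feature_sequence(
    lin, GeneFeature("x", 3, 5, "+", "protein")), "linear")
})

test_that("annotation sets reject duplicate canonical labels and stay sorted", {
  expect_error(AnnotationSet("g", list(
    GeneFeature("cox1", 0, 10), GeneFeature("cox1", 20, 30))),
    "duplicate canonical")
  ann <- AnnotationSet("g", list(
    GeneFeature("cob", 50, 80), GeneFeature("cox1", 0, 10)))
  expect_equal(vapply(ann$features, `[[`, "", "label"), c("cox1", "cob"))
})
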