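mold <- get_code_table("mold")
pbachei <- get_code_table("pbachei")

test_that("translation follows the mold code and its TGA->Ser variant", {
  expect_identical(translate_seq("TGA", mold), "W")
  expect_identical(translate_seq("TGA", pbachei), "S")
  expect_identical(translate_seq("ATG", mold), "M")
  expect_identical(translate_seq("ATG", pbachei), "M")
  expect_identical(translate_seq("TAATAG", mold), "**")
  expect_identical(translate_seq("ATGAA", mold), "MX")  # trailing partial
  expect_error(translate_seq("ATN", mold), "position 3")
})

test_that("the two code tables differ only at TGA", {
  set.seed(5)
  for (i in 1:25) {
    n_codons <- sample(5:40, 1)
    sq <- paste(sample(c("A", "C", "G", "T"), 3 * n_codons, TRUE),
                collapse = "")
    a <- strsplit(translate_seq(sq, mold), "")[[1]]
    b <- strsplit(translate_seq(sq, pbachei), "")[[1]]
    codons <- substring(sq, seq(1, 3 * n_codons, 3), seq(3, 3 * n_codons, 3))
    expect_identical(a != b, codons == "TGA")
  }
})

test_that("ORF scanning finds minimal and absent ORFs", {
  g <- MitoGenome("m", "ATGAAATAA", is_circular = FALSE)
  orfs <- find_orfs(g, mold, min_len = 9)
  expect_length(orfs, 1L)
  expect_equal(orfs[[1]]$start, 0L)
  expect_equal(orfs[[1]]$end, 9L)
  expect_identical(orfs[[1]]$protein, "MK")
  expect_identical(orfs[[1]]$stop_kind, "TAA")

  nostart <- MitoGenome("n", "CCCCCCCCCTAACCC", is_circular = FALSE)
  expect_length(find_orfs(nostart, mold, min_len = 3), 0L)
})

test_that("an origin-spanning planted gene is recovered with exact coordinates", {
  # rotate the circle so the origin falls inside cox1
  gx <- generate_genome(compact_spec(31, origin_shift = 300L), "oswrap")
  led <- gx$ledger$features
  cox1 <- led[led$label == "cox1", ]
  expect_true(cox1$end > gx$genome$length)  # really spans the origin
  orfs <- find_orfs(gx$genome, mold, min_len = 100)
  L <- gx$genome$length
  hit <- Filter(function(o)
    (o$end %% L) == (cox1$end %% L) &&
      (cox1$start %% L) %in% (o$candidate_starts %% L), orfs)
  expect_gte(length(hit), 1L)
  # and the full annotator places the gene at the planted coordinates
  res <- annotate_genome(gx$genome, list(proteins = gx$ledger$proteins,
                                         rnas = gx$ledger$rnas))
  f <- Filter(function(x) x$label == "cox1", res$annotation$features)[[1]]
  expect_equal(f$start %% L, cox1$start %% L)
  expect_equal(f$end - f$start, cox1$end - cox1$start)
})

test_that("homology scan scores identity 1, drops noise, survives mutation", {
  set.seed(9)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  ref <- paste(sample(aas, 120, TRUE), collapse = "")
  refs <- c(cox1 = ref, cob = paste(sample(aas, 90, TRUE), collapse = ""))

  hits <- homology_scan(list(orf_candidate(0, 363, ref)), refs)
  expect_length(hits, 1L)
  expect_identical(hits[[1]]$query_label, "cox1")
  expect_equal(hits[[1]]$score, 1, tolerance = 1e-12)

  # dissimilar sequence: below the floor, no hit
  junk <- paste(rep("P", 120), collapse = "")
  expect_length(homology_scan(list(orf_candidate(0, 363, junk)),
                              c(cox1 = paste(rep("W", 120), collapse = ""))),
                0L)

  # 10% point substitutions: label recovered, score consistent with the
  # independent edit-distance bound (12 substitutions of 120 residues)
  mut <- strsplit(ref, "")[[1]]
  at <- sample(120, 12)
  mut[at] <- vapply(mut[at], function(a) sample(setdiff(aas, a), 1), "")
  mutseq <- paste(mut, collapse = "")
  dist <- utils::adist(ref, mutseq)[1, 1]
  expect_equal(dist, 12)
  h <- homology_scan(list(orf_candidate(0, 363, mutseq)), refs)
  expect_identical(h[[1]]$query_label, "cox1")
  expect_gt(h[[1]]$score, 0.6)
  expect_lt(h[[1]]$score, 1)
})

test_that("transmembrane segment counting follows the hydropathy windows", {
  expect_equal(predict_tm(strrep("L", 19)), 1L)
  expect_equal(predict_tm(strrep("G", 40)), 0L)
  # two hydrophobic stretches separated by a charged linker
  p <- paste0(strrep("L", 20), strrep("K", 10), strrep("I", 20))
  expect_equal(predict_tm(p), 2L)
  expect_warning(tm <- predict_tm(paste0(strrep("L", 19), "Z")), "unknown")
  expect_equal(tm, 1L)
})

test_that("URF calling applies the length and transmembrane filters", {
  hydro <- paste0(strrep("K", 30), strrep("L", 21), strrep("K", 48))
  urfs <- annotate_urfs(list(
    orf_candidate(0, 90, strrep("L", 29)),            # too short (90 bp)
    orf_candidate(200, 503, strrep("K", 100)),        # no TM segment
    orf_candidate(700, 1000, hydro)))                 # planted 21-L stretch
  expect_length(urfs, 1L)
  expect_equal(urfs[[1]]$start, 700L)
  expect_identical(urfs[[1]]$label, "urf1")
  expect_identical(urfs[[1]]$kind, "URF")
})

test_that("tRNA-like candidates are rejected only inside genes without structure", {
  ann <- AnnotationSet("g", list(
    GeneFeature("cox1", 100, 700, "+", "protein"),
    GeneFeature("rnl", 800, 1500, "+", "rRNA")))
  cands <- list(
    list(start = 200, end = 270, canonical_structure = FALSE),  # in cox1
    list(start = 720, end = 790, canonical_structure = TRUE),   # in gap
    list(start = 900, end = 970, canonical_structure = TRUE))   # in rnl
  res <- filter_trna_candidates(cands, ann, genome_length = 2000)
  expect_length(res$rejected, 1L)
  expect_equal(res$rejected[[1]]$start, 200)
  expect_length(res$kept, 2L)
  expect_false(res$kept[[1]]$review)   # non-coding gap, no flag
  expect_true(res$kept[[2]]$review)    # canonical but inside the rnl
})

test_that("boundary selection minimizes overlap, then maximizes similarity", {
  set.seed(13)
  g <- random_genome("b", 600)
  stops <- data.frame(end = 400, kind = "TAA", stringsAsFactors = FALSE)
  up <- GeneFeature("cob", 0, 110, "+", "protein")

  # two starts: one overlapping the upstream gene by 10 bp, one clear
  sel <- select_boundaries(c(100L, 130L), stops, list(up), g)
  expect_equal(sel$start, 130L)

  # a single candidate start comes back unchanged
  sel1 <- select_boundaries(166L, stops, list(up), g)
  expect_equal(sel1$start, 166L)
  expect_equal(sel1$end, 400L)

  # two zero-overlap starts: the one whose protein matches the reference
  # over more columns wins, judged by the module's own aligner
  code <- get_code_table("mold")
  nt_long <- extract_feature_sequence(
    g, GeneFeature("x", 130, 400, "+", "protein"))
  prot_long <- paste0("M", translate_seq(substr(nt_long, 4, nchar(nt_long) - 3),
                                         code))
  sel2 <- select_boundaries(c(130L, 160L), stops, list(up), g,
                            reference = prot_long, code = code)
  expect_equal(sel2$start, 130L)
  short_ref <- substr(prot_long, 11, nchar(prot_long))
  sel3 <- select_boundaries(c(130L, 160L), stops, list(up), g,
                            reference = short_ref, code = code)
  expect_equal(sel3$start, 160L)
})

test_that("incomplete stops are used only when no complete stop fits", {
  set.seed(14)
  g <- random_genome("ic", 500)
  nxt <- GeneFeature("nad4", 300, 420, "+", "protein")
  both <- data.frame(end = c(450, 300), kind = c("TAA", "incomplete_T"),
                     stringsAsFactors = FALSE)
  # complete stop lies beyond the next feature start: incomplete allowed
  sel <- select_boundaries(90L, both, list(nxt), g)
  expect_identical(sel$stop_kind, "incomplete_T")
  expect_equal(sel$end, 300)
  # complete stop before the neighbour: incomplete candidates discarded
  both2 <- data.frame(end = c(240, 300), kind = c("TAA", "incomplete_T"),
                      stringsAsFactors = FALSE)
  sel2 <- select_boundaries(90L, both2, list(nxt), g)
  expect_identical(sel2$stop_kind, "TAA")
})

test_that("full annotation recovers planted genes exactly on a small cohort", {
  ok <- 0L; total <- 0L
  for (seed in 101:110) {
    gx <- generate_genome(compact_spec(seed), paste0("t", seed))
    refs <- list(proteins = gx$ledger$proteins, rnas = gx$ledger$rnas)
    res <- annotate_genome(gx$genome, refs)
    led <- gx$ledger$features
    L <- gx$genome$length
    for (i in seq_len(nrow(led))) {
      if (led$kind[i] == "URF") next
      total <- total + 1L
      f <- Filter(function(x) x$label == led$label[i],
                  res$annotation$features)
      if (length(f) == 1L &&
          (f[[1]]$start %% L) == (led$start[i] %% L) &&
          (f[[1]]$end - f[[1]]$start) == (led$end[i] - led$start[i]))
        ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("planted URFs are recovered among the annotated URFs", {
  gx <- generate_genome(genome_spec(gene_models = COMPACT_GENE_MODELS,
                                    seed = 55), "u")
  refs <- list(proteins = gx$ledger$proteins, rnas = gx$ledger$rnas)
  res <- annotate_genome(gx$genome, refs)
  led <- gx$ledger$features
  planted <- led[led$kind == "URF", ]
  got <- Filter(function(f) f$kind == "URF", res$annotation$features)
  for (i in seq_len(nrow(planted))) {
    expect_true(any(vapply(got, function(f)
      f$start == planted$start[i] && f$end == planted$end[i], FALSE)),
      label = paste("planted URF at", planted$start[i]))
  }
})

test_that("frameshift repair follows the majority of spanning reads", {
  flank_l <- "ACGTGACGTGACGTGACGTG"
  flank_r <- "GACTGGACTGGACTGGACTG"
  ref7 <- MitoGenome("r", paste0(flank_l, strrep("T", 7), flank_r), FALSE)
  truth8 <- MitoGenome("t", paste0(flank_l, strrep("T", 8), flank_r), FALSE)

  reads8 <- simulate_reads(truth8, depth = 30, read_len = 30, seed = 8)
  fix <- repair_frameshift(ref7, reads8, c(5, 45))
  expect_identical(fix$status, "ok")
  expect_identical(fix$genome$sequence, truth8$sequence)
  applied <- fix$edits[fix$edits$applied, ]
  expect_equal(nrow(applied), 1L)
  expect_equal(applied$old_len, 7L)
  expect_equal(applied$new_len, 8L)
  expect_identical(applied$note, "insertion")

  # reads agreeing with the reference leave it unchanged
  reads7 <- simulate_reads(ref7, depth = 30, read_len = 30, seed = 9)
  fix2 <- repair_frameshift(ref7, reads7, c(5, 45))
  expect_identical(fix2$status, "no_edits")
  expect_identical(fix2$genome$sequence, ref7$sequence)

  # an exact 50/50 split is left alone and logged as a tie
  half <- c(vapply(simulate_reads(ref7, 10, 30, seed = 10), `[[`, "", "seq")[1:5],
            vapply(simulate_reads(truth8, 10, 30, seed = 10), `[[`, "", "seq")[1:5])
  # keep only reads spanning the run from both constructions
  span7 <- half[grepl(paste0("GACGTG", "T{6,9}", "GACTGG"), half)]
  n7 <- sum(grepl("GT{7}G", span7)); n8 <- sum(grepl("GT{8}G", span7))
  fix3 <- repair_frameshift(ref7, c(rep(span7[grepl("GT{7}G", span7)][1], 3),
                                    rep(span7[grepl("GT{8}G", span7)][1], 3)),
                            c(5, 45))
  expect_false(any(fix3$edits$applied))
  expect_true(any(grepl("tie", fix3$edits$note)))

  # no spanning reads at all: uncorrectable, genome unchanged
  fix4 <- repair_frameshift(ref7, c("AAAAACCCCCGGGGG"), c(5, 45))
  expect_identical(fix4$status, "uncorrectable")
  expect_identical(fix4$genome$sequence, ref7$sequence)
})
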