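test_that("gene orders come from annotations in circular start order", {
  ann <- AnnotationSet("g", list(
    GeneFeature("cox1", 10, 400, "+", "protein"),
    GeneFeature("urf1", 700, 820, "+", "URF"),
    GeneFeature("cox2", 500, 690, "+", "protein"),
    GeneFeature("cob", 900, 1200, "+", "protein")))
  expect_equal(gene_order_from_annotation(ann)$order,
               c("cox1", "cox2", "cob"))
  expect_equal(gene_order_from_annotation(ann, include_urfs = TRUE)$order,
               c("cox1", "cox2", "urf1", "cob"))
})

test_that("restriction to shared labels preserves relative order", {
  a <- GeneOrder("a", c("x", "y", "z", "w"))
  b <- GeneOrder("b", c("x", "z", "y"))
  r <- restrict_to_shared(a, b)
  expect_equal(r[[1]]$order, c("x", "y", "z"))
  expect_equal(r[[2]]$order, c("x", "z", "y"))
  # identical label sets come back unchanged
  r2 <- restrict_to_shared(a, GeneOrder("c", rev(a$order)))
  expect_equal(r2[[1]]$order, a$order)
  expect_error(restrict_to_shared(a, GeneOrder("d", c("x", "q1", "q2"))),
               "fewer than 2 shared")
})

test_that("breakpoint distance matches enumerated adjacency sets", {
  a <- GeneOrder("a", as.character(1:5))
  expect_equal(breakpoint_distance(a, a)$bd, 0L)
  b <- GeneOrder("b", c("1", "3", "2", "4", "5"))
  # adjacency sets {12,23,34,45,51} vs {13,32,24,45,51}: intersection {45,51}
  res <- breakpoint_distance(a, b)
  expect_equal(res$bd, 3L)
  expect_equal(res$n_shared, 5L)
  expect_equal(res$bdn, 3 / 5)
  # symmetric with equal label sets
  expect_equal(breakpoint_distance(b, a)$bd, 3L)
  # a full reversal breaks every directed adjacency
  expect_equal(breakpoint_distance(
    a, GeneOrder("r", rev(a$order)))$bd, 5L)
  expect_error(breakpoint_distance(a, GeneOrder("c", c("1", "2", "9"))),
               "label sets")
})

test_that("BDn display rounding is half-up to two decimals", {
  expect_equal(ctenomito:::round_half_up(9 / 13, 2), 0.69)
  expect_equal(ctenomito:::round_half_up(11 / 13, 2), 0.85)
  expect_equal(ctenomito:::round_half_up(12 / 13, 2), 0.92)
  expect_equal(ctenomito:::round_half_up(0.125, 2), 0.13)
})

test_that("breakpoint distance equals the brute-force oracle on random pairs", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    a <- random_order(n, "a"); b <- GeneOrder("b", sample(a$order))
    expect_equal(breakpoint_distance(a, b)$bd, brute_bd(a$order, b$order))
  }
})

test_that("distances and blocks are invariant under rotation", {
  set.seed(55)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    a <- random_order(n, "a"); b <- GeneOrder("b", sample(a$order))
    k <- sample(n, 1)
    a_rot <- GeneOrder("a", a$order[c(k:n, seq_len(k - 1))])
    expect_equal(breakpoint_distance(a_rot, b)$bd,
                 breakpoint_distance(a, b)$bd)
    blocks <- lapply(synteny_blocks(a, b), `[[`, "genes")
    blocks_rot <- lapply(synteny_blocks(a_rot, b), `[[`, "genes")
    expect_equal(blocks_rot, blocks)
  }
})

test_that("synteny blocks chain exactly the conserved adjacencies", {
  a <- GeneOrder("a", as.character(1:5))
  # identical orders: one block of the whole circle
  blocks <- synteny_blocks(a, a)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$length, 5L)
  # conserved adjacencies {12, 51} chain circularly into (5,1,2)
  b <- GeneOrder("b", c("1", "2", "4", "3", "5"))
  blocks2 <- synteny_blocks(a, b)
  expect_length(blocks2, 1L)
  expect_equal(blocks2[[1]]$genes, c("5", "1", "2"))
  # reversal: no directed adjacency survives
  expect_length(synteny_blocks(a, GeneOrder("r", rev(a$order))), 0L)
})

test_that("blocks account for exactly n - BD conserved adjacencies", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    a <- random_order(n, "a"); b <- GeneOrder("b", sample(a$order))
    bd <- breakpoint_distance(a, b)$bd
    blocks <- synteny_blocks(a, b)
    covered <- if (bd == 0L) n else
      sum(vapply(blocks, function(bl) bl$length - 1L, 0L))
    expect_equal(covered, n - bd)
    # blocks never overlap
    genes <- unlist(lapply(blocks, `[[`, "genes"))
    if (bd > 0L) expect_false(anyDuplicated(genes) > 0L)
  }
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(9)
  orders <- lapply(1:4, function(i) GeneOrder(paste0("g", i),
                                              sample(letters[1:7])))
  dm <- distance_matrix(orders)
  expect_true(all(dm$bd == t(dm$bd)))
  expect_true(all(diag(dm$bd) == 0))
  expect_equal(dm$bdn, dm$bd / dm$n_shared)
  rendered <- render_bd_matrix(dm)
  expect_equal(rendered[1, 2], as.character(dm$bd[1, 2]))
  expect_equal(rendered[2, 1],
               sprintf("%.2f", ctenomito:::round_half_up(dm$bdn[2, 1], 2)))
  # two identical orders give off-diagonal zero
  dm0 <- distance_matrix(list(GeneOrder("x", letters[1:5]),
                              GeneOrder("y", letters[1:5])))
  expect_equal(dm0$bd[1, 2], 0L)
})

test_that("BDn reaches 1 when every adjacency is broken", {
  a <- GeneOrder("a", as.character(1:5))
  r <- breakpoint_distance(a, GeneOrder("r", rev(a$order)))
  expect_equal(r$bdn, 1)
})
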