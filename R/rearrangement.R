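# Circular gene-order comparison: breakpoint distance, normalized
# breakpoint distance (BDn), synteny blocks and pairwise matrices.
#
# These genomes encode all genes on one strand, so adjacencies are
# directed ordered pairs (g, next(g)) around the circle; a full reversal
# therefore breaks every adjacency. Rotations of an order compare equal.

#' Construct a circular gene order
#'
#' @param genome_id Identifier.
#' @param order Character vector of unique gene labels in circular order
#'   (all oriented `+`).
#' @return An object of class `GeneOrder`.
#' @export
GeneOrder <- function(genome_id, order) {
  order <- as.character(order)
  stopifnot(length(order) >= 2L, !anyDuplicated(order))
  structure(list(genome_id = genome_id, order = order,
                 n_genes = length(order)),
            class = "GeneOrder")
}

#' @export
print.GeneOrder <- function(x, ...) {
  cat(sprintf("GeneOrder %s (%d genes): %s\n", x$genome_id, x$n_genes,
              paste(x$order, collapse = " ")))
  invisible(x)
}

# Canonical rotation: start at the lexicographically smallest label.
canonical_rotation <- function(order)
  rotate_vec(order, which(order == min(order))[1L])

#' Gene order from an annotation
#'
#' Labels in circular genomic order by start coordinate; URFs excluded
#' unless requested; non-coding gaps ignored.
#'
#' @param ann [AnnotationSet()].
#' @param include_urfs Keep URF features in the order.
#' @return A [GeneOrder()].
#' @export
gene_order_from_annotation <- function(ann, include_urfs = FALSE) {
  feats <- ann$features
  if (!include_urfs) feats <- Filter(function(f) f$kind != "URF", feats)
  if (length(feats) < 2L) stop("need at least 2 features for a gene order")
  labs <- vapply(feats, `[[`, "", "label")
  if (anyDuplicated(labs))
    stop("duplicate label(s) in annotation: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  GeneOrder(ann$genome_id, labs[order(vapply(feats, `[[`, 0L, "start"))])
}

#' Restrict two gene orders to their shared label set
#'
#' @param a,b [GeneOrder()] objects.
#' @return List of the two reduced [GeneOrder()]s, circular relative order
#'   preserved.
#' @export
restrict_to_shared <- function(a, b) {
  shared <- intersect(a$order, b$order)
  if (length(shared) < 2L)
    stop("fewer than 2 shared labels between ", a$genome_id, " and ",
         b$genome_id)
  list(GeneOrder(a$genome_id, a$order[a$order %in% shared]),
       GeneOrder(b$genome_id, b$order[b$order %in% shared]))
}

# Directed circular adjacencies as "g>h" strings.
adjacencies <- function(order) {
  n <- length(order)
  paste(order, order[c(2:n, 1L)], sep = ">")
}

#' Breakpoint distance between two circular gene orders
#'
#' The number of directed adjacencies of `a` absent from `b`; the
#' normalized distance divides by the number of shared genes. With
#' identical label sets the measure is symmetric.
#'
#' @param a,b [GeneOrder()] objects over the same label set (apply
#'   [restrict_to_shared()] first otherwise).
#' @return A `BreakpointResult`: list with `bd`, `n_shared`, `bdn`.
#' @export
breakpoint_distance <- function(a, b) {
  if (!setequal(a$order, b$order))
    stop("label sets differ; apply restrict_to_shared() first")
  bd <- sum(!(adjacencies(a$order) %in% adjacencies(b$order)))
  structure(list(bd = as.integer(bd), n_shared = a$n_genes,
                 bdn = bd / a$n_genes),
            class = "BreakpointResult")
}

#' @export
print.BreakpointResult <- function(x, ...) {
  cat(sprintf("BD %d of %d shared genes (BDn %.2f)\n",
              x$bd, x$n_shared, round_half_up(x$bdn, 2L)))
  invisible(x)
}

#' Synteny blocks shared by two circular gene orders
#'
#' Maximal runs of two or more genes that are consecutive and co-ordered
#' in both circular orders. Blocks are reported in `a`'s order, the list
#' anchored at the lexicographically smallest label, and never overlap.
#'
#' @param a,b [GeneOrder()] objects over the same label set.
#' @return List of `SyntenyBlock` objects (`genes`, `length`); empty when
#'   no adjacency is conserved.
#' @export
synteny_blocks <- function(a, b) {
  if (!setequal(a$order, b$order))
    stop("label sets differ; apply restrict_to_shared() first")
  ord <- canonical_rotation(a$order)
  n <- length(ord)
  conserved <- adjacencies(ord) %in% adjacencies(b$order)  # edge i: ord[i]->ord[i+1]
  if (all(conserved)) {
    blk <- structure(list(genes = ord, length = n), class = "SyntenyBlock")
    return(list(blk))
  }
  # chain maximal runs of conserved edges on the circle
  blocks <- list()
  i <- 1L
  # find a broken edge to start after, so runs never split across the seam
  first_break <- which(!conserved)[1L]
  idx <- c(seq.int(first_break + 1L, n), seq_len(first_break))[seq_len(n)]
  run <- integer(0)
  for (k in idx) {
    if (conserved[k]) run <- c(run, k)
    else {
      if (length(run))
        blocks[[length(blocks) + 1L]] <- run
      run <- integer(0)
    }
  }
  if (length(run)) blocks[[length(blocks) + 1L]] <- run
  out <- lapply(blocks, function(edges) {
    genes <- ord[c(edges, edges[length(edges)] %% n + 1L)]
    structure(list(genes = genes, length = length(genes)),
              class = "SyntenyBlock")
  })
  # report in a's canonical order by first-gene position
  pos <- vapply(out, function(b) match(b$genes[1L], ord), 0L)
  out[order(pos)]
}

#' @export
print.SyntenyBlock <- function(x, ...) {
  cat(paste(x$genes, collapse = "-"), "\n")
  invisible(x)
}

#' Pairwise breakpoint-distance matrix
#'
#' @param orders List of [GeneOrder()] objects (labels need not be
#'   identical; each pair is restricted to its shared set first).
#' @return List with `bd` and `bdn` numeric matrices (symmetric, zero
#'   diagonal) and `n_shared`.
#' @export
distance_matrix <- function(orders) {
  stopifnot(length(orders) >= 2L)
  ids <- vapply(orders, `[[`, "", "genome_id")
  k <- length(orders)
  bd <- matrix(0L, k, k, dimnames = list(ids, ids))
  bdn <- matrix(0, k, k, dimnames = list(ids, ids))
  ns <- matrix(0L, k, k, dimnames = list(ids, ids))
  diag(ns) <- vapply(orders, `[[`, 0L, "n_genes")
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    r <- restrict_to_shared(orders[[i]], orders[[j]])
    res <- breakpoint_distance(r[[1]], r[[2]])
    bd[i, j] <- bd[j, i] <- res$bd
    bdn[i, j] <- bdn[j, i] <- res$bdn
    ns[i, j] <- ns[j, i] <- res$n_shared
  }
  list(bd = bd, bdn = bdn, n_shared = ns)
}

#' Render a distance matrix with BD above and BDn below the diagonal
#'
#' @param dm Result of [distance_matrix()].
#' @return A character matrix suitable for printing or TSV export; BDn
#'   entries are rounded half-up to two decimals.
#' @export
render_bd_matrix <- function(dm) {
  k <- nrow(dm$bd)
  out <- matrix("-", k, k, dimnames = dimnames(dm$bd))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) out[i, j] <- as.character(dm$bd[i, j])
    if (i > j) out[i, j] <- sprintf("%.2f", round_half_up(dm$bdn[i, j], 2L))
  }
  out
}
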