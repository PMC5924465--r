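# Homology-guided annotation of an unannotated circular mitogenome:
# boundary selection, URF calling, transmembrane heuristic, tRNA
# false-positive filtering, and the orchestrating annotate_genome().

# Unwrap a (possibly origin-spanning) 0-based half-open interval into one
# or two plain intervals within [0, L).
unwrap_interval <- function(start, end, L) {
  if (end <= L) return(list(c(start, end)))
  list(c(start, L), c(0L, end - L))
}

# Total overlap in bp between two features on a circle of length L.
circ_overlap <- function(a_start, a_end, b_start, b_end, L) {
  ov <- 0L
  for (ia in unwrap_interval(a_start, a_end, L))
    for (ib in unwrap_interval(b_start, b_end, L))
      ov <- ov + max(0L, min(ia[2], ib[2]) - max(ia[1], ib[1]))
  ov
}

# Kyte-Doolittle hydropathy values.
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Count putative transmembrane segments
#'
#' A simple published-style hydropathy heuristic: the number of
#' non-overlapping windows of `window` residues whose mean Kyte-Doolittle
#' hydropathy exceeds `cutoff`, scanning greedily left to right. Unknown
#' residues contribute hydropathy 0 with a warning.
#'
#' @param protein Amino-acid string.
#' @param window Window width in residues (default 19, a typical
#'   transmembrane helix span).
#' @param cutoff Mean-hydropathy threshold (default 1.6).
#' @return Integer count of predicted segments.
#' @export
predict_tm <- function(protein, window = 19L, cutoff = 1.6) {
  stopifnot(nzchar(protein))
  ch <- seq_chars(protein)
  h <- unname(KD_HYDROPATHY[ch])
  if (anyNA(h)) {
    warning("unknown residue(s) treated as hydropathy 0: ",
            paste(unique(ch[is.na(h)]), collapse = ""))
    h[is.na(h)] <- 0
  }
  n <- length(h)
  if (n < window) return(0L)
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]) / window
  count <- 0L; i <- 1L
  while (i <= length(means)) {
    if (means[i] > cutoff) { count <- count + 1L; i <- i + window }
    else i <- i + 1L
  }
  count
}

#' Annotate unidentified reading frames
#'
#' Keeps unassigned ORFs strictly longer than `min_len` bp whose protein
#' carries at least one predicted transmembrane segment, and labels them
#' `urf1..urfN` in genomic order.
#'
#' @param orfs List of `OrfCandidate`s left without a homology label.
#' @param min_len Length threshold in bp (strict `>`, default 100).
#' @param tm_window,tm_cutoff Passed to [predict_tm()].
#' @return List of [GeneFeature()]s of kind `"URF"`.
#' @export
annotate_urfs <- function(orfs, min_len = 100L, tm_window = 19L,
                          tm_cutoff = 1.6) {
  keep <- Filter(function(o) {
    (o$end - o$start) > min_len &&
      predict_tm(o$protein, tm_window, tm_cutoff) >= 1L
  }, orfs)
  if (!length(keep)) return(list())
  keep <- keep[order(vapply(keep, `[[`, 0L, "start"))]
  lapply(seq_along(keep), function(i) {
    o <- keep[[i]]
    GeneFeature(paste0("urf", i), o$start, o$end, o$strand, "URF")
  })
}

#' Filter tRNA-like candidates against the annotation
#'
#' Implements the false-positive rule used for these genomes: a candidate
#' is rejected iff it overlaps an annotated protein or rRNA feature and
#' lacks a canonical cloverleaf structure. All other candidates are kept;
#' those that overlap coding features but do have a canonical structure
#' are kept with a review flag (they may be chance structures inside a
#' gene, as seen inside the rnl).
#'
#' @param candidates List of lists with fields `start`, `end`,
#'   `canonical_structure` (logical supplied by the upstream scanner).
#' @param ann [AnnotationSet()] of protein/rRNA features.
#' @param genome_length Circle length for overlap arithmetic.
#' @return List with elements `kept` (each with added `review` flag) and
#'   `rejected`.
#' @export
filter_trna_candidates <- function(candidates, ann, genome_length) {
  kept <- list(); rejected <- list()
  coding <- Filter(function(f) f$kind %in% c("protein", "rRNA"), ann$features)
  for (cand in candidates) {
    ov <- any(vapply(coding, function(f)
      circ_overlap(cand$start, cand$end, f$start, f$end, genome_length) > 0L,
      FALSE))
    if (ov && !isTRUE(cand$canonical_structure)) {
      rejected[[length(rejected) + 1L]] <- cand
    } else {
      cand$review <- ov && isTRUE(cand$canonical_structure)
      kept[[length(kept) + 1L]] <- cand
    }
  }
  list(kept = kept, rejected = rejected)
}

#' Select gene boundaries among candidate starts and stops
#'
#' Applies the two published criteria in lexicographic order: (1) minimal
#' total overlap in bp with neighbouring annotated features, (2) among
#' ties, maximal homology score of the implied protein against the
#' reference, (3) among remaining ties, the longest ORF. Incomplete stop
#' candidates (a T or TA abutting the next feature) are admissible only
#' when no complete-stop candidate ends at or before the next feature
#' start.
#'
#' @param candidate_starts Integer vector of candidate start positions
#'   (0-based, in frame).
#' @param candidate_stops Data frame with columns `end` (0-based
#'   half-open feature end) and `kind` (`"TAA"`, `"TAG"`,
#'   `"incomplete_T"`, `"incomplete_TA"`).
#' @param neighbors List of [GeneFeature()]s already (or provisionally)
#'   placed around this gene.
#' @param genome [MitoGenome()] the coordinates refer to.
#' @param reference Reference protein used for criterion 2, or `NULL` to
#'   skip similarity scoring.
#' @param code [CodeTable()] for translating candidate proteins.
#' @return List with `start`, `end`, `stop_kind`.
#' @export
select_boundaries <- function(candidate_starts, candidate_stops, neighbors,
                              genome, reference = NULL,
                              code = get_code_table("mold")) {
  stopifnot(length(candidate_starts) >= 1L, nrow(candidate_stops) >= 1L)
  L <- genome$length
  complete <- candidate_stops$kind %in% c("TAA", "TAG")
  if (any(complete)) {
    # next downstream feature start (circular) after the earliest start
    next_start <- next_feature_start(min(candidate_starts), neighbors, L)
    if (!is.null(next_start)) {
      reach <- candidate_stops$end[complete]
      # admissible complete stop before the neighbour begins?
      dist_stop <- (reach - min(candidate_starts)) %% L
      dist_next <- (next_start - min(candidate_starts)) %% L
      if (any(dist_stop <= dist_next | dist_next == 0))
        candidate_stops <- candidate_stops[complete, , drop = FALSE]
    } else {
      candidate_stops <- candidate_stops[complete, , drop = FALSE]
    }
  }
  grid <- expand.grid(si = seq_along(candidate_starts),
                      ei = seq_len(nrow(candidate_stops)))
  grid$start <- candidate_starts[grid$si]
  grid$end <- candidate_stops$end[grid$ei]
  grid$kind <- as.character(candidate_stops$kind[grid$ei])
  wrap <- grid$end <= grid$start
  grid$end[wrap] <- grid$end[wrap] + L           # unwrap across the origin
  grid <- grid[grid$end > grid$start, , drop = FALSE]
  if (!nrow(grid)) stop("no valid (start, stop) combination")
  grid$start <- as.integer(grid$start)
  grid$end <- as.integer(grid$end)
  grid$overlap <- vapply(seq_len(nrow(grid)), function(r)
    sum(vapply(neighbors, function(f)
      circ_overlap(grid$start[r], grid$end[r], f$start, f$end, L), 0)),
    0)
  grid$len <- grid$end - grid$start
  # criterion 1: minimal total overlap with neighbours
  grid <- grid[grid$overlap == min(grid$overlap), , drop = FALSE]
  # criterion 2: among ties, maximal similarity of the implied protein
  if (nrow(grid) > 1L && !is.null(reference)) {
    prots <- vapply(seq_len(nrow(grid)), function(r) {
      nt <- extract_feature_sequence(
        genome, GeneFeature("cand", grid$start[r], grid$end[r], "+",
                            "protein"))
      ncod <- if (grid$kind[r] %in% c("TAA", "TAG")) nchar(nt) - 3L
              else 3L * (nchar(nt) %/% 3L)
      paste0("M", translate_seq(substr(nt, 4L, ncod), code))
    }, "")
    mat <- align_score_matrix(FALSE)
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(prots),
      Biostrings::AAStringSet(reference)[[1]], type = "global",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
      scoreOnly = TRUE) / self_score(reference, mat)
    grid <- grid[abs(sc - max(sc)) <= 1e-12, , drop = FALSE]
  }
  # criterion 3: among remaining ties, the longest ORF
  best <- grid[which.max(grid$len), ]
  list(start = best$start, end = best$end, stop_kind = best$kind)
}

# First neighbour start strictly downstream (circularly) of `pos`, or NULL.
next_feature_start <- function(pos, neighbors, L) {
  if (!length(neighbors)) return(NULL)
  starts <- vapply(neighbors, `[[`, 0L, "start")
  d <- (starts - pos) %% L
  d[d == 0] <- L
  starts[which.min(d)]
}

#' Annotate a circular mitogenome by ORF scanning plus homology
#'
#' The full annotation stage: maximal ORFs are scanned, scored against
#' labelled reference proteins, the best ORF per gene label is retained,
#' start positions are refined by the overlap/similarity criteria, rRNAs
#' are located by nucleotide homology, and remaining unassigned ORFs that
#' pass the length and transmembrane filters become URFs (unassigned ORFs
#' mostly buried in annotated genes are discarded).
#'
#' @param genome [MitoGenome()] to annotate.
#' @param references List with elements `proteins` (named amino-acid
#'   vector) and optionally `rnas` (named nucleotide vector).
#' @param code [CodeTable()] (default mold).
#' @param min_orf_len Minimum ORF length in bp.
#' @param floor Homology score floor for calling a gene present.
#' @param urf_min_len URF length threshold (strict `>`).
#' @return List with `annotation` ([AnnotationSet()]), `orfs`, `hits`.
#' @export
annotate_genome <- function(genome, references, code = get_code_table("mold"),
                            min_orf_len = 100L, floor = 0.3,
                            urf_min_len = 100L) {
  orfs <- find_orfs(genome, code, min_len = min_orf_len)
  hits <- homology_scan(orfs, references$proteins, floor = floor)
  L <- genome$length

  # best ORF per label (score, then length)
  by_label <- split(hits, vapply(hits, `[[`, "", "query_label"))
  chosen <- lapply(by_label, function(hs) {
    sc <- vapply(hs, `[[`, 0, "score")
    len <- vapply(hs, function(h) {
      o <- orfs[[h$orf]]; o$end - o$start
    }, 0L)
    hs[[order(-sc, -len)[1L]]]
  })

  rna_feats <- list()
  if (!is.null(references$rnas)) {
    for (lab in names(references$rnas)) {
      loc <- locate_rna(genome, references$rnas[[lab]])
      if (loc$score < floor) next
      rna_feats[[length(rna_feats) + 1L]] <-
        GeneFeature(lab, loc$start, loc$end, "+", "rRNA")
    }
  }

  # Boundary selection, refined iteratively: the first pass sees the
  # other genes at their maximal ORF extent, later passes see the starts
  # selected so far, until the selection is stable (3 passes suffice for
  # chains of upstream-extended ORFs).
  current <- lapply(names(chosen), function(lab) {
    o <- orfs[[chosen[[lab]]$orf]]
    GeneFeature(lab, o$start, o$end, o$strand, "protein")
  })
  names(current) <- names(chosen)
  for (pass in 1:3) {
    nxt <- current
    for (lab in names(chosen)) {
      o <- orfs[[chosen[[lab]]$orf]]
      neighbors <- c(rna_feats, unname(nxt[names(nxt) != lab]))
      stops <- data.frame(end = o$end, kind = o$stop_kind,
                          stringsAsFactors = FALSE)
      sel <- select_boundaries(o$candidate_starts, stops, neighbors, genome,
                               reference = references$proteins[[lab]],
                               code = code)
      nxt[[lab]] <- GeneFeature(
        lab, sel$start %% L, sel$start %% L + (sel$end - sel$start),
        o$strand, "protein",
        has_incomplete_stop = grepl("incomplete", sel$stop_kind))
    }
    stable <- identical(lapply(nxt, `[[`, "start"),
                        lapply(current, `[[`, "start"))
    current <- nxt
    if (stable && pass > 1L) break
  }
  feats <- c(rna_feats, unname(current))

  # URFs from unassigned ORFs: each is trimmed to its least-overlapping
  # start (no reference to score against), and only ORFs that end up
  # clear of annotated features and still pass the length and
  # transmembrane filters are kept.
  assigned_orf_idx <- vapply(chosen, `[[`, 0L, "orf")
  unassigned <- orfs[setdiff(seq_along(orfs), assigned_orf_idx)]
  urf_cand <- list()
  for (o in unassigned) {
    stops <- data.frame(end = o$end, kind = o$stop_kind,
                        stringsAsFactors = FALSE)
    sel <- select_boundaries(o$candidate_starts, stops, feats, genome,
                             reference = NULL, code = code)
    ov <- sum(vapply(feats, function(f)
      circ_overlap(sel$start, sel$end, f$start, f$end, L), 0L))
    if (ov > 0L) next
    d_codons <- (sel$start - o$start) %/% 3L
    o$start <- sel$start %% L
    o$end <- o$start + (sel$end - sel$start)
    if (d_codons > 0L)
      o$protein <- paste0("M", substr(o$protein, d_codons + 2L,
                                      nchar(o$protein)))
    urf_cand[[length(urf_cand) + 1L]] <- o
  }
  urfs <- annotate_urfs(urf_cand, min_len = urf_min_len)
  # greedy non-overlap among URFs themselves (longest first)
  urfs <- urfs[order(-vapply(urfs, feature_length, 0L))]
  kept <- list()
  for (u in urfs) {
    if (!any(vapply(kept, function(k)
      circ_overlap(u$start, u$end, k$start, k$end, L) > 0L, FALSE)))
      kept[[length(kept) + 1L]] <- u
  }
  kept <- kept[order(vapply(kept, `[[`, 0L, "start"))]
  kept <- lapply(seq_along(kept), function(i) {
    u <- kept[[i]]; u$label <- paste0("urf", i); u
  })
  feats <- c(feats, kept)

  list(annotation = AnnotationSet(genome$id, feats), orfs = orfs, hits = hits)
}
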