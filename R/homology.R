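# Homology scoring of ORF candidates against labelled reference sets.
#
# Scoring is a deterministic global pairwise alignment (Needleman-Wunsch,
# BLOSUM62, affine gaps: open 10 / extend 1), normalized by the self-score
# of the reference so that an identical sequence scores 1. rRNA references
# use a +1/-1 nucleotide matrix with the same gap scheme.

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

self_score <- function(seq, mat) {
  ch <- seq_chars(seq)
  sum(mat[cbind(ch, ch)])
}

align_score_matrix <- function(nucleotide = FALSE) {
  if (nucleotide)
    Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                             baseOnly = TRUE)
  else blosum62
}

#' Score ORF candidates against labelled reference sequences
#'
#' Every (ORF, reference) pair is scored by global alignment; the score is
#' normalized by the reference self-score and clamped to [0, 1]. Pairs
#' below `floor` are dropped, and each ORF keeps its single best label;
#' ties go to the longer aligned span, then the lexicographically smaller
#' label.
#'
#' @param orfs List of `OrfCandidate` objects (or plain character
#'   sequences for nucleotide mode).
#' @param references Named character vector of reference sequences
#'   (proteins by default).
#' @param floor Minimum normalized score for a hit (default 0.3; the
#'   published procedure states no cut-off, so this is configurable).
#' @param nucleotide Use the nucleotide scoring matrix instead of
#'   BLOSUM62.
#' @return A list of `HomologyHit` objects: `orf` (index into `orfs`),
#'   `query_label`, `score`, `query_span`, `target_span`.
#' @export
homology_scan <- function(orfs, references, floor = 0.3, nucleotide = FALSE) {
  stopifnot(length(references) > 0L, !is.null(names(references)))
  if (!length(orfs)) return(list())
  seqs <- vapply(orfs, function(o)
    if (inherits(o, "OrfCandidate")) o$protein else o, "")
  mat <- align_score_matrix(nucleotide)
  make_set <- if (nucleotide) Biostrings::DNAStringSet else Biostrings::AAStringSet
  pat <- make_set(seqs)
  score_mat <- matrix(-Inf, nrow = length(seqs), ncol = length(references),
                      dimnames = list(NULL, names(references)))
  for (j in seq_along(references)) {
    ref <- references[[j]]
    ss <- self_score(ref, mat)
    sc <- Biostrings::pairwiseAlignment(
      pat, make_set(ref)[[1]], type = "global",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
      scoreOnly = TRUE)
    score_mat[, j] <- clamp(sc / ss, 0, 1)
  }
  hits <- list()
  for (i in seq_along(seqs)) {
    ok <- which(score_mat[i, ] >= floor)
    if (!length(ok)) next
    best_score <- max(score_mat[i, ok])
    tied <- ok[score_mat[i, ok] == best_score]
    if (length(tied) > 1L) {
      # break ties by longer aligned span, then label
      spans <- vapply(tied, function(j) {
        al <- Biostrings::pairwiseAlignment(
          pat[[i]], make_set(references[[j]])[[1]], type = "global",
          substitutionMatrix = mat, gapOpening = 10, gapExtension = 1)
        Biostrings::nchar(Biostrings::pattern(al))
      }, 0L)
      tied <- tied[order(-spans, names(references)[tied])]
    }
    j <- tied[1L]
    al <- Biostrings::pairwiseAlignment(
      pat[[i]], make_set(references[[j]])[[1]], type = "global",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 1)
    hits[[length(hits) + 1L]] <- structure(list(
      orf = i, query_label = names(references)[j],
      score = unname(score_mat[i, j]),
      query_span = c(1L, nchar(seqs[i])),
      target_span = c(1L, nchar(references[[j]]))),
      class = "HomologyHit")
  }
  hits
}

# Normalized global-alignment score of one pair (used by boundary
# selection when rescoring candidate starts).
pair_score <- function(query, ref, nucleotide = FALSE) {
  mat <- align_score_matrix(nucleotide)
  make_set <- if (nucleotide) Biostrings::DNAStringSet else Biostrings::AAStringSet
  sc <- Biostrings::pairwiseAlignment(
    make_set(query)[[1]], make_set(ref)[[1]], type = "global",
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
    scoreOnly = TRUE)
  clamp(sc / self_score(ref, mat), 0, 1)
}

# Locate an rRNA reference on the genome: exact-match fast path first,
# then the alignment fallback.
locate_rna <- function(genome, ref) {
  D <- if (genome$is_circular) paste0(genome$sequence, genome$sequence)
       else genome$sequence
  m <- Biostrings::matchPattern(ref, Biostrings::DNAString(D))
  if (length(m)) {
    s <- Biostrings::start(m)[1] - 1L
    L <- genome$length
    if (genome$is_circular && s >= L) s <- s - L
    return(list(start = s, end = s + nchar(ref), score = 1))
  }
  locate_by_homology(genome, ref)
}

# Locate a reference sequence (e.g. an rRNA) on a circular genome by
# fitting the whole reference inside the doubled genome (global-local
# alignment). Returns a 0-based half-open interval, possibly wrapping.
locate_by_homology <- function(genome, ref, nucleotide = TRUE) {
  D <- if (genome$is_circular) paste0(genome$sequence, genome$sequence)
       else genome$sequence
  mat <- align_score_matrix(nucleotide)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(D),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 1)
  sub <- Biostrings::subject(al)
  s <- Biostrings::start(sub) - 1L
  e <- Biostrings::end(sub)
  score <- clamp(Biostrings::score(al) / self_score(ref, mat), 0, 1)
  L <- genome$length
  if (genome$is_circular && s >= L) { s <- s - L; e <- e - L }
  list(start = s, end = e, score = score)
}
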