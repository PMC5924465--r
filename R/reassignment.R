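# Genetic-code reassignment detection from conserved alignment columns.
#
# The logic mirrors codon-usage investigation in conserved gene regions:
# at alignment columns where most non-target species agree on one amino
# acid, the target's codon is expected to encode that amino acid. A codon
# whose consensus profile contradicts its meaning under the expected code
# across enough columns is flagged as reassigned (the classic example
# being TGA read as Ser rather than Trp).

#' Detect codon reassignment in a target species
#'
#' @param coding_alignments List of codon-aware nucleotide alignments, one
#'   per gene: each a named character vector of equal-length aligned
#'   sequences (gaps `-`, length a multiple of 3), including the target.
#' @param target_species Name of the target row in each alignment.
#' @param expected [CodeTable()] giving the presumed meanings.
#' @param conservation_threshold Fraction of non-target species that must
#'   agree on one amino acid for a column to count as conserved
#'   (default 0.7).
#' @param min_columns Minimum number of conserved columns in which a codon
#'   must appear before it can be flagged (default 5).
#' @return A `ReassignmentReport`: a data frame with one row per codon
#'   used by the target at conserved columns (`codon`, `expected`,
#'   `inferred`, `n_columns`, `modal_freq`, `flagged`), plus a `profiles`
#'   attribute holding each codon's consensus-amino-acid frequency table.
#' @export
detect_reassignment <- function(coding_alignments, target_species,
                                expected = get_code_table("mold"),
                                conservation_threshold = 0.7,
                                min_columns = 5L) {
  stopifnot(length(coding_alignments) >= 1L)
  obs <- list()  # codon -> character vector of consensus amino acids
  for (aln in coding_alignments) {
    stopifnot(!is.null(names(aln)), target_species %in% names(aln))
    widths <- nchar(aln)
    if (length(unique(widths)) != 1L)
      stop("alignment rows have unequal lengths")
    if (widths[1] %% 3L != 0L)
      stop("alignment is not codon-aware (length not a multiple of 3)")
    others <- names(aln)[names(aln) != target_species]
    if (length(others) < 3L)
      stop("need at least 3 non-target species, got ", length(others))
    cod <- vapply(aln, codon_split, character(widths[1] %/% 3L))
    if (is.null(dim(cod))) cod <- matrix(cod, ncol = length(aln),
                                         dimnames = list(NULL, names(aln)))
    for (j in seq_len(nrow(cod))) {
      tcod <- cod[j, target_species]
      if (grepl("-", tcod, fixed = TRUE)) next
      ocod <- cod[j, others]
      ocod <- ocod[!grepl("-", ocod, fixed = TRUE)]
      if (length(ocod) < 3L) next
      aa <- unname(expected$codon_map[ocod])
      tab <- table(aa)
      consensus <- names(tab)[which.max(tab)]
      if (max(tab) / length(aa) < conservation_threshold) next
      obs[[tcod]] <- c(obs[[tcod]], consensus)
    }
  }
  codons <- sort(names(obs))
  profiles <- lapply(codons, function(cd) {
    tb <- table(obs[[cd]])
    tb / sum(tb)
  })
  names(profiles) <- codons
  rows <- lapply(codons, function(cd) {
    prof <- profiles[[cd]]
    inferred <- names(prof)[which.max(prof)]
    data.frame(codon = cd,
               expected = unname(expected$codon_map[cd]),
               inferred = inferred,
               n_columns = length(obs[[cd]]),
               modal_freq = max(prof),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  if (is.null(rep))
    rep <- data.frame(codon = character(), expected = character(),
                      inferred = character(), n_columns = integer(),
                      modal_freq = numeric(), stringsAsFactors = FALSE)
  rep$flagged <- rep$inferred != rep$expected &
    rep$n_columns >= min_columns & rep$modal_freq >= 0.5
  attr(rep, "profiles") <- profiles
  class(rep) <- c("ReassignmentReport", "data.frame")
  rep
}
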