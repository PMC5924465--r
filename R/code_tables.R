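# Genetic code tables.
#
# Compact ctenophore-like mitogenomes use the "Mold, Protozoan and
# Coelenterate" mitochondrial code (NCBI translation table 4), in which
# TGA encodes tryptophan. A lineage-specific variant reassigns TGA to
# serine; it is identical to the mold table at every other codon.

#' Construct a genetic code table
#'
#' @param name Table name.
#' @param codon_map Named character vector of length 64 mapping codons
#'   (DNA alphabet) to one-letter amino acids, stops as `"*"`.
#' @param start_codons Codons accepted as translation starts.
#' @return An object of class `CodeTable` with fields `name`, `codon_map`,
#'   `start_codons` and `stop_codons` (derived from the map).
#' @export
CodeTable <- function(name, codon_map, start_codons) {
  stopifnot(length(codon_map) == 64L, !is.null(names(codon_map)),
            all(nchar(names(codon_map)) == 3L),
            all(start_codons %in% names(codon_map)))
  structure(list(name = name, codon_map = codon_map,
                 start_codons = start_codons,
                 stop_codons = names(codon_map)[codon_map == "*"]),
            class = "CodeTable")
}

#' Retrieve a built-in genetic code
#'
#' `"mold"` is NCBI translation table 4 (TGA = Trp) with the four start
#' codons observed in these mitogenomes (ATA, ATG, ATT, TTA).
#' `"pbachei"` is the same table with TGA reassigned to Ser.
#'
#' @param name `"mold"` or `"pbachei"`.
#' @return A [CodeTable()].
#' @export
get_code_table <- function(name = c("mold", "pbachei")) {
  name <- match.arg(name)
  map <- Biostrings::getGeneticCode("4")
  starts <- c("ATA", "ATG", "ATT", "TTA")
  if (name == "pbachei") map["TGA"] <- "S"
  CodeTable(name, map, starts)
}

#' Translate a nucleotide sequence
#'
#' Stop codons are rendered as `"*"`. A trailing incomplete codon (1 or 2
#' bases) is rendered as `"X"`; ambiguous bases are an error.
#'
#' @param seq Nucleotide string over {A,C,G,T}.
#' @param code A [CodeTable()].
#' @return Amino-acid string.
#' @export
translate_seq <- function(seq, code) {
  stopifnot(inherits(code, "CodeTable"))
  seq <- toupper(seq)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L)
    stop("cannot translate: ambiguous base '", substr(seq, bad, bad),
         "' at position ", bad)
  codons <- codon_split(seq)
  aa <- character(length(codons))
  full <- nchar(codons) == 3L
  aa[full] <- unname(code$codon_map[codons[full]])
  aa[!full] <- "X"
  paste(aa, collapse = "")
}
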