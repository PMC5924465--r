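# Published per-genome statistics for the five ctenophore mitogenomes,
# shipped as plain-text fixtures. These are the inputs for the in-paper
# arithmetic checks (non-coding proportions, BDn normalization, size~NC
# correlation); the sequences themselves are not required for them.

#' Published non-coding statistics for the five ctenophore mitogenomes
#'
#' One row per species: genome length and non-coding totals computed with
#' URFs counted as non-coding (`nc_with_urfs`) and as coding
#' (`nc_without_urfs`), tract counts above 20 bp, and the longest tract
#' with its flanking genes.
#'
#' @return A data frame.
#' @export
published_nc_stats <- function() {
  utils::read.delim(system.file("extdata", "ctenophora_nc_stats.tsv",
                                package = "ctenomito"),
                    stringsAsFactors = FALSE)
}

#' Published breakpoint-distance table for the five ctenophore mitogenomes
#'
#' Breakpoint distances (BD) above the diagonal and normalized breakpoint
#' distances (BDn) below it, as printed. Note one internal inconsistency
#' in the published rendering: the Vallicula-Pleurobrachia cell shows
#' BD 12 above the diagonal but BDn 0.77 (= 10/13) below it; the fixture
#' preserves both values verbatim.
#'
#' @return A list with `bd` (integer matrix, upper triangle mirrored),
#'   `bdn_printed` (numeric matrix from the lower triangle), `orders`
#'   (named taxonomic order per species), and `raw` (the character
#'   matrix as printed).
#' @export
published_bd_table <- function() {
  raw <- as.matrix(utils::read.delim(
    system.file("extdata", "ctenophora_bd.tsv", package = "ctenomito"),
    row.names = 1, stringsAsFactors = FALSE, check.names = FALSE))
  k <- nrow(raw)
  bd <- matrix(NA_integer_, k, k, dimnames = dimnames(raw))
  bdn <- matrix(NA_real_, k, k, dimnames = dimnames(raw))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) bd[i, j] <- bd[j, i] <- as.integer(raw[i, j])
    if (i > j) bdn[i, j] <- bdn[j, i] <- as.numeric(raw[i, j])
  }
  nc <- published_nc_stats()
  list(bd = bd, bdn_printed = bdn,
       orders = stats::setNames(nc$order, nc$species), raw = raw)
}
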