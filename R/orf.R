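# ORF scanning on circular genomes.
#
# These genomes encode everything on one strand ("all genes are
# transcribed clockwise"), so by default only the + strand is scanned;
# `scan_minus` turns on the reverse strand. Coordinates follow the
# internal 0-based half-open convention; an ORF crossing the origin of a
# circular genome has end > genome length.

#' Find maximal open reading frames
#'
#' Scans all three frames (plus strand by default), wrapping the origin on
#' circular genomes via a doubled-sequence pass deduplicated modulo the
#' genome length. A maximal ORF runs from the first allowed start codon
#' after the previous in-frame stop through its stop codon (included in
#' the span). All alternative in-frame start positions inside the ORF are
#' recorded for downstream boundary selection. The initiator codon is
#' translated as M regardless of which allowed start codon it is.
#'
#' @param genome A [MitoGenome()]; must contain no N.
#' @param code A [CodeTable()].
#' @param min_len Minimum ORF length in bp, stop codon included; ORFs of
#'   exactly `min_len` are kept.
#' @param scan_minus Also scan the reverse strand.
#' @return A list of `OrfCandidate` objects: fields `start`, `end`,
#'   `frame`, `strand`, `protein`, `stop_kind` (`"TAA"`, `"TAG"`,
#'   `"truncated"`), `candidate_starts`.
#' @export
find_orfs <- function(genome, code, min_len = 100L, scan_minus = FALSE) {
  stopifnot(inherits(genome, "MitoGenome"), inherits(code, "CodeTable"),
            min_len >= 3L)
  if (grepl("N", genome$sequence, fixed = TRUE))
    stop("genome ", genome$id, " contains unresolved bases (N); ",
         "ORF scanning requires a fully resolved sequence")
  out <- scan_orfs_strand(genome$sequence, genome$is_circular, code,
                          min_len, "+")
  if (scan_minus) {
    L <- genome$length
    rc <- scan_orfs_strand(revcomp(genome$sequence), genome$is_circular,
                           code, min_len, "-")
    # map reverse-strand coordinates back to the forward system: a
    # reverse-scan interval [s, e) corresponds to forward [L - e, L - s),
    # possibly wrapped.
    rc <- lapply(rc, function(o) {
      len <- o$end - o$start
      s <- (L - (o$end %% L)) %% L
      o$start <- as.integer(s)
      o$end <- as.integer(s + len)
      o$candidate_starts <- as.integer(sort((L - (o$candidate_starts %% L)) %% L))
      o
    })
    out <- c(out, rc)
  }
  out
}

scan_orfs_strand <- function(sq, circular, code, min_len, strand) {
  L <- nchar(sq)
  D <- if (circular) paste0(sq, sq) else sq
  nD <- nchar(D)
  res <- list()
  seen <- character(0)                        # dedupe key "start:len" mod L
  for (f in 0:2) {
    n_codons <- (nD - f) %/% 3L
    if (n_codons < 1L) next
    starts_bp <- f + 3L * (seq_len(n_codons) - 1L)     # 0-based codon starts
    codons <- substring(D, starts_bp + 1L, starts_bp + 3L)
    is_stop <- codons %in% code$stop_codons
    is_start <- codons %in% code$start_codons
    stop_idx <- which(is_stop)

    # Segments of codons that may host an ORF ending at stop seg_stop[k].
    # On a circle only segments preceded by an in-frame stop are maximal;
    # the doubled sequence guarantees every circular ORF occurs in one.
    if (circular) {
      if (length(stop_idx) < 2L) next
      seg_begin <- head(stop_idx, -1L) + 1L
      seg_stop <- stop_idx[-1L]
    } else {
      seg_begin <- c(1L, head(stop_idx, -1L) + 1L)
      seg_stop <- c(stop_idx, if (!length(stop_idx) || max(stop_idx) < n_codons)
        n_codons + 1L)                        # sentinel: truncated trailing run
      if (length(seg_stop) > length(seg_begin))
        seg_begin <- c(seg_begin, if (length(stop_idx)) max(stop_idx) + 1L else 1L)
    }

    for (k in seq_along(seg_begin)) {
      b <- seg_begin[k]; e <- seg_stop[k]
      truncated <- e > n_codons
      last_cod <- if (truncated) n_codons else e - 1L
      if (last_cod < b) next
      starts_in <- which(is_start[b:last_cod]) + b - 1L
      if (!length(starts_in)) next
      first <- starts_in[1L]
      orf_start <- starts_bp[first]
      orf_end <- if (truncated) starts_bp[last_cod] + 3L else starts_bp[e] + 3L
      len <- orf_end - orf_start
      if (circular && len > L) {
        warning("ORF at ", orf_start %% L, " exceeds genome length ",
                "without a stop; dropped")
        next
      }
      if (len < min_len) next
      cand <- starts_bp[starts_in]
      if (circular) {
        norm_start <- orf_start %% L
        key <- paste0(norm_start, ":", len)
        if (key %in% seen) next
        seen <- c(seen, key)
        cand <- (cand - orf_start) + norm_start   # keep starts unwrapped
        orf_start <- norm_start
        orf_end <- norm_start + len
      }
      if (truncated)
        warning("ORF at ", orf_start, " crosses the end of a linear ",
                "sequence; truncated")
      prot_cod <- codons[first:last_cod]
      prot <- paste(c("M", unname(code$codon_map[prot_cod[-1L]])),
                    collapse = "")
      res[[length(res) + 1L]] <- structure(list(
        start = as.integer(orf_start), end = as.integer(orf_end),
        frame = as.integer(orf_start %% 3L), strand = strand, protein = prot,
        stop_kind = if (truncated) "truncated" else codons[e],
        candidate_starts = as.integer(cand)),
        class = "OrfCandidate")
    }
  }
  res
}

#' @export
print.OrfCandidate <- function(x, ...) {
  cat(sprintf("OrfCandidate %d..%d (%s, frame %d), %d aa, stop %s\n",
              x$start, x$end, x$strand, x$frame, nchar(x$protein),
              x$stop_kind))
  invisible(x)
}
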