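# Homopolymer frame-shift repair from read evidence.
#
# AT-rich mitogenomes carry poly-T tracts that sequencers miscount; a
# missing or extra base there shifts the downstream reading frame. Within
# a small region, each homopolymer run is re-estimated as the majority run
# length among reads that fully span the run (anchored on both flanks),
# and the reference is edited when the majority disagrees with it.

#' Repair homopolymer frame shifts in a region using reads
#'
#' @param genome [MitoGenome()] to correct.
#' @param reads Character vector of read sequences (or the `seq` fields of
#'   a FASTQ collection from [read_fastq()]).
#' @param region Integer pair `c(start, end)`, 0-based half-open, at most
#'   500 bp wide.
#' @param min_run Minimum reference run length to interrogate (default 3).
#' @param flank Anchor width on each side of a run that a read must match
#'   exactly to count as spanning (default 5).
#' @return List with `genome` (edited [MitoGenome()]), `edits` (data frame
#'   with `position`, `base`, `old_len`, `new_len`, `n_spanning`,
#'   `applied`, `note`) and `status` (`"ok"`, `"no_edits"`, or
#'   `"uncorrectable"` when no run had spanning reads).
#' @export
repair_frameshift <- function(genome, reads, region, min_run = 3L,
                              flank = 5L) {
  if (is.list(reads)) reads <- vapply(reads, `[[`, "", "seq")
  stopifnot(length(region) == 2L, region[2] > region[1],
            region[2] - region[1] <= 500L, region[1] >= 0L,
            region[2] <= genome$length)
  sq <- genome$sequence
  reg <- substr(sq, region[1] + 1L, region[2])
  runs <- gregexpr("(A{3,}|C{3,}|G{3,}|T{3,})", reg)[[1]]
  edits <- data.frame(position = integer(), base = character(),
                      old_len = integer(), new_len = integer(),
                      n_spanning = integer(), applied = logical(),
                      note = character(), stringsAsFactors = FALSE)
  if (runs[1] == -1L)
    return(list(genome = genome, edits = edits, status = "no_edits"))
  lens <- attr(runs, "match.length")
  keep <- lens >= min_run
  run_start <- region[1] + as.integer(runs)[keep] - 1L   # 0-based in genome
  run_len <- lens[keep]
  any_spanning <- FALSE
  # collect evidence per run (coordinates still refer to the original genome)
  for (i in seq_along(run_start)) {
    s <- run_start[i]; n <- run_len[i]
    base <- substr(sq, s + 1L, s + 1L)
    left <- substr(sq, s - flank + 1L, s)
    right <- substr(sq, s + n + 1L, s + n + flank)
    if (nchar(left) < flank || nchar(right) < flank) next
    pat <- paste0(left, "(", base, "+)", right)
    counts <- integer(0)
    for (rd in reads) {
      m <- regexec(pat, rd)[[1]]
      if (m[1] == -1L) next
      counts <- c(counts, attr(m, "match.length")[2])
    }
    if (!length(counts)) {
      edits[nrow(edits) + 1L, ] <- list(s, base, n, NA_integer_, 0L,
                                        FALSE, "no spanning reads")
      next
    }
    any_spanning <- TRUE
    tab <- table(counts)
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) > 1L) {
      edits[nrow(edits) + 1L, ] <- list(s, base, n, NA_integer_,
                                        length(counts), FALSE,
                                        "tie among spanning reads")
      next
    }
    if (top == n) {
      edits[nrow(edits) + 1L, ] <- list(s, base, n, n, length(counts),
                                        FALSE, "reads agree with reference")
      next
    }
    edits[nrow(edits) + 1L, ] <- list(s, base, n, top, length(counts),
                                      TRUE,
                                      if (top > n) "insertion" else "deletion")
  }
  if (!any_spanning && nrow(edits) > 0L && !any(edits$applied))
    return(list(genome = genome, edits = edits, status = "uncorrectable"))
  # apply edits right-to-left so earlier coordinates stay valid
  todo <- edits[edits$applied, , drop = FALSE]
  if (nrow(todo)) {
    todo <- todo[order(-todo$position), , drop = FALSE]
    for (r in seq_len(nrow(todo))) {
      s <- todo$position[r]
      sq <- paste0(substr(sq, 1L, s),
                   strrep(todo$base[r], todo$new_len[r]),
                   substr(sq, s + todo$old_len[r] + 1L, nchar(sq)))
    }
    genome <- MitoGenome(genome$id, sq, genome$is_circular)
  }
  status <- if (any(edits$applied)) "ok" else "no_edits"
  list(genome = genome, edits = edits, status = status)
}
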