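# Iterative read-overlap contig elongation and circularization.
#
# The assembly contract for a mitogenome at deep coverage: reads whose
# prefix exactly matches the contig's suffix (or vice versa) over at
# least `min_overlap` bp vote, column by column, on the overhanging
# consensus; each productive round with fully overhanging reads of
# length R extends an end by at least R - min_overlap bp. When a suffix
# of the grown contig equals a prefix, the molecule is circular and the
# duplicated copy is trimmed.

#' Read a FASTQ file
#'
#' @param path FASTQ file (plain or gzip).
#' @return List of records, each a list with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (!length(lines)) return(list())
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4")
  n <- length(lines) %/% 4L
  lapply(seq_len(n), function(i) {
    id <- lines[4L * i - 3L]
    if (!startsWith(id, "@")) stop("malformed FASTQ record ", i)
    list(id = sub("^@", "", id), seq = toupper(lines[4L * i - 2L]),
         qual = lines[4L * i])
  })
}

#' Write a FASTQ file
#'
#' @param reads List of records as returned by [read_fastq()] or
#'   [simulate_reads()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (r in reads)
    writeLines(c(paste0("@", r$id), r$seq, "+",
                 r$qual %||% strrep("I", nchar(r$seq))), con)
  invisible(path)
}

#' Construct a contig
#'
#' @param sequence Nucleotide string.
#' @return An object of class `Contig` tracking rounds applied and bp
#'   gained on each end.
#' @export
Contig <- function(sequence) {
  structure(list(sequence = toupper(sequence), rounds_applied = 0L,
                 left_extended_bp = 0L, right_extended_bp = 0L),
            class = "Contig")
}

# Reads overlapping the right end of `sq`: a read prefix equals the
# contig suffix over >= min_overlap bp. Returns the overhanging strings.
right_overhangs <- function(sq, read_seqs, min_overlap) {
  seed <- substr(sq, nchar(sq) - min_overlap + 1L, nchar(sq))
  cand <- which(grepl(seed, read_seqs, fixed = TRUE))
  out <- character(0)
  for (k in cand) {
    rd <- read_seqs[k]
    hits <- gregexpr(seed, rd, fixed = TRUE)[[1]]
    for (h in hits) {
      ov <- h + min_overlap - 1L            # candidate overlap length
      if (ov >= nchar(rd)) next             # no overhang
      if (ov > nchar(sq)) next
      if (substr(sq, nchar(sq) - ov + 1L, nchar(sq)) == substr(rd, 1L, ov))
        out <- c(out, substr(rd, ov + 1L, nchar(rd)))
    }
  }
  out
}

# Majority consensus of a set of overhangs, column by column; stops at
# the first column where no base reaches 50% or coverage ends.
consensus_extension <- function(overhangs) {
  if (!length(overhangs)) return("")
  maxw <- max(nchar(overhangs))
  ext <- character(0)
  for (p in seq_len(maxw)) {
    col <- substr(overhangs, p, p)
    col <- col[col != ""]
    if (!length(col)) break
    tab <- table(col)
    top <- names(tab)[which.max(tab)]
    if (max(tab) / length(col) < 0.5) break  # conflicting consensus
    if (max(tab) / length(col) == 0.5 && sum(tab == max(tab)) > 1L) break
    ext <- c(ext, top)
  }
  paste(ext, collapse = "")
}

#' Extend a contig by iterative read overlap
#'
#' Per round, reads with an exact suffix-prefix overlap of at least
#' `min_overlap` bp against either contig end contribute their
#' overhanging bases; the extension is the column-wise majority
#' consensus, stopping at the first conflicted column. Rounds continue
#' until neither end grows or `max_rounds` is reached.
#'
#' @param contig A [Contig()] (or nucleotide string).
#' @param reads FASTQ collection (list with `seq` fields) or character
#'   vector of read sequences.
#' @param min_overlap Minimum exact overlap in bp (default 25).
#' @param max_rounds Maximum extension rounds (default 30).
#' @return The extended [Contig()].
#' @export
extend_contig <- function(contig, reads, min_overlap = 25L,
                          max_rounds = 30L) {
  if (is.character(contig)) contig <- Contig(contig)
  read_seqs <- if (is.list(reads)) vapply(reads, `[[`, "", "seq") else reads
  stopifnot(min_overlap >= 15L, all(nchar(read_seqs) >= min_overlap + 1L))
  rc_seqs <- NULL
  for (round in seq_len(max_rounds)) {
    grew <- FALSE
    # right end
    ext <- consensus_extension(
      right_overhangs(contig$sequence, read_seqs, min_overlap))
    if (nzchar(ext)) {
      contig$sequence <- paste0(contig$sequence, ext)
      contig$right_extended_bp <- contig$right_extended_bp + nchar(ext)
      grew <- TRUE
    }
    # left end: work on the reversed problem
    rev_ext <- consensus_extension(
      right_overhangs(str_reverse(contig$sequence),
                      vapply(read_seqs, str_reverse, ""), min_overlap))
    if (nzchar(rev_ext)) {
      contig$sequence <- paste0(str_reverse(rev_ext), contig$sequence)
      contig$left_extended_bp <- contig$left_extended_bp + nchar(rev_ext)
      grew <- TRUE
    }
    contig$rounds_applied <- contig$rounds_applied + 1L
    if (!grew) break
  }
  contig
}

str_reverse <- function(x)
  paste(rev(seq_chars(x)), collapse = "")

#' Detect circularity of a contig and trim the duplicated end
#'
#' If a suffix of length at least `min_end_overlap` exactly equals a
#' prefix, the molecule is circular: the duplicate copy is trimmed and a
#' circular genome returned. When several end-overlaps qualify the
#' longest is taken (with a warning), which collapses a contig that has
#' wrapped past one full turn down to a single copy of the circle.
#'
#' @param contig [Contig()] or nucleotide string.
#' @param min_end_overlap Minimum end match in bp (default 25).
#' @param id Identifier for the resulting genome.
#' @return List with `is_circular` and `genome` (a trimmed circular
#'   [MitoGenome()], or the untrimmed linear sequence).
#' @export
detect_circularity <- function(contig, min_end_overlap = 25L,
                               id = "contig") {
  sq <- if (inherits(contig, "Contig")) contig$sequence else contig
  M <- nchar(sq)
  stopifnot(M > 2L * min_end_overlap)
  matches <- integer(0)
  for (o in seq.int(M - 1L, min_end_overlap)) {
    if (substr(sq, 1L, o) == substr(sq, M - o + 1L, M))
      matches <- c(matches, o)
  }
  if (!length(matches))
    return(list(is_circular = FALSE,
                genome = MitoGenome(id, sq, is_circular = FALSE)))
  if (length(matches) > 1L)
    warning("multiple end-overlaps (", paste(matches, collapse = ", "),
            " bp); taking the longest")
  o <- max(matches)
  list(is_circular = TRUE,
       genome = MitoGenome(id, substr(sq, 1L, M - o), is_circular = TRUE))
}

#' Per-base coverage of a circular genome by exact read placement
#'
#' Each read is placed at every position where it matches the doubled
#' sequence exactly over its full length; depth accumulates on the
#' circle. Unplaceable reads are counted, not fatal.
#'
#' @param genome Circular [MitoGenome()].
#' @param reads FASTQ collection or character vector.
#' @return A `CoverageSummary`: `mean`, `sd` (population), `min`, `max`,
#'   `depth` (per-base vector), `n_unplaced`, `placed_bp`.
#' @export
coverage_stats <- function(genome, reads) {
  stopifnot(genome$is_circular)
  read_seqs <- if (is.list(reads)) vapply(reads, `[[`, "", "seq") else reads
  L <- genome$length
  D <- Biostrings::DNAString(paste0(genome$sequence, genome$sequence))
  depth <- integer(L)
  unplaced <- 0L; placed_bp <- 0
  for (rd in read_seqs) {
    m <- Biostrings::matchPattern(rd, D)
    starts <- Biostrings::start(m) - 1L
    starts <- unique(starts[starts < L] %% L)
    if (!length(starts)) { unplaced <- unplaced + 1L; next }
    w <- nchar(rd)
    for (s in starts) {
      pos <- (s + seq_len(w) - 1L) %% L + 1L
      depth[pos] <- depth[pos] + 1L
      placed_bp <- placed_bp + w
    }
  }
  structure(list(mean = mean(depth),
                 sd = sqrt(mean((depth - mean(depth))^2)),
                 min = min(depth), max = max(depth), depth = depth,
                 n_unplaced = unplaced, placed_bp = placed_bp),
            class = "CoverageSummary")
}

#' @export
print.CoverageSummary <- function(x, ...) {
  cat(sprintf("coverage %.0f (SD %.0f; range: %d-%d)\n",
              x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Find a seed contig region matching a bait sequence
#'
#' Exact k-mer seeding (default k = 21): reads sharing a k-mer with the
#' bait are assembled into a seed by taking the read with the most
#' bait k-mers. Abstracts the marker-gene search used to pick the
#' mitochondrial contig out of a mixed assembly.
#'
#' @param reads FASTQ collection or character vector.
#' @param bait Nucleotide string (e.g. a cox1 fragment).
#' @param k K-mer size (default 21).
#' @return The best-matching read sequence (the seed), or `NULL` when no
#'   read shares a k-mer with the bait.
#' @export
find_seed_by_bait <- function(reads, bait, k = 21L) {
  read_seqs <- if (is.list(reads)) vapply(reads, `[[`, "", "seq") else reads
  stopifnot(nchar(bait) >= k)
  kmers <- unique(substring(bait, 1:(nchar(bait) - k + 1L),
                            k:nchar(bait)))
  counts <- vapply(read_seqs, function(rd) {
    if (nchar(rd) < k) return(0L)
    rk <- substring(rd, 1:(nchar(rd) - k + 1L), k:nchar(rd))
    sum(rk %in% kmers)
  }, 0L)
  if (max(counts) == 0L) return(NULL)
  read_seqs[[which.max(counts)]]
}

#' Assemble a circular genome from a seed contig and reads
#'
#' Alternates extension rounds with a circularity check until the circle
#' closes or `max_rounds` is exhausted.
#'
#' @inheritParams extend_contig
#' @param min_end_overlap Passed to [detect_circularity()].
#' @param id Identifier for the assembled genome.
#' @return List with `is_circular`, `genome`, `contig`, `mates_concordant`
#'   (NA unless paired reads are supplied via `mates`).
#' @export
assemble_circular <- function(contig, reads, min_overlap = 25L,
                              max_rounds = 60L, min_end_overlap = 25L,
                              id = "assembly") {
  if (is.character(contig)) contig <- Contig(contig)
  for (round in seq_len(max_rounds)) {
    before <- nchar(contig$sequence)
    contig <- extend_contig(contig, reads, min_overlap, max_rounds = 1L)
    if (nchar(contig$sequence) > 2L * min_end_overlap) {
      circ <- detect_circularity(contig, min_end_overlap, id = id)
      if (circ$is_circular)
        return(list(is_circular = TRUE, genome = circ$genome,
                    contig = contig, rounds = round))
    }
    if (nchar(contig$sequence) == before) break
  }
  list(is_circular = FALSE,
       genome = MitoGenome(id, contig$sequence, is_circular = FALSE),
       contig = contig, rounds = contig$rounds_applied)
}
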