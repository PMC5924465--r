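# Per-genome statistics: base composition, codon usage, non-coding
# accounting (with and without URFs), genome-size ~ NC-length correlation,
# and perfect-repeat finding on the circularized sequence.

#' Base composition of a genome
#'
#' @param genome [MitoGenome()].
#' @return A `CompositionProfile`: list with `counts` (A,C,G,T,N),
#'   `percent`, `AT_percent`, `T_percent`, `length`.
#' @export
composition <- function(genome) {
  stopifnot(inherits(genome, "MitoGenome"), genome$length > 0L)
  ch <- seq_chars(genome$sequence)
  counts <- vapply(c("A", "C", "G", "T", "N"), function(b) sum(ch == b), 0L)
  pct <- 100 * counts / genome$length
  structure(list(counts = counts, percent = pct,
                 AT_percent = unname(pct["A"] + pct["T"]),
                 T_percent = unname(pct["T"]),
                 length = genome$length),
            class = "CompositionProfile")
}

#' @export
print.CompositionProfile <- function(x, ...) {
  cat(sprintf("%d bp; AT %.1f%% (T %.1f%%)\n", x$length, x$AT_percent,
              x$T_percent))
  invisible(x)
}

#' Codon usage over the protein genes of a genome
#'
#' Codons are tallied over protein features only (URFs optionally
#' included). The start codon of each gene is tallied separately, and
#' stop codons -- complete and incomplete -- form their own categories, so
#' the main table reflects internal codons.
#'
#' @param ann [AnnotationSet()].
#' @param genome [MitoGenome()].
#' @param code [CodeTable()] (used to aggregate by amino acid).
#' @param include_urfs Also tally URF features.
#' @return A `CodonUsageTable`: list with `codon` (data frame `codon`,
#'   `aa`, `count`, `percent`), `by_aa`, `starts`, `stops` (named counts;
#'   incomplete stops appear as `T.` / `TA.`).
#' @export
codon_usage <- function(ann, genome, code = get_code_table("mold"),
                        include_urfs = FALSE) {
  kinds <- if (include_urfs) c("protein", "URF") else "protein"
  feats <- Filter(function(f) f$kind %in% kinds, ann$features)
  internal <- character(0); starts <- character(0); stops <- character(0)
  for (f in feats) {
    nt <- extract_feature_sequence(genome, f)
    if (nchar(nt) < 6L) stop("protein feature ", f$label, " shorter than 6 bp")
    if (f$has_incomplete_stop) {
      tail_len <- nchar(nt) %% 3L
      if (tail_len == 0L) tail_len <- 3L  # treat a full trailing codon as given
      body <- substr(nt, 1L, nchar(nt) - tail_len)
      stops <- c(stops, paste0(substr(nt, nchar(nt) - tail_len + 1L,
                                      nchar(nt)), "."))
    } else {
      extra <- nchar(nt) %% 3L
      if (extra != 0L) {
        warning("feature ", f$label, " length not a multiple of 3; ",
                "trailing ", extra, " base(s) dropped")
        nt <- substr(nt, 1L, nchar(nt) - extra)
      }
      body <- substr(nt, 1L, nchar(nt) - 3L)
      stops <- c(stops, substr(nt, nchar(nt) - 2L, nchar(nt)))
    }
    starts <- c(starts, substr(body, 1L, 3L))
    if (nchar(body) > 3L)
      internal <- c(internal, codon_split(substr(body, 4L, nchar(body))))
  }
  all_codons <- names(code$codon_map)
  count <- vapply(all_codons, function(cd) sum(internal == cd), 0L)
  tot <- sum(count)
  df <- data.frame(codon = all_codons,
                   aa = unname(code$codon_map[all_codons]),
                   count = unname(count),
                   percent = if (tot > 0) 100 * unname(count) / tot else 0,
                   stringsAsFactors = FALSE)
  by_aa <- tapply(df$count, df$aa, sum)
  structure(list(codon = df,
                 by_aa = by_aa[order(names(by_aa))],
                 starts = table(starts), stops = table(stops),
                 total_codons = tot),
            class = "CodonUsageTable")
}

# 0/1 coverage of the circle by a set of features.
circle_coverage <- function(feats, L) {
  cov <- logical(L)
  for (f in feats)
    for (iv in unwrap_interval(f$start, f$end, L))
      if (iv[2] > iv[1]) cov[(iv[1] + 1L):iv[2]] <- TRUE
  cov
}

# Maximal uncovered tracts on the circle as 0-based half-open intervals
# (a tract spanning the origin counts once, with end > L).
nc_tracts <- function(cov) {
  L <- length(cov)
  if (all(cov)) return(list())
  if (!any(cov)) return(list(c(0L, L)))
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  iv <- Map(c, starts[!r$values], ends[!r$values])
  # merge a tract touching position L with one starting at 0 (origin wrap)
  n <- length(iv)
  if (n >= 1L && iv[[n]][2] == L && iv[[1]][1] == 0L && n > 1L) {
    iv[[n]] <- c(iv[[n]][1], L + iv[[1]][2])
    iv[[1]] <- NULL
  } else if (n == 1L && iv[[1]][1] == 0L && iv[[1]][2] == L) {
    # whole circle uncovered, already handled above
  }
  iv
}

#' Non-coding accounting for an annotated genome
#'
#' Non-coding sequence is the circular complement of the union of
#' annotated features, computed twice: with URFs treated as non-coding
#' ("with URFs" in the sense of NC totals that include URF bases) and
#' with URFs treated as coding ("without URFs"). Also reports the number
#' of NC tracts strictly longer than `tract_cutoff` bp and the longest
#' tract with its flanking gene labels.
#'
#' @param ann [AnnotationSet()].
#' @param genome [MitoGenome()].
#' @param tract_cutoff Tract-count threshold in bp (strict `>`,
#'   default 20).
#' @return An `NCProfile`: list with `genome_length`, `nc_with_urfs`,
#'   `nc_without_urfs`, `n_nc_gt_with`, `n_nc_gt_without`,
#'   `longest_with`, `longest_without` (each a list `bp`, `flanks`).
#' @export
summarize_noncoding <- function(ann, genome, tract_cutoff = 20L) {
  L <- genome$length
  coding_all <- Filter(function(f) f$kind %in% c("protein", "rRNA", "URF"),
                       ann$features)
  coding_non_urf <- Filter(function(f) f$kind != "URF", coding_all)
  one_side <- function(feats) {
    tracts <- nc_tracts(circle_coverage(feats, L))
    lens <- vapply(tracts, function(t) t[2] - t[1], 0L)
    total <- sum(lens)
    longest <- if (length(lens)) {
      t <- tracts[[which.max(lens)]]
      list(bp = max(lens), flanks = tract_flanks(t, feats, L))
    } else list(bp = 0L, flanks = c(NA_character_, NA_character_))
    list(total = total, n_gt = sum(lens > tract_cutoff), longest = longest)
  }
  with_urfs <- one_side(coding_non_urf)    # URFs counted as non-coding
  without_urfs <- one_side(coding_all)     # URFs counted as coding
  structure(list(genome_length = L,
                 nc_with_urfs = with_urfs$total,
                 nc_without_urfs = without_urfs$total,
                 n_nc_gt_with = with_urfs$n_gt,
                 n_nc_gt_without = without_urfs$n_gt,
                 longest_with = with_urfs$longest,
                 longest_without = without_urfs$longest),
            class = "NCProfile")
}

# Labels of the features flanking a non-coding tract in genomic order.
tract_flanks <- function(tract, feats, L) {
  if (!length(feats)) return(c(NA_character_, NA_character_))
  starts <- vapply(feats, `[[`, 0L, "start")
  ends <- vapply(feats, `[[`, 0L, "end") %% L
  labs <- vapply(feats, `[[`, "", "label")
  d_up <- (tract[1] - ends) %% L          # feature ending at tract start
  d_dn <- (starts - (tract[2] %% L)) %% L # feature starting at tract end
  c(labs[which.min(d_up)], labs[which.min(d_dn)])
}

#' Non-coding proportion of a genome
#'
#' @param nc_len Non-coding length in bp.
#' @param genome_len Genome length in bp.
#' @return Percentage (full precision); use one-decimal display rounding
#'   for tables.
#' @export
nc_percent <- function(nc_len, genome_len) {
  stopifnot(genome_len > 0, nc_len >= 0, nc_len <= genome_len)
  100 * nc_len / genome_len
}

#' Pearson correlation of genome size and non-coding length
#'
#' @param rows Data frame or matrix with two columns: genome length and
#'   NC length (at least 3 rows, non-constant).
#' @return Sample Pearson correlation coefficient (full precision).
#' @export
size_nc_correlation <- function(rows) {
  rows <- as.data.frame(rows)
  stopifnot(ncol(rows) >= 2L, nrow(rows) >= 3L)
  x <- rows[[1]]; y <- rows[[2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant column")
  stats::cor(x, y)
}

## ---- perfect repeats ----------------------------------------------------

# Shannon entropy (bits) of the dinucleotide composition of a unit.
dinucleotide_entropy <- function(unit) {
  n <- nchar(unit)
  if (n < 2L) return(0)
  di <- substring(unit, 1:(n - 1L), 2:n)
  p <- table(di) / length(di)
  -sum(p * log2(p))
}

#' Find perfect repeats on a circularized genome
#'
#' Reports maximal exact repeated substrings of length at least
#' `min_unit` occurring at two or more distinct circular positions. For
#' every pair of occurrences the common substring is extended left and
#' right until it breaks; pairs sharing an identical maximal unit are
#' merged into one hit. Units whose dinucleotide Shannon entropy falls
#' below `entropy_cutoff` bits are flagged low-complexity and suppressed
#' when `filter_low_complexity` is on (poly-T tracts are the typical
#' casualty).
#'
#' @param genome [MitoGenome()].
#' @param min_unit Minimum unit length in bp (`>=`; to reproduce a
#'   "longer than 20 bp" search pass 21).
#' @param filter_low_complexity Suppress low-complexity units.
#' @param entropy_cutoff Dinucleotide entropy threshold in bits
#'   (default 1.5).
#' @return List of `RepeatHit` objects: `unit`, `unit_length`,
#'   `positions` (0-based starts on the circle), `separation` (bp between
#'   consecutive occurrences), `low_complexity`.
#' @export
find_perfect_repeats <- function(genome, min_unit = 21L,
                                 filter_low_complexity = FALSE,
                                 entropy_cutoff = 1.5) {
  stopifnot(min_unit >= 2L)
  L <- genome$length
  if (min_unit > L) return(list())
  sq <- genome$sequence
  # candidate position pairs from shared k-mer seeds (k = min_unit)
  D <- if (genome$is_circular) paste0(sq, substr(sq, 1L, min(min_unit - 1L, L)))
       else sq
  n_kmers <- nchar(D) - min_unit + 1L
  if (n_kmers < 2L) return(list())
  kmers <- substring(D, 1:n_kmers, min_unit:(n_kmers + min_unit - 1L))
  starts0 <- 0:(n_kmers - 1L)
  keep <- starts0 < L | !genome$is_circular
  kmers <- kmers[keep]; starts0 <- starts0[keep]
  dup_groups <- split(starts0, kmers)
  dup_groups <- dup_groups[lengths(dup_groups) >= 2L]
  if (!length(dup_groups)) return(list())
  pairs <- unique(do.call(rbind, lapply(dup_groups, function(p) {
    t(utils::combn(sort(p), 2L))
  })))
  hits <- new.env()
  circular <- genome$is_circular
  char_at <- function(pos) substr(sq, (pos %% L) + 1L, (pos %% L) + 1L)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (circular && (j - i) %% L == 0L) next
    # maximal common extension around the shared seed; on a circle the
    # unit is capped at L - 1 bp so periodic sequences terminate
    li <- i; lj <- j; len <- min_unit
    repeat {
      if (circular) { if (len >= L - 1L) break }
      else if (li == 0L || lj == 0L) break
      if (char_at(li - 1L) != char_at(lj - 1L)) break
      li <- li - 1L; lj <- lj - 1L; len <- len + 1L
    }
    repeat {
      if (circular) { if (len >= L - 1L) break }
      else if (lj + len >= L) break
      if (char_at(li + len) != char_at(lj + len)) break
      len <- len + 1L
    }
    unit <- circ_substr(sq, li, len)
    positions <- sort(unique(c(li %% L, lj %% L)))
    if (!is.null(hits[[unit]])) {
      hits[[unit]]$positions <- sort(unique(c(hits[[unit]]$positions,
                                              positions)))
    } else {
      hits[[unit]] <- list(unit = unit, positions = positions)
    }
  }
  out <- lapply(ls(hits), function(k) {
    h <- hits[[k]]
    pos <- h$positions
    sep <- if (length(pos) >= 2L) diff(pos) else integer(0)
    structure(list(unit = h$unit, unit_length = nchar(h$unit),
                   positions = pos, separation = sep,
                   low_complexity = dinucleotide_entropy(h$unit) < entropy_cutoff),
              class = "RepeatHit")
  })
  if (filter_low_complexity)
    out <- Filter(function(h) !h$low_complexity, out)
  out[order(-vapply(out, `[[`, 0L, "unit_length"))]
}

# Substring of length `len` starting at 0-based `start`, wrapping on the
# circle when needed.
circ_substr <- function(sq, start, len) {
  L <- nchar(sq)
  start <- start %% L
  if (start + len <= L) return(substr(sq, start + 1L, start + len))
  paste0(substr(sq, start + 1L, L), substr(sq, 1L, start + len - L))
}

#' @export
print.RepeatHit <- function(x, ...) {
  cat(sprintf("Repeat %d bp at %s%s\n", x$unit_length,
              paste(x$positions, collapse = ", "),
              if (x$low_complexity) " (low complexity)" else ""))
  invisible(x)
}
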