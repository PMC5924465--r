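# Containers and file formats.
#
# Internal coordinates are 0-based half-open throughout. On a circular
# genome a feature may span the origin, in which case end > genome length
# and the feature occupies [start, length) plus [0, end - length). GenBank
# flatfiles use 1-based inclusive locations with join() for origin spans;
# conversion happens only at the I/O boundary.

CANONICAL_LABELS <- c("cox1", "cox2", "cox3", "cob",
                      paste0("nad", 1:6), "nad4L", "rns", "rnl")

#' Construct a mitochondrial genome object
#'
#' A `MitoGenome` is a single nucleotide sequence over {A,C,G,T,N} with a
#' topology flag. Compact animal mitochondrial genomes are circular; the
#' flag controls whether features and scans may wrap the origin.
#'
#' @param id Sequence identifier.
#' @param sequence Nucleotide string; lowercase is accepted and
#'   canonicalised to uppercase.
#' @param is_circular Logical topology flag.
#' @return An object of class `MitoGenome` with fields `id`, `sequence`,
#'   `is_circular` and `length`.
#' @export
MitoGenome <- function(id, sequence, is_circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L,
            is.logical(is_circular), length(is_circular) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("MitoGenome '", id, "': empty sequence")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L)
    stop("MitoGenome '", id, "': illegal character '",
         substr(sequence, bad, bad), "' at position ", bad)
  structure(list(id = id, sequence = sequence,
                 is_circular = is_circular, length = nchar(sequence)),
            class = "MitoGenome")
}

#' @export
print.MitoGenome <- function(x, ...) {
  cat(sprintf("MitoGenome %s: %d bp, %s\n", x$id, x$length,
              if (x$is_circular) "circular" else "linear"))
  invisible(x)
}

#' Construct a gene feature on circular coordinates
#'
#' @param label Gene name (`cox1`..`cox3`, `cob`, `nad1`..`nad6`, `nad4L`,
#'   `rns`, `rnl`, or `urfN` for unidentified reading frames).
#' @param start,end 0-based half-open interval; `end` may exceed the genome
#'   length to encode an origin-spanning feature.
#' @param strand `"+"` or `"-"`.
#' @param kind One of `"protein"`, `"rRNA"`, `"URF"`.
#' @param has_incomplete_stop Logical; `TRUE` when the gene terminates on a
#'   partial stop codon (T or TA) completed by polyadenylation.
#' @return An object of class `GeneFeature`.
#' @export
GeneFeature <- function(label, start, end, strand = "+",
                        kind = c("protein", "rRNA", "URF"),
                        has_incomplete_stop = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.character(label), length(label) == 1L,
            start >= 0, end > start, strand %in% c("+", "-"))
  structure(list(label = label, start = as.integer(start),
                 end = as.integer(end), strand = strand, kind = kind,
                 has_incomplete_stop = isTRUE(has_incomplete_stop)),
            class = "GeneFeature")
}

feature_length <- function(f) f$end - f$start

is_origin_spanning <- function(f, genome_length) f$end > genome_length

#' Construct an annotation set
#'
#' An ordered collection of [GeneFeature()]s on one genome, kept sorted by
#' start coordinate. Each canonical gene label may appear at most once.
#'
#' @param genome_id Identifier of the annotated genome.
#' @param features List of [GeneFeature()] objects.
#' @return An object of class `AnnotationSet`.
#' @export
AnnotationSet <- function(genome_id, features = list()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, is.list(features))
  for (f in features)
    if (!inherits(f, "GeneFeature")) stop("features must be GeneFeature objects")
  labs <- vapply(features, `[[`, "", "label")
  dup <- labs[labs %in% CANONICAL_LABELS][duplicated(labs[labs %in% CANONICAL_LABELS])]
  if (length(dup))
    stop("duplicate canonical label(s): ", paste(unique(dup), collapse = ", "))
  if (length(features)) {
    ord <- order(vapply(features, `[[`, 0L, "start"),
                 vapply(features, `[[`, 0L, "end"), labs)
    features <- features[ord]
  }
  structure(list(genome_id = genome_id, features = features),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet for %s: %d feature(s)\n",
              x$genome_id, length(x$features)))
  for (f in x$features)
    cat(sprintf("  %-6s %6d..%-6d %s %s%s\n", f$label, f$start, f$end,
                f$strand, f$kind,
                if (f$has_incomplete_stop) " (incomplete stop)" else ""))
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' Headers carrying a `circular` token (word match, case-insensitive) mark
#' the record as circular; all other records default to linear.
#'
#' @param path FASTA file.
#' @return A list of [MitoGenome()] objects (empty for an empty file).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(list())
  set <- Biostrings::readBStringSet(path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    id <- strsplit(header, "[ \t]+")[[1]][1]
    if (is.na(id) || !nzchar(id))
      stop("malformed FASTA header at record ", i)
    circ <- grepl("\\bcircular\\b", header, ignore.case = TRUE)
    sq <- toupper(as.character(set[[i]]))
    bad <- regexpr("[^ACGTN]", sq)
    if (bad > 0L)
      stop("record '", id, "': illegal character '", substr(sq, bad, bad),
           "' at position ", bad)
    out[[i]] <- MitoGenome(id, sq, is_circular = circ)
  }
  out
}

#' Write genomes to a FASTA file
#'
#' Sequences are wrapped at 70 columns; circular genomes carry a
#' `circular` token in the header so topology survives a round trip.
#'
#' @param genomes A [MitoGenome()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "MitoGenome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, function(g)
    if (g$is_circular) paste(g$id, "circular") else g$id, "")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

## ---- GenBank flatfile dialect -------------------------------------------

# Parse a GenBank location string into (start, end, strand) in internal
# 0-based half-open coordinates. join(x..len,1..y) on a circular genome
# becomes one origin-spanning interval (start = x-1, end = len + y).
parse_gb_location <- function(loc, genome_length, feature_desc = loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  m <- regmatches(loc, regexec("^complement\\((.*)\\)$", loc))[[1]]
  if (length(m)) { strand <- "-"; loc <- m[2] }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    iv <- lapply(parts, parse_gb_span)
    if (length(iv) != 2L ||
        iv[[1]][2] != genome_length || iv[[2]][1] != 1L)
      stop("unresolvable location '", feature_desc,
           "': only origin-spanning join(x..len,1..y) is supported")
    return(list(start = iv[[1]][1] - 1L,
                end = genome_length + iv[[2]][2], strand = strand))
  }
  iv <- parse_gb_span(loc, feature_desc)
  list(start = iv[1] - 1L, end = iv[2], strand = strand)
}

parse_gb_span <- function(x, feature_desc = x) {
  m <- regmatches(x, regexec("^([0-9]+)\\.\\.([0-9]+)$", x))[[1]]
  if (length(m) == 3L) return(c(as.integer(m[2]), as.integer(m[3])))
  if (grepl("^[0-9]+$", x)) { p <- as.integer(x); return(c(p, p)) }
  stop("unresolvable location '", feature_desc, "'")
}

format_gb_location <- function(f, genome_length) {
  if (is_origin_spanning(f, genome_length))
    loc <- sprintf("join(%d..%d,1..%d)", f$start + 1L, genome_length,
                   f$end - genome_length)
  else
    loc <- sprintf("%d..%d", f$start + 1L, f$end)
  if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Read a GenBank flatfile
#'
#' Accepts the compact mitogenome dialect: a LOCUS line carrying the
#' topology, a FEATURES table with `CDS` and `rRNA` entries (plain spans,
#' `complement()`, and origin-spanning `join(x..len,1..y)` locations), and
#' an ORIGIN sequence block. 1-based inclusive locations are converted to
#' the internal 0-based half-open convention.
#'
#' @param path GenBank flatfile.
#' @return A list with elements `genome` ([MitoGenome()]) and `annotation`
#'   ([AnnotationSet()]).
#' @export
read_genbank <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("format error: missing LOCUS line")
  toks <- strsplit(trimws(locus[1]), "[ \t]+")[[1]]
  id <- toks[2]
  len <- as.integer(toks[grep("^[0-9]+$", toks)[1]])
  circular <- grepl("\\bcircular\\b", locus[1], ignore.case = TRUE)

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("format error: missing ORIGIN block")
  term <- grep("^//", lines)
  term <- if (length(term)) term[term > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(term - 1L)]
  sequence <- toupper(gsub("[0-9 \t]", "", paste(seq_lines, collapse = "")))

  feats <- list()
  fstart <- grep("^FEATURES", lines)
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    # Fold continuation lines (21 leading spaces, no key) onto their entry.
    entries <- list(); cur <- NULL
    for (ln in block) {
      if (grepl("^ {5}[A-Za-z]", ln)) {
        if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
        cur <- ln
      } else if (!is.null(cur)) {
        cur <- c(cur, ln)
      }
    }
    if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
    for (e in entries) {
      key <- sub("^ +([A-Za-z_0-9']+).*$", "\\1", e[1])
      if (!key %in% c("CDS", "rRNA", "misc_feature")) next
      # location may continue over lines until the first qualifier
      qual_at <- grep("^ +/", e)
      loc_lines <- if (length(qual_at)) e[seq_len(qual_at[1] - 1L)] else e
      loc <- gsub(" ", "", sub("^ +[A-Za-z_0-9']+ +", "", paste(loc_lines, collapse = "")))
      quals <- grep("^ +/", e, value = TRUE)
      getq <- function(name) {
        hit <- grep(paste0("^ +/", name, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("\"", "", sub(paste0("^ +/", name, "="), "", hit[1]))
      }
      label <- getq("gene")
      if (is.na(label)) label <- getq("product")
      if (is.na(label)) label <- key
      pos <- parse_gb_location(loc, len, paste(key, loc))
      kind <- if (key == "rRNA") "rRNA"
              else if (grepl("^urf", label, ignore.case = TRUE)) "URF"
              else "protein"
      incomplete <- any(grepl("^ +/transl_except=", quals))
      if (pos$end > len && !circular)
        stop("feature ", label, " wraps the origin of a linear genome")
      feats[[length(feats) + 1L]] <-
        GeneFeature(label, pos$start, pos$end, pos$strand, kind,
                    has_incomplete_stop = incomplete)
    }
  }
  genome <- MitoGenome(id, sequence, is_circular = circular)
  if (genome$length != len)
    warning("LOCUS length ", len, " differs from ORIGIN length ", genome$length)
  list(genome = genome, annotation = AnnotationSet(id, feats))
}

#' Write a GenBank flatfile
#'
#' Emits the same dialect [read_genbank()] accepts, so a write/read round
#' trip reproduces the sequence bit-exactly and every feature coordinate
#' identically. Origin-spanning features become `join(x..len,1..y)`
#' locations; incomplete stop codons are recorded as a `/transl_except`
#' qualifier.
#'
#' @param genome A [MitoGenome()].
#' @param ann An [AnnotationSet()] whose features fit the genome.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, ann, path) {
  stopifnot(inherits(genome, "MitoGenome"), inherits(ann, "AnnotationSet"))
  L <- genome$length
  for (f in ann$features) {
    if (f$start >= L || f$end > 2L * L)
      stop("feature ", f$label, " lies beyond wrapped bounds of ", genome$id)
    if (f$end > L && !genome$is_circular)
      stop("feature ", f$label, " wraps the origin of a linear genome")
  }
  con <- file(path, "w"); on.exit(close(con))
  topo <- if (genome$is_circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s UNK 01-JAN-2000",
                     genome$id, L, topo), con)
  writeLines(sprintf("DEFINITION  %s mitochondrial genome.", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (f in ann$features) {
    key <- if (f$kind == "rRNA") "rRNA" else "CDS"
    writeLines(sprintf("     %-15s %s", key, format_gb_location(f, L)), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$label), con)
    if (f$kind == "URF")
      writeLines("                     /note=\"unidentified reading frame\"", con)
    if (f$has_incomplete_stop) {
      stop_at <- format_gb_location(
        GeneFeature(f$label, max(f$end - 2L, f$start), f$end, f$strand, f$kind), L)
      writeLines(sprintf(
        "                     /transl_except=(pos:%s,aa:TERM)", stop_at), con)
      writeLines("                     /note=\"incomplete stop codon\"", con)
    }
  }
  writeLines("ORIGIN", con)
  sq <- tolower(genome$sequence)
  i <- 1L
  while (i <= L) {
    chunk <- substr(sq, i, min(i + 59L, L))
    groups <- codon_groups_of_ten(chunk)
    writeLines(sprintf("%9d %s", i, groups), con)
    i <- i + 60L
  }
  writeLines("//", con)
  invisible(path)
}

codon_groups_of_ten <- function(chunk) {
  starts <- seq.int(1L, nchar(chunk), by = 10L)
  paste(substring(chunk, starts, pmin(starts + 9L, nchar(chunk))), collapse = " ")
}

#' Extract a feature's nucleotide sequence
#'
#' Wraps across the origin for origin-spanning features on circular
#' genomes and reverse-complements minus-strand features.
#'
#' @param genome A [MitoGenome()].
#' @param f A [GeneFeature()].
#' @return Nucleotide string of length `end - start`.
#' @export
extract_feature_sequence <- function(genome, f) {
  L <- genome$length
  if (f$end > L) {
    if (!genome$is_circular)
      stop("feature ", f$label, " wraps the origin but genome ", genome$id,
           " is linear")
    if (f$end - L > f$start)
      stop("feature ", f$label, " wraps more than once around the genome")
    s <- paste0(substr(genome$sequence, f$start + 1L, L),
                substr(genome$sequence, 1L, f$end - L))
  } else {
    s <- substr(genome$sequence, f$start + 1L, f$end)
  }
  if (f$strand == "-") s <- revcomp(s)
  s
}
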