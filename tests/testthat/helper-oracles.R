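# Independent oracles and small fixture builders used across tests.

# Brute-force directed circular breakpoint distance.
brute_bd <- function(a, b) {
  adj <- function(v) {
    n <- length(v)
    paste(v, v[c(2:n, 1L)], sep = ">")
  }
  sum(!(adj(a) %in% adj(b)))
}

# Number of conserved adjacencies between two circular orders.
brute_conserved <- function(a, b) length(a) - brute_bd(a, b)

# Brute-force maximal pairwise repeats on a LINEAR string: for every
# pair of start positions, extend the common substring left and right by
# direct substring comparison; collect units of length >= min_unit,
# grouped by unit string with the union of occurrence starts (0-based).
brute_repeats <- function(sq, min_unit) {
  L <- nchar(sq)
  ch <- strsplit(sq, "")[[1]]
  units <- list()
  for (i in 0:(L - 2L)) for (j in (i + 1L):(L - 1L)) {
    # maximal common extension at offset pair (i, j)
    if (ch[i + 1L] != ch[j + 1L]) next
    li <- i; lj <- j
    while (li > 0L && lj > 0L && ch[li] == ch[lj]) { li <- li - 1L; lj <- lj - 1L }
    len <- 1L
    while (lj + len < L && ch[li + len + 1L] == ch[lj + len + 1L]) len <- len + 1L
    if (len < min_unit) next
    if (li < i) next   # not left-maximal at this pair; counted at (li, lj)
    unit <- substr(sq, li + 1L, li + len)
    key <- unit
    units[[key]] <- sort(unique(c(units[[key]], li, lj)))
  }
  units
}

# Two-pass textbook Pearson correlation.
brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# A random circular permutation of n labelled genes.
random_order <- function(n, id = "o") GeneOrder(id, sample(letters[1:n]))

# Hand-built OrfCandidate (the class is a plain list).
orf_candidate <- function(start, end, protein, strand = "+",
                          stop_kind = "TAA",
                          candidate_starts = start) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 frame = as.integer(start %% 3L), strand = strand,
                 protein = protein, stop_kind = stop_kind,
                 candidate_starts = as.integer(candidate_starts)),
            class = "OrfCandidate")
}

# Small random genome for round-trip tests.
random_genome <- function(id, len, circular = TRUE) {
  MitoGenome(id, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                              prob = c(0.24, 0.08, 0.08, 0.60)),
                       collapse = ""),
             is_circular = circular)
}

# Compact study spec used where many genomes are simulated.
compact_spec <- function(seed, ...) {
  genome_spec(gene_models = COMPACT_GENE_MODELS,
              urf_aa_lens = c(60L),
              nc_tract_lengths = c(60L, 30L, 15L, 8L),
              seed = seed, ...)
}
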