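# Synthetic mitogenome generator.
#
# Emulates the statistical structure of tiny ctenophore-like mt genomes:
# ~84% AT with T near 60% of all nucleotides, 13 canonical single-strand
# genes (11 proteins + 2 rRNAs) on a circle, URFs with a hydrophobic
# stretch, short non-coding tracts carrying poly-T runs, and optionally a
# planted perfect repeat. Every planted property is recorded in a truth
# ledger so downstream analyses can be verified without re-derivation.

DEFAULT_GENE_MODELS <- data.frame(
  label = c("cox1", "cox2", "nad4", "nad4L", "nad1", "cob", "cox3",
            "nad3", "rnl", "rns", "nad5", "nad2", "nad6"),
  kind = c("protein", "protein", "protein", "protein", "protein",
           "protein", "protein", "protein", "rRNA", "rRNA", "protein",
           "protein", "protein"),
  # protein lengths in aa (excluding stop); rRNA lengths in nt
  len = c(500L, 220L, 450L, 95L, 290L, 360L, 250L, 115L, 840L, 400L,
          550L, 330L, 165L),
  stringsAsFactors = FALSE)

#' Compact variant of the 13-gene model set (same genes and circular
#' order, proteins and rRNAs shortened ~2.5-fold) for simulation studies
#' where many genomes are generated; annotation behaves identically but
#' alignment costs drop with the squared sequence length.
#' @export
COMPACT_GENE_MODELS <- local({
  m <- DEFAULT_GENE_MODELS
  m$len <- as.integer(c(200, 90, 180, 60, 120, 150, 100, 50, 340, 160,
                        220, 130, 70))
  m
})

#' Specification for a synthetic mitogenome
#'
#' Defaults emulate the observed genomes: ~84% AT, T about 60% of all
#' nucleotides, 11 protein genes and 2 rRNAs on one strand of an
#' ~11.5 kb circle, 2 URFs with a planted transmembrane stretch, and
#' non-coding tracts with poly-T runs.
#'
#' @param gene_models Data frame with columns `label`, `kind`
#'   (`protein`/`rRNA`) and `len` (aa for proteins, nt for rRNAs), in the
#'   desired circular order.
#' @param at_fraction,t_fraction Target AT fraction and T fraction of all
#'   nucleotides.
#' @param urf_aa_lens Protein lengths of the URFs to plant (aa).
#' @param nc_tract_lengths Lengths (bp) of non-coding tracts interleaved
#'   between features.
#' @param planted_repeat `NULL`, or `list(unit_len =, separation =)` for
#'   a perfect repeat planted in two dedicated non-coding tracts.
#' @param origin_shift Rotate the finished circle left by this many bp so
#'   that a feature can span the origin (0 keeps the natural origin).
#' @param proteins Optional named amino-acid vector of ortholog proteins
#'   (keyed by gene label); matching genes are reverse-translated with
#'   AT-biased synonymous codon choice instead of sampled, so several
#'   genomes can share identical orthologs (as congeneric species do).
#' @param rnas Optional named nucleotide vector of ortholog rRNAs.
#' @param code [CodeTable()] used for coding segments.
#' @param seed Integer seed; the generator is deterministic given the
#'   spec.
#' @return A `GenomeSpec` list.
#' @export
genome_spec <- function(gene_models = DEFAULT_GENE_MODELS,
                        at_fraction = 0.84, t_fraction = 0.60,
                        urf_aa_lens = c(100L, 60L),
                        nc_tract_lengths = c(120L, 60L, 40L, 25L, 15L,
                                             10L, 8L, 5L),
                        planted_repeat = NULL, origin_shift = 0L,
                        proteins = NULL, rnas = NULL,
                        code = get_code_table("mold"), seed = 1L) {
  stopifnot(at_fraction > 0, at_fraction < 1, t_fraction > 0,
            t_fraction <= at_fraction,
            all(gene_models$kind %in% c("protein", "rRNA")))
  structure(list(gene_models = gene_models, at_fraction = at_fraction,
                 t_fraction = t_fraction, urf_aa_lens = urf_aa_lens,
                 nc_tract_lengths = nc_tract_lengths,
                 planted_repeat = planted_repeat,
                 origin_shift = as.integer(origin_shift),
                 proteins = proteins, rnas = rnas, code = code,
                 seed = as.integer(seed)),
            class = "GenomeSpec")
}

base_probs <- function(spec) {
  at <- spec$at_fraction; t <- spec$t_fraction
  gc <- 1 - at
  c(T = t, A = at - t, C = gc / 2, G = gc / 2)
}

sample_bases <- function(n, p) {
  sample(names(p), n, replace = TRUE, prob = p)
}

# Sample n sense codons (no stop) under the spec's code.
sample_codons <- function(n, p, code) {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste0(sample_bases(n, p), sample_bases(n, p), sample_bases(n, p))
    cand <- cand[!cand %in% code$stop_codons]
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

HYDROPHOBIC_CODONS <- c("TTA", "ATT", "TTT", "GTT", "ATA")  # L I F V I

# Reverse-translate a protein (leading M stands for whichever start codon
# is drawn) choosing synonymous codons with AT-biased weights.
reverse_translate <- function(protein, p, code) {
  aas <- seq_chars(protein)
  start <- sample(c("ATT", "ATG", "ATA", "TTA"), 1L,
                  prob = c(0.4, 0.4, 0.15, 0.05))
  sense <- names(code$codon_map)[code$codon_map != "*"]
  codon_weight <- vapply(sense, function(cd) {
    prod(p[seq_chars(cd)])
  }, 0)
  body <- vapply(aas[-1L], function(a) {
    cands <- sense[code$codon_map[sense] == a]
    if (!length(cands)) stop("no codon for residue '", a, "'")
    if (length(cands) == 1L) cands else
      sample(cands, 1L, prob = codon_weight[cands])
  }, "")
  stop_codon <- sample(c("TAA", "TAG"), 1L, prob = c(0.9, 0.1))
  list(nt = paste(c(start, body, stop_codon), collapse = ""),
       protein = protein)
}

# A coding segment for a protein of `aa_len` residues (start codon
# included); returns the nucleotide string and the protein as the
# annotator will see it (initiator rendered M).
make_cds <- function(aa_len, p, code, tm_stretch = FALSE) {
  start <- sample(c("ATT", "ATG", "ATA", "TTA"), 1L,
                  prob = c(0.4, 0.4, 0.15, 0.05))
  body <- sample_codons(aa_len - 1L, p, code)
  if (tm_stretch && aa_len >= 25L) {
    at <- sample(seq_len(aa_len - 1L - 21L), 1L)
    body[at:(at + 20L)] <- sample(HYDROPHOBIC_CODONS, 21L, replace = TRUE)
  }
  stop_codon <- sample(c("TAA", "TAG"), 1L, prob = c(0.9, 0.1))
  nt <- paste(c(start, body, stop_codon), collapse = "")
  prot <- paste0("M", paste(unname(code$codon_map[body]), collapse = ""))
  list(nt = nt, protein = prot)
}

# Non-coding tract of `len` bp with a poly-T run when it fits.
make_nc <- function(len, p) {
  if (len <= 0L) return("")
  s <- sample_bases(len, p)
  if (len >= 8L) {
    run <- min(len - 2L, sample(6:12, 1L))
    at <- sample(seq_len(len - run + 1L), 1L)
    s[at:(at + run - 1L)] <- "T"
  }
  paste(s, collapse = "")
}

#' Generate a synthetic mitogenome with truth ledger
#'
#' @param spec A [genome_spec()].
#' @param id Genome identifier.
#' @return List with `genome` ([MitoGenome()]), `annotation`
#'   ([AnnotationSet()]) and `ledger` (planted gene order, proteins,
#'   rRNA sequences, URFs, NC tracts, repeat coordinates, spec echo).
#' @export
generate_genome <- function(spec, id = "synthetic") {
  stopifnot(inherits(spec, "GenomeSpec"))
  with_seed(spec$seed, {
    p <- base_probs(spec)
    gm <- spec$gene_models
    segments <- list()   # list of (type, label, kind, nt, protein)
    add_seg <- function(type, label, kind, nt, protein = NULL)
      segments[[length(segments) + 1L]] <<-
        list(type = type, label = label, kind = kind, nt = nt,
             protein = protein)

    # interleave features with NC tracts (recycled over the gaps)
    ncs <- spec$nc_tract_lengths
    urfs_todo <- length(spec$urf_aa_lens)
    urf_slots <- if (urfs_todo)
      sort(sample(seq_len(nrow(gm)), urfs_todo)) else integer(0)
    nc_i <- 0L
    for (g in seq_len(nrow(gm))) {
      row <- gm[g, ]
      if (row$kind == "protein") {
        cds <- if (!is.null(spec$proteins) && row$label %in% names(spec$proteins))
          reverse_translate(spec$proteins[[row$label]], p, spec$code)
        else make_cds(row$len, p, spec$code)
        add_seg("feature", row$label, "protein", cds$nt, cds$protein)
      } else {
        rna_nt <- if (!is.null(spec$rnas) && row$label %in% names(spec$rnas))
          spec$rnas[[row$label]]
        else paste(sample_bases(row$len, p), collapse = "")
        add_seg("feature", row$label, "rRNA", rna_nt)
      }
      if (g %in% urf_slots) {
        k <- which(urf_slots == g)[1L]
        cds <- make_cds(spec$urf_aa_lens[k], p, spec$code, tm_stretch = TRUE)
        # spacer ending in an in-frame stop, so the URF's maximal ORF
        # extent is exactly the planted one
        add_seg("nc", NA, NA, paste0(make_nc(3L, p), "TAA"))
        add_seg("feature", paste0("urf", k), "URF", cds$nt, cds$protein)
      }
      nc_i <- nc_i + 1L
      len <- ncs[((nc_i - 1L) %% length(ncs)) + 1L]
      add_seg("nc", NA, NA, make_nc(len, p))
    }

    # planted perfect repeat: two dedicated NC tracts with one unit
    repeat_info <- NULL
    if (!is.null(spec$planted_repeat)) {
      ul <- spec$planted_repeat$unit_len
      sep <- spec$planted_repeat$separation
      unit <- ""
      repeat {
        unit <- paste(sample_bases(ul, p), collapse = "")
        if (dinucleotide_entropy(unit) >= 1.7) break
      }
      # The two copies sit in dedicated NC tracts. Guard bases that
      # differ between the copies pin the maximal extension to exactly
      # the unit: copy 1 is C-unit-C, copy 2 is G-unit-G.
      seg1 <- list(type = "nc", label = NA, kind = NA,
                   nt = paste0("C", unit, "C"))
      seg2 <- list(type = "nc", label = NA, kind = NA,
                   nt = paste0("G", unit, "G"))
      # first copy right after the first segment; second at the boundary
      # whose cumulative position is closest to `separation` downstream
      segments <- append(segments, list(seg1), after = 1L)
      cum <- cumsum(vapply(segments, function(s) nchar(s$nt), 0L))
      pos1 <- cum[1L] + 1L                  # start of the first unit copy
      target <- pos1 + sep
      after2 <- max(which.min(abs(cum - target)), 3L)
      segments <- append(segments, list(seg2), after = after2)
      repeat_info <- list(unit = unit, unit_len = ul)
    }

    # assemble
    lens <- vapply(segments, function(s) nchar(s$nt), 0L)
    starts <- c(0L, cumsum(lens))[seq_along(lens)]
    sequence <- paste(vapply(segments, `[[`, "", "nt"), collapse = "")
    L <- nchar(sequence)

    feats <- list(); proteins <- character(0); rnas <- character(0)
    urf_truth <- list()
    for (k in seq_along(segments)) {
      s <- segments[[k]]
      if (s$type != "feature") next
      f <- GeneFeature(s$label, starts[k], starts[k] + lens[k], "+", s$kind)
      feats[[length(feats) + 1L]] <- f
      if (s$kind == "protein") proteins[s$label] <- s$protein
      if (s$kind == "rRNA") rnas[s$label] <- s$nt
      if (s$kind == "URF")
        urf_truth[[s$label]] <- list(start = starts[k],
                                     end = starts[k] + lens[k],
                                     protein = s$protein)
    }
    if (!is.null(repeat_info)) {
      pos <- which(vapply(segments, function(s)
        grepl(repeat_info$unit, s$nt, fixed = TRUE), FALSE))
      repeat_info$positions <- starts[pos] + 1L   # skip the guard base
      repeat_info$separation <- diff(repeat_info$positions)
    }

    genome <- MitoGenome(id, sequence, is_circular = TRUE)
    ann <- AnnotationSet(id, feats)
    if (spec$origin_shift > 0L) {
      rot <- rotate_genome(genome, ann, spec$origin_shift)
      genome <- rot$genome; ann <- rot$annotation
      if (!is.null(repeat_info))
        repeat_info$positions <-
          sort((repeat_info$positions - spec$origin_shift) %% L)
    }

    labels <- vapply(ann$features, `[[`, "", "label")
    keep <- vapply(ann$features, function(f) f$kind != "URF", FALSE)
    ledger <- list(
      id = id, length = L,
      gene_order = labels[keep],
      features = data.frame(
        label = labels,
        start = vapply(ann$features, `[[`, 0L, "start"),
        end = vapply(ann$features, `[[`, 0L, "end"),
        kind = vapply(ann$features, `[[`, "", "kind"),
        stringsAsFactors = FALSE),
      proteins = proteins, rnas = rnas, urfs = urf_truth,
      planted_repeat = repeat_info,
      at_fraction = spec$at_fraction, t_fraction = spec$t_fraction,
      seed = spec$seed)
    list(genome = genome, annotation = ann, ledger = ledger)
  })
}

#' Rotate a circular genome's origin
#'
#' Shifts the origin `shift` bp downstream; features are re-based and may
#' become origin-spanning.
#'
#' @param genome Circular [MitoGenome()].
#' @param ann [AnnotationSet()].
#' @param shift Left-rotation in bp.
#' @return List with rotated `genome` and `annotation`.
#' @export
rotate_genome <- function(genome, ann, shift) {
  stopifnot(genome$is_circular)
  L <- genome$length
  shift <- shift %% L
  sq <- paste0(substr(genome$sequence, shift + 1L, L),
               substr(genome$sequence, 1L, shift))
  feats <- lapply(ann$features, function(f) {
    s <- (f$start - shift) %% L
    GeneFeature(f$label, s, s + (f$end - f$start), f$strand, f$kind,
                f$has_incomplete_stop)
  })
  list(genome = MitoGenome(genome$id, sq, TRUE),
       annotation = AnnotationSet(ann$genome_id, feats))
}

#' Generate a cohort of synthetic genomes sharing orthologs
#'
#' The first genome is generated from `base_spec`; the others reuse its
#' protein and rRNA sequences (so homology search works across the
#' cohort) but have their gene order rearranged by single-gene
#' transpositions, emulating congeneric-to-inter-order divergence in
#' gene order while protein sequences stay recognizable.
#'
#' @param base_spec A [genome_spec()] for the first genome.
#' @param k_moves Integer vector, one entry per additional genome: the
#'   number of transpositions applied to the base gene order.
#' @param seed Integer seed.
#' @param ids Genome identifiers (default `g1..gN`).
#' @return List with `genomes` (per-genome [generate_genome()] results)
#'   and `ledger` (shared proteins/rnas, per-genome gene orders and
#'   applied move counts).
#' @export
generate_cohort <- function(base_spec, k_moves = c(1L, 3L), seed = 1L,
                            ids = NULL) {
  n <- length(k_moves) + 1L
  if (is.null(ids)) ids <- paste0("g", seq_len(n))
  stopifnot(length(ids) == n)
  base_spec$seed <- seed
  base <- generate_genome(base_spec, id = ids[1])
  out <- list(base)
  orders <- list(GeneOrder(ids[1], base$ledger$gene_order))
  gm <- base_spec$gene_models
  # per-genome scaling of the non-coding budget, so cohort genome sizes
  # vary with their NC content (as the real genomes do)
  nc_scale <- with_seed(seed, stats::runif(length(k_moves), 0.3, 2.5))
  for (i in seq_along(k_moves)) {
    ro <- rearrange_order(orders[[1]], k_moves[i], seed = seed + i)
    new_order <- ro$order$order
    spec_i <- base_spec
    spec_i$gene_models <- gm[match(new_order[new_order %in% gm$label],
                                   gm$label), ]
    spec_i$proteins <- base$ledger$proteins
    spec_i$rnas <- base$ledger$rnas
    spec_i$nc_tract_lengths <-
      pmax(3L, as.integer(round(base_spec$nc_tract_lengths * nc_scale[i])))
    spec_i$seed <- seed + 100L * i
    out[[i + 1L]] <- generate_genome(spec_i, id = ids[i + 1L])
    orders[[i + 1L]] <- GeneOrder(ids[i + 1L],
                                  out[[i + 1L]]$ledger$gene_order)
  }
  names(out) <- ids
  list(genomes = out,
       ledger = list(proteins = base$ledger$proteins,
                     rnas = base$ledger$rnas,
                     orders = lapply(orders, `[[`, "order"),
                     k_moves = c(0L, k_moves), seed = seed))
}

#' Apply random single-gene transpositions to a gene order
#'
#' Each move removes one gene and reinserts it elsewhere; a transposition
#' alters at most 3 adjacencies, so the breakpoint distance to the input
#' is at most `3 * k_moves`.
#'
#' @param order A [GeneOrder()].
#' @param k_moves Number of transpositions (>= 0).
#' @param seed Integer seed.
#' @return List with `order` (rearranged [GeneOrder()]) and `ledger`
#'   (each move's gene and insertion point).
#' @export
rearrange_order <- function(order, k_moves, seed = 1L) {
  stopifnot(inherits(order, "GeneOrder"), k_moves >= 0L)
  with_seed(seed, {
    v <- order$order
    moves <- list()
    for (m in seq_len(k_moves)) {
      n <- length(v)
      repeat {
        i <- sample(n, 1L)
        g <- v[i]
        rest <- v[-i]
        j <- sample(n - 1L, 1L)
        w <- append(rest, g, after = j)
        # reject a reinsertion into the same circular gap (a no-op)
        if (!identical(canonical_rotation(w), canonical_rotation(v))) break
      }
      v <- w
      moves[[m]] <- list(gene = g, from = i, after = j)
    }
    list(order = GeneOrder(paste0(order$genome_id, "_r"), v),
         ledger = list(k_moves = k_moves, moves = moves, seed = seed))
  })
}

#' Simulate error-free reads from a genome
#'
#' Reads are sampled uniformly on the circle at the expected depth (read
#' count is Poisson); paired mode emits two mates per fragment at the
#' given insert size, the second mate reverse-complemented.
#'
#' @param genome [MitoGenome()].
#' @param depth Expected per-base coverage.
#' @param read_len Read length in bp (default 100).
#' @param paired Emit mate pairs.
#' @param insert Outer fragment length for paired mode (default 300).
#' @param seed Integer seed.
#' @return FASTQ collection: list of records (`id`, `seq`, `qual`).
#' @export
simulate_reads <- function(genome, depth, read_len = 100L, paired = FALSE,
                           insert = 300L, seed = 1L) {
  stopifnot(read_len < genome$length, depth >= 0)
  with_seed(seed, {
    L <- genome$length
    per_frag <- if (paired) 2L * read_len else read_len
    n <- stats::rpois(1L, depth * L / per_frag)
    if (n == 0L) return(list())
    D <- if (genome$is_circular) paste0(genome$sequence, genome$sequence)
         else genome$sequence
    starts <- if (genome$is_circular) sample.int(L, n, replace = TRUE) - 1L
              else sample.int(L - per_frag + 1L, n, replace = TRUE) - 1L
    out <- list()
    qual <- strrep("I", read_len)
    for (i in seq_len(n)) {
      s <- starts[i]
      r1 <- substr(D, s + 1L, s + read_len)
      if (paired) {
        e <- s + insert
        r2 <- revcomp(substr(D, e - read_len + 1L, e))
        out[[length(out) + 1L]] <- list(id = sprintf("frag%05d/1", i),
                                        seq = r1, qual = qual)
        out[[length(out) + 1L]] <- list(id = sprintf("frag%05d/2", i),
                                        seq = r2, qual = qual)
      } else {
        out[[length(out) + 1L]] <- list(id = sprintf("read%05d", i),
                                        seq = r1, qual = qual)
      }
    }
    out
  })
}

#' Simulate a codon-aware alignment with an optional code reassignment
#'
#' Builds one conserved protein alignment rendered at the nucleotide
#' level. Non-target species use the mold code; the target species uses
#' the mold code with the stated reassignment, preferring the reassigned
#' codon at columns whose consensus is the reassigned amino acid.
#'
#' @param n_species Number of species including the target (>= 4).
#' @param n_columns Codon columns.
#' @param reassigned `NULL` or `list(codon =, aa =)`, e.g.
#'   `list(codon = "TGA", aa = "S")`.
#' @param seed Integer seed.
#' @param conservation Probability a non-target species shows the
#'   consensus amino acid at a column (default 0.9).
#' @return List with `alignment` (named character vector, target row
#'   named `"target"`), `ledger`.
#' @export
simulate_code_alignment <- function(n_species = 8L, n_columns = 60L,
                                    reassigned = NULL, seed = 1L,
                                    conservation = 0.9) {
  stopifnot(n_species >= 4L)
  mold <- get_code_table("mold")
  with_seed(seed, {
    aa_pool <- c("S", "L", "I", "F", "G", "K", "T", "N", "Y", "W")
    wts <- c(0.25, rep(0.75 / 9, 9))
    consensus <- sample(aa_pool, n_columns, replace = TRUE, prob = wts)
    if (!is.null(reassigned)) {
      # guarantee plenty of columns for the reassigned meaning
      n_target_cols <- max(10L, round(0.25 * n_columns))
      consensus[sample(n_columns, n_target_cols)] <- reassigned$aa
    }
    codons_for <- function(aa, code)
      names(code$codon_map)[code$codon_map == aa]
    rows <- list()
    for (s in seq_len(n_species - 1L)) {
      aas <- ifelse(stats::runif(n_columns) < conservation, consensus,
                    sample(aa_pool, n_columns, replace = TRUE))
      rows[[paste0("sp", s)]] <- paste(vapply(aas, function(a)
        sample(codons_for(a, mold), 1L), ""), collapse = "")
    }
    target_code <- mold
    if (!is.null(reassigned))
      target_code$codon_map[reassigned$codon] <- reassigned$aa
    target_cods <- vapply(consensus, function(a) {
      cands <- codons_for(a, target_code)
      if (!is.null(reassigned) && a == reassigned$aa &&
          stats::runif(1) < 0.8)
        reassigned$codon
      else sample(setdiff(cands, if (!is.null(reassigned)) reassigned$codon
                          else character(0)), 1L)
    }, "")
    rows[["target"]] <- paste(target_cods, collapse = "")
    list(alignment = unlist(rows),
         ledger = list(consensus = consensus, reassigned = reassigned,
                       seed = seed, n_species = n_species))
  })
}
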