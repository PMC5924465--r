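# Pipeline orchestration: thin, reproducible drivers over the analysis
# stages. Machine-readable outputs go to files; messages to stderr. Each
# run writes a manifest (config echo, seed, package version) so identical
# configs reproduce identical reports.

#' Build or load a pipeline configuration
#'
#' @param x A named list of settings, or the path of a YAML file holding
#'   one.
#' @param ... Further settings overriding those in `x`.
#' @return A `PipelineConfig` list with defaults filled in:
#'   `code_table` ("mold"), `min_orf_len` (100), `floor` (0.3),
#'   `min_unit` (21), `min_overlap` (25), `conservation_threshold` (0.7),
#'   `tract_cutoff` (20), `seed` (1), `out_dir` (".").
#' @export
pipeline_config <- function(x = list(), ...) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  x <- utils::modifyList(x, list(...))
  defaults <- list(code_table = "mold", min_orf_len = 100L, floor = 0.3,
                   min_unit = 21L, min_overlap = 25L,
                   conservation_threshold = 0.7, tract_cutoff = 20L,
                   seed = 1L, out_dir = ".")
  cfg <- utils::modifyList(defaults, x)
  stopifnot(cfg$min_orf_len >= 3L, cfg$floor >= 0, cfg$floor <= 1,
            cfg$min_unit >= 2L, cfg$min_overlap >= 15L,
            cfg$conservation_threshold > 0, cfg$conservation_threshold <= 1)
  structure(cfg, class = "PipelineConfig")
}

write_manifest <- function(cfg, stage) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stage = stage,
                   config = unclass(cfg)[order(names(unclass(cfg)))],
                   seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("ctenomito")))
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Annotation stage
#'
#' Annotates every genome in the input FASTA against reference protein
#' (and optional rRNA) sets, and writes one GenBank flatfile plus a URF
#' report per genome.
#'
#' @param cfg [pipeline_config()] with fields `fasta`, `refs_proteins`
#'   (labelled FASTA of reference proteins), optional `refs_rnas`.
#' @return Invisibly, the list of annotation results per genome.
#' @export
run_annotate <- function(cfg) {
  cfg <- pipeline_config(cfg)
  genomes <- read_fasta(cfg$fasta)
  if (!length(genomes)) stop("no sequences in ", cfg$fasta)
  prot_set <- Biostrings::readAAStringSet(cfg$refs_proteins)
  refs <- list(proteins = stats::setNames(as.character(prot_set),
                                          sub(" .*", "", names(prot_set))))
  if (!is.null(cfg$refs_rnas)) {
    rna_set <- Biostrings::readBStringSet(cfg$refs_rnas)
    refs$rnas <- stats::setNames(toupper(as.character(rna_set)),
                                 sub(" .*", "", names(rna_set)))
  }
  code <- get_code_table(cfg$code_table)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  urf_rows <- list()
  for (g in genomes) {
    message("annotating ", g$id)
    res <- annotate_genome(g, refs, code, min_orf_len = cfg$min_orf_len,
                           floor = cfg$floor)
    write_genbank(g, res$annotation,
                  file.path(cfg$out_dir, paste0(g$id, ".gb")))
    for (f in res$annotation$features)
      if (f$kind == "URF")
        urf_rows[[length(urf_rows) + 1L]] <- data.frame(
          genome = g$id, label = f$label, start = f$start, end = f$end,
          length = f$end - f$start,
          tm_segments = predict_tm(translate_seq(
            substr(extract_feature_sequence(g, f), 1L,
                   3L * ((f$end - f$start) %/% 3L) - 3L), code)),
          stringsAsFactors = FALSE)
    results[[g$id]] <- res
  }
  urf_df <- if (length(urf_rows)) do.call(rbind, urf_rows) else
    data.frame(genome = character(), label = character(),
               start = integer(), end = integer(), length = integer(),
               tm_segments = integer())
  utils::write.table(urf_df, file.path(cfg$out_dir, "urf_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "annotate")
  invisible(results)
}

#' Gene-order comparison stage
#'
#' Computes the pairwise breakpoint-distance matrix (BD above, BDn below
#' the diagonal) and per-pair synteny blocks over a set of annotated
#' genomes.
#'
#' @param cfg [pipeline_config()] with field `gb` (character vector of at
#'   least two GenBank files).
#' @return Invisibly, a list with `matrix` ([distance_matrix()] result)
#'   and `synteny` (per-pair block lists).
#' @export
run_compare <- function(cfg) {
  cfg <- pipeline_config(cfg)
  if (length(cfg$gb) < 2L) stop("need at least 2 annotated genomes")
  anns <- lapply(cfg$gb, function(p) read_genbank(p)$annotation)
  orders <- lapply(anns, gene_order_from_annotation)
  dm <- distance_matrix(orders)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dm$bd, file.path(cfg$out_dir, "bd_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(render_bd_matrix(dm),
                     file.path(cfg$out_dir, "bd_table.txt"),
                     sep = "\t", quote = FALSE, col.names = NA)
  syn <- list()
  ids <- vapply(orders, `[[`, "", "genome_id")
  con <- file(file.path(cfg$out_dir, "synteny_blocks.txt"), "w")
  for (i in seq_along(orders)[-length(orders)])
    for (j in (i + 1L):length(orders)) {
      r <- restrict_to_shared(orders[[i]], orders[[j]])
      blocks <- synteny_blocks(r[[1]], r[[2]])
      key <- paste(ids[i], ids[j], sep = " vs ")
      syn[[key]] <- blocks
      writeLines(c(key, vapply(blocks, function(b)
        paste(" ", paste(b$genes, collapse = "-")), "")), con)
    }
  close(con)
  write_manifest(cfg, "compare")
  invisible(list(matrix = dm, synteny = syn))
}

#' Genome statistics stage
#'
#' Per-genome composition, codon usage, non-coding accounting, perfect
#' repeats, and the cohort-level genome-size ~ NC-length correlation
#' (skipped with a warning for cohorts smaller than 3).
#'
#' @param cfg [pipeline_config()] with field `gb` (GenBank files).
#' @return Invisibly, a list with `nc_table` (data frame), `correlation`
#'   (list with `with_urfs`, `without_urfs`, or `NULL`), `repeats`,
#'   `codon_usage`.
#' @export
run_stats <- function(cfg) {
  cfg <- pipeline_config(cfg)
  stopifnot(length(cfg$gb) >= 1L)
  code <- get_code_table(cfg$code_table)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); reps <- list(); usage <- list()
  for (p in cfg$gb) {
    gx <- read_genbank(p)
    ncp <- summarize_noncoding(gx$annotation, gx$genome,
                               tract_cutoff = cfg$tract_cutoff)
    comp <- composition(gx$genome)
    rows[[gx$genome$id]] <- data.frame(
      genome = gx$genome$id, length = ncp$genome_length,
      at_percent = round(comp$AT_percent, 1),
      nc_with_urfs = ncp$nc_with_urfs,
      nc_without_urfs = ncp$nc_without_urfs,
      n_nc_gt20_with = ncp$n_nc_gt_with,
      n_nc_gt20_without = ncp$n_nc_gt_without,
      longest_with = ncp$longest_with$bp,
      longest_with_loc = paste(ncp$longest_with$flanks, collapse = "-"),
      longest_without = ncp$longest_without$bp,
      longest_without_loc = paste(ncp$longest_without$flanks, collapse = "-"),
      stringsAsFactors = FALSE)
    usage[[gx$genome$id]] <- codon_usage(gx$annotation, gx$genome, code)
    utils::write.table(usage[[gx$genome$id]]$codon,
                       file.path(cfg$out_dir,
                                 paste0(gx$genome$id, "_codon_usage.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hits <- find_perfect_repeats(gx$genome, min_unit = cfg$min_unit,
                                 filter_low_complexity = TRUE)
    reps[[gx$genome$id]] <- hits
  }
  nc_table <- do.call(rbind, rows)
  rownames(nc_table) <- NULL
  utils::write.table(nc_table, file.path(cfg$out_dir, "nc_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rep_rows <- do.call(rbind, lapply(names(reps), function(id) {
    hs <- reps[[id]]
    if (!length(hs)) return(NULL)
    do.call(rbind, lapply(hs, function(h) data.frame(
      genome = id, start = h$positions[1], end = h$positions[1] + h$unit_length,
      unit_length = h$unit_length,
      positions = paste(h$positions, collapse = ","),
      low_complexity = h$low_complexity, stringsAsFactors = FALSE)))
  }))
  if (is.null(rep_rows))
    rep_rows <- data.frame(genome = character(), start = integer(),
                           end = integer(), unit_length = integer(),
                           positions = character(),
                           low_complexity = logical())
  utils::write.table(rep_rows, file.path(cfg$out_dir, "repeats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  correlation <- NULL
  if (nrow(nc_table) >= 3L) {
    correlation <- tryCatch(
      list(with_urfs = size_nc_correlation(
             nc_table[, c("length", "nc_with_urfs")]),
           without_urfs = size_nc_correlation(
             nc_table[, c("length", "nc_without_urfs")])),
      error = function(e) { warning(conditionMessage(e)); NULL })
  } else {
    warning("fewer than 3 genomes; size~NC correlation skipped")
  }
  write_manifest(cfg, "stats")
  invisible(list(nc_table = nc_table, correlation = correlation,
                 repeats = reps, codon_usage = usage))
}
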