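#!/usr/bin/env Rscript
# Annotate the cohort genomes from their bare FASTA sequences against the
# shared ortholog references, write GenBank flatfiles and the URF report,
# and score the annotation against the planted truth.

suppressPackageStartupMessages(library(ctenomito))

cohort <- "results/cohort"
out <- "results/annotation"
stopifnot(file.exists(file.path(cohort, "cohort.fasta")))

cfg <- pipeline_config(list(
  fasta = file.path(cohort, "cohort.fasta"),
  refs_proteins = file.path(cohort, "reference_proteins.faa"),
  refs_rnas = file.path(cohort, "reference_rnas.fasta"),
  out_dir = out))
res <- run_annotate(cfg)

# compare against the planted truth
truth_files <- list.files(cohort, pattern = "_truth\\.gb$",
                          full.names = TRUE)
rows <- list()
for (tf in truth_files) {
  truth <- read_genbank(tf)
  id <- truth$genome$id
  L <- truth$genome$length
  got <- res[[id]]$annotation$features
  labs <- vapply(got, `[[`, "", "label")
  exact <- 0L; n <- 0L
  for (f in truth$annotation$features) {
    if (f$kind == "URF") next
    n <- n + 1L
    k <- which(labs == f$label)
    if (length(k) == 1L && got[[k]]$start %% L == f$start %% L &&
        (got[[k]]$end - got[[k]]$start) == (f$end - f$start))
      exact <- exact + 1L
  }
  rows[[id]] <- data.frame(genome = id, genes = n, exact = exact,
                           urfs_called = sum(labs == "" |
                                               grepl("^urf", labs)))
}
scorecard <- do.call(rbind, rows)
write.table(scorecard, file.path(out, "recovery_scorecard.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(scorecard, row.names = FALSE)
cat(sprintf("boundary recovery: %d/%d exact (%.1f%%)\n",
            sum(scorecard$exact), sum(scorecard$genes),
            100 * sum(scorecard$exact) / sum(scorecard$genes)))
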