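#!/usr/bin/env Rscript
# Genome statistics. Two views:
#   (a) the published five-species non-coding table: NC proportions and
#       the genome-size ~ NC-length Pearson correlation;
#   (b) the synthetic cohort: composition, codon usage, NC accounting and
#       perfect repeats (including the planted 84 bp unit).

suppressPackageStartupMessages(library(ctenomito))

out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## (a) published table arithmetic
nc <- published_nc_stats()
nc$pct_with <- round(nc_percent(nc$nc_with_urfs, nc$genome_length), 1)
nc$pct_without <- round(nc_percent(nc$nc_without_urfs, nc$genome_length), 1)
write.table(nc, file.path(out, "published_nc_percent.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("largest NC proportion, URFs as non-coding:",
    nc$species[which.max(nc$pct_with)], nc$pct_with[which.max(nc$pct_with)],
    "%\n")
cat("largest NC proportion, URFs as coding:",
    nc$species[which.max(nc$pct_without)],
    nc$pct_without[which.max(nc$pct_without)], "%\n")
r_with <- size_nc_correlation(nc[, c("genome_length", "nc_with_urfs")])
r_without <- size_nc_correlation(nc[, c("genome_length", "nc_without_urfs")])
cat(sprintf("size~NC Pearson r: %.4f with URFs, %.4f without\n",
            r_with, r_without))
cat("smallest genome:", min(nc$genome_length), "bp\n")

## (b) synthetic cohort
gbs <- file.path("results/annotation",
                 paste0(c("synA", "synB", "synC", "synD", "synE"), ".gb"))
stopifnot(all(file.exists(gbs)))
st <- run_stats(pipeline_config(list(gb = gbs, out_dir = out)))
print(st$nc_table[, c("genome", "length", "at_percent", "nc_with_urfs",
                      "nc_without_urfs")], row.names = FALSE)
if (!is.null(st$correlation))
  cat(sprintf("cohort size~NC r: %.3f with URFs, %.3f without\n",
              st$correlation$with_urfs, st$correlation$without_urfs))

## repeat search on the dedicated repeat genome
rep_g <- read_fasta("results/cohort/synRepeat.fasta")[[1]]
hits <- find_perfect_repeats(rep_g, min_unit = 21,
                             filter_low_complexity = TRUE)
if (length(hits))
  cat(sprintf("longest perfect repeat (low-complexity filtered): %d bp at %s\n",
              hits[[1]]$unit_length,
              paste(hits[[1]]$positions, collapse = ", ")))
hits_all <- find_perfect_repeats(rep_g, min_unit = 21)
cat(sprintf("without the filter: %d repeat unit(s), %d of them low-complexity\n",
            length(hits_all),
            sum(vapply(hits_all, `[[`, FALSE, "low_complexity"))))
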