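#!/usr/bin/env Rscript
# Contig elongation and circularization demo on one cohort genome:
# simulate error-free 100 bp reads at 30x, seed a contig from a cox1
# bait, extend by iterative >= 25 bp read overlap, detect circularity,
# and report coverage statistics of the finished circle.

suppressPackageStartupMessages(library(ctenomito))

out <- "results/elongation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20180427L

g <- read_fasta("results/cohort/cohort.fasta")[[1]]
truth <- read_genbank(list.files("results/cohort",
                                 pattern = paste0(g$id, "_truth\\.gb$"),
                                 full.names = TRUE)[1])
cox1 <- Filter(function(f) f$label == "cox1",
               truth$annotation$features)[[1]]
bait <- substr(extract_feature_sequence(g, cox1), 1, 200)

reads <- simulate_reads(g, depth = 30, read_len = 100, seed = seed)
write_fastq(reads, file.path(out, "reads.fastq"))
cat(length(reads), "reads at ~30x over", g$length, "bp\n")

seed_contig <- find_seed_by_bait(reads, bait, k = 21)
stopifnot(!is.null(seed_contig))
asm <- assemble_circular(seed_contig, reads, min_overlap = 25,
                         max_rounds = 200, id = paste0(g$id, "_asm"))
cat("circular:", asm$is_circular, "after", asm$rounds, "rounds;",
    "assembled", asm$genome$length, "bp (truth", g$length, "bp)\n")
cat("identical up to rotation:",
    grepl(asm$genome$sequence, paste0(g$sequence, g$sequence),
          fixed = TRUE), "\n")
write_fasta(asm$genome, file.path(out, "assembly.fasta"))

cov <- coverage_stats(asm$genome, reads)
cat(sprintf("coverage: mean %.0f (SD %.0f; range: %d-%d); unplaced reads: %d\n",
            cov$mean, cov$sd, cov$min, cov$max, cov$n_unplaced))
jsonlite::write_json(
  list(genome = asm$genome$id, length = asm$genome$length,
       circular = asm$is_circular, mean = cov$mean, sd = cov$sd,
       min = cov$min, max = cov$max, unplaced = cov$n_unplaced),
  file.path(out, "coverage.json"), auto_unbox = TRUE, digits = NA)
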