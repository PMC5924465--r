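#!/usr/bin/env Rscript
# Build the synthetic study cohort: five circular AT-rich mitogenomes
# sharing 13 orthologous genes (11 proteins + 2 rRNAs), with gene orders
# progressively rearranged (0, 1, 4, 8 and 13 single-gene transpositions
# from the base order) to emulate congeneric through inter-order
# divergence. One extra genome carries a planted 84 bp perfect repeat
# ~8.2 kb apart. Everything is written under results/cohort/ together
# with the truth ledger.

suppressPackageStartupMessages({
  library(ctenomito)
  library(Biostrings)
})

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20180427L

co <- generate_cohort(genome_spec(seed = seed),
                      k_moves = c(1L, 4L, 8L, 13L), seed = seed,
                      ids = c("synA", "synB", "synC", "synD", "synE"))
write_fasta(lapply(co$genomes, `[[`, "genome"),
            file.path(out, "cohort.fasta"))
writeXStringSet(AAStringSet(co$ledger$proteins),
                file.path(out, "reference_proteins.faa"))
writeXStringSet(DNAStringSet(co$ledger$rnas),
                file.path(out, "reference_rnas.fasta"))
for (g in co$genomes)
  write_genbank(g$genome, g$annotation,
                file.path(out, paste0(g$genome$id, "_truth.gb")))

rep_gx <- generate_genome(genome_spec(
  seed = seed + 1L, planted_repeat = list(unit_len = 84L,
                                          separation = 8200L)),
  "synRepeat")
write_fasta(rep_gx$genome, file.path(out, "synRepeat.fasta"))

ledger <- list(cohort = co$ledger,
               repeat_genome = rep_gx$ledger,
               seed = seed)
jsonlite::write_json(ledger, file.path(out, "truth_ledger.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

sizes <- vapply(co$genomes, function(g) g$genome$length, 0L)
cat("cohort written:", paste(names(sizes), sizes, "bp", collapse = ", "),
    "\n")
cat("repeat genome:", rep_gx$genome$length, "bp; unit at",
    paste(rep_gx$ledger$planted_repeat$positions, collapse = " and "),
    sprintf("(separation %d bp)\n",
            rep_gx$ledger$planted_repeat$separation))
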