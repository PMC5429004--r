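#!/usr/bin/env Rscript
# Classify each simulated unigene by coverage peaks, breadth and depth and
# tabulate the composition; compare against the designated truth classes.

suppressMessages(library(fabatools))
dir.create("results", showWarnings = FALSE)

aln <- read_alignments("results/simdata/genomic_vs_unigenes.sam")
cls <- classify_unigenes(aln)
write.table(cls, "results/unigene_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
tab <- tabulate_classes(cls)
write.table(tab, "results/unigene_class_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim("results/simdata/truth_classes.tsv")
truth_cls <- data.frame(
  peak_bin = vapply(truth$n_peaks, fabatools:::.peak_bin, ""),
  breadth_bin = vapply(truth$breadth * 100, fabatools:::.breadth_bin, ""),
  depth_bin = vapply(truth$depth, fabatools:::.depth_bin, ""))
exact <- identical(tab, tabulate_classes(truth_cls))

cat("Classified", nrow(cls), "unigenes; class table:\n")
print(tab[tab$total > 0, ], row.names = FALSE)
cat("Recovered the designated composition exactly:", exact, "\n")
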