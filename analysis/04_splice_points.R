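#!/usr/bin/env Rscript
# Detect putative splice points on the unigenes from clustered softclip
# boundaries of the unspliced genomic reads, and score recovery against
# the planted junctions.

suppressMessages(library(fabatools))
dir.create("results", showWarnings = FALSE)

aln <- read_alignments("results/simdata/genomic_vs_unigenes.sam")
det <- detect_splice_points(aln)
write.table(det$points, "results/splice_points.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim("results/simdata/truth_splice.tsv")
recall <- mean(vapply(seq_len(nrow(truth)), function(k)
  any(det$points$unigene_id == truth$unigene_id[k] &
        abs(det$points$pos - truth$pos[k]) <= 1L), TRUE))
precision <- mean(vapply(seq_len(nrow(det$points)), function(k)
  any(truth$unigene_id == det$points$unigene_id[k] &
        abs(truth$pos - det$points$pos[k]) <= 1L), TRUE))

cat(sprintf("%d unigenes with >=1 splice point; %d points total\n",
            det$summary$unigenes_with_points, det$summary$total_points))
cat(sprintf("Against %d planted junctions: recall %.2f, precision %.2f\n",
            nrow(truth), recall, precision))
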