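#!/usr/bin/env Rscript
# Generate the full synthetic input set with known truth: a spliced
# reference transcriptome plus unspliced genomic-read alignments, an
# annotated organelle genome with planted near-fixed SNVs, linkage markers
# with overhanging de novo contigs, and repeat-class read assignments.
# Everything downstream (02-07) reads from results/simdata/.

suppressMessages(library(fabatools))

outdir <- "results/simdata"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 101L

## transcriptome + genomic alignments (10 unigenes carry one junction each)
cfg0 <- sim_config(seed = seed, n_unigenes = 60)
tx <- simulate_transcriptome(cfg0)
lens <- Biostrings::width(tx$unigenes)
ids <- names(tx$unigenes)
ispec <- list()
for (i in seq(1L, 60L, by = 6L))
  ispec[[ids[i]]] <- as.integer(round(lens[i] * 0.5))
cfg <- sim_config(seed = seed, n_unigenes = 60, intron_spec = ispec)
# unigenes with a junction keep a single clean peak so the clip signal is
# unambiguous; the rest carry the designated class mixture
cls <- fabatools:::.designate_classes(lens, cfg$read_len)
cls[ids %in% names(ispec), ] <- list(1L, 0.98, 30)
cfg$unigene_classes <- cls
ga <- simulate_genomic_alignments(cfg, tx$unigenes)
Biostrings::writeXStringSet(tx$unigenes, file.path(outdir, "unigenes.fasta"))
write_alignments(ga$alignments, file.path(outdir, "genomic_vs_unigenes.sam"))
write.table(ga$truth_classes, file.path(outdir, "truth_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ga$truth_splice, file.path(outdir, "truth_splice.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## organelle genome, annotation, reads, truth variants
cfg_org <- sim_config(seed = seed, organelle_len = 60000L, n_cds = 20,
                      n_trna = 4, n_rrna = 2, organelle_depth = 40,
                      n_snvs = 7, snv_where = "mixed")
org <- simulate_organelle(cfg_org)
Biostrings::writeXStringSet(org$genome, file.path(outdir, "organelle.fasta"))
rtracklayer::export(org$gff, file.path(outdir, "organelle.gff3"),
                    format = "GFF3")
write_alignments(org$alignments, file.path(outdir, "organelle_reads.sam"))
truth_vcf_in <- data.frame(ref_id = "organelle_1",
                           pos = org$truth_snvs$pos + 1L,
                           ref = org$truth_snvs$ref, alt = org$truth_snvs$alt,
                           gene_id = org$truth_snvs$gene_id,
                           gene_name = org$truth_snvs$gene_id,
                           effect = org$truth_snvs$effect,
                           aa_change = "-")
write_variant_table(truth_vcf_in, vcf = file.path(outdir, "truth_snvs.vcf"),
                    ref_lengths = c(organelle_1 = cfg_org$organelle_len))
write.table(org$truth_snvs, file.path(outdir, "truth_snvs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## linkage markers and contigs
mc <- simulate_markers_and_contigs(sim_config(seed = seed))
Biostrings::writeXStringSet(mc$markers, file.path(outdir, "markers.fasta"))
Biostrings::writeXStringSet(mc$contigs, file.path(outdir, "contigs.fasta"))
write.table(mc$truth, file.path(outdir, "truth_extension.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## repeat-class assignments
ra <- simulate_repeat_assignments(sim_config(seed = seed), n_pairs = 50000L)
write.table(ra, file.path(outdir, "repeat_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated inputs written to", outdir, "\n")
cat(sprintf(" - %d unigenes (%d with a planted junction), %d alignment records\n",
            length(tx$unigenes), length(ispec), nrow(ga$alignments)))
cat(sprintf(" - organelle %d bp, %d features, %d planted SNVs, %d reads\n",
            cfg_org$organelle_len, length(org$genes), nrow(org$truth_snvs),
            nrow(org$alignments)))
cat(sprintf(" - %d marker/contig pairs, %d repeat-assigned read pairs\n",
            length(mc$markers), sum(!is.na(ra$class))))
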