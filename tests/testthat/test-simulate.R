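test_that("simulators are byte-deterministic at a fixed seed", {
  cfg <- sim_config(seed = 3, n_unigenes = 6, organelle_len = 20000L,
                    n_cds = 6, n_trna = 2, n_rrna = 1, organelle_depth = 15)
  out <- replicate(2, {
    tx <- simulate_transcriptome(cfg)
    ga <- simulate_genomic_alignments(cfg, tx$unigenes)
    f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".sam")
    Biostrings::writeXStringSet(tx$unigenes, f1)
    write_alignments(ga$alignments, f2)
    c(tools::md5sum(f1), tools::md5sum(f2))
  })
  expect_equal(unname(out[1, 1]), unname(out[1, 2]))
  expect_equal(unname(out[2, 1]), unname(out[2, 2]))
})

test_that("transcriptome respects count, length range and id scheme", {
  cfg <- sim_config(seed = 5, n_unigenes = 50)
  tx <- simulate_transcriptome(cfg)
  expect_length(tx$unigenes, 50L)
  expect_true(all(Biostrings::width(tx$unigenes) >= 300 &
                    Biostrings::width(tx$unigenes) <= 3000))
  expect_equal(names(tx$unigenes)[1], "unigene_0001")
  empty <- simulate_transcriptome(sim_config(seed = 5, n_unigenes = 0))
  expect_length(empty$unigenes, 0L)
  expect_error(sim_config(unigene_len_range = c(3000, 300)), "degenerate")
})

test_that("genomic alignments hit their designated depth and breadth", {
  cfg <- sim_config(seed = 13, n_unigenes = 12)
  tx <- simulate_transcriptome(cfg)
  ga <- simulate_genomic_alignments(cfg, tx$unigenes)
  profs <- coverage_profiles(ga$alignments)
  for (i in seq_along(profs)) {
    md <- mean(profs[[i]])
    expect_lt(abs(md - ga$truth_classes$depth[i]) / ga$truth_classes$depth[i],
              0.2)
    br <- mean(profs[[i]] >= 1)
    expect_lt(abs(br - ga$truth_classes$breadth[i]), 0.03)
  }
})

test_that("unigenes without introns emit no softclipped records", {
  cfg <- sim_config(seed = 17, n_unigenes = 4)
  tx <- simulate_transcriptome(cfg)
  ga <- simulate_genomic_alignments(cfg, tx$unigenes)
  expect_false(any(grepl("S", ga$alignments$cigar)))
})

test_that("planted junctions leave clustered clip boundaries at the junction", {
  cfg0 <- sim_config(seed = 19, n_unigenes = 3)
  tx <- simulate_transcriptome(cfg0)
  id <- names(tx$unigenes)[1]
  cfg <- sim_config(seed = 19, n_unigenes = 3,
                    unigene_classes = data.frame(n_peaks = 1, breadth = 0.98,
                                                 depth = 30),
                    intron_spec = setNames(list(500L), id))
  ga <- simulate_genomic_alignments(cfg, tx$unigenes)
  b <- collect_clip_boundaries(ga$alignments)
  expect_true(all(b$unigene_id == id))
  expect_true(all(abs(b$pos - 500L) <= 1L))
  expect_gte(sum(b$count), 5L)
  # a junction too close to the unigene end is a config error
  bad <- sim_config(seed = 19, n_unigenes = 3,
                    intron_spec = setNames(list(5L), id))
  expect_error(simulate_genomic_alignments(bad, tx$unigenes), "junction")
})

test_that("organelle features are valid CDS and truth SNVs are recoverable", {
  cfg <- sim_config(seed = 23, organelle_len = 20000L, n_cds = 6, n_trna = 2,
                    n_rrna = 1, organelle_depth = 20, n_snvs = 5,
                    snv_where = "cds")
  org <- simulate_organelle(cfg)
  gseq <- as.character(org$genome[[1]])
  for (g in org$genes) {
    if (g$kind != "CDS") next
    cds <- fabatools:::.cds_sequence(g, gseq)
    expect_equal(nchar(cds) %% 3L, 0L)
    expect_equal(substring(cds, 1, 3), "ATG")
    aa <- fabatools:::.translate_chr(cds)
    expect_equal(substring(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substring(aa, 1, nchar(aa) - 1L)))
  }
  # every truth SNV appears in (nearly) all covering reads at fraction 1
  aln <- org$alignments
  for (k in seq_len(nrow(org$truth_snvs))) {
    p0 <- org$truth_snvs$pos[k]
    tal <- oracle_base_tally(aln, p0)
    expect_gt(sum(tal), 0)
    expect_equal(as.integer(tal[org$truth_snvs$alt[k]]), sum(tal))
  }
  # an SNV spec with a wrong reference base is rejected
  bad_spec <- data.frame(pos = org$truth_snvs$pos[1],
                         ref = setdiff(c("A", "C", "G", "T"),
                                       org$truth_snvs$ref[1])[1],
                         alt = "A", fraction = 1)
  cfg_bad <- sim_config(seed = 23, organelle_len = 20000L, n_cds = 6,
                        n_trna = 2, n_rrna = 1, snv_spec = bad_spec)
  expect_error(simulate_organelle(cfg_bad), "mismatch")
})

test_that("intergenic truth SNVs are labelled NONCODING", {
  cfg <- sim_config(seed = 29, organelle_len = 20000L, n_cds = 4, n_trna = 1,
                    n_rrna = 1, organelle_depth = 12, n_snvs = 4,
                    snv_where = "intergenic")
  org <- simulate_organelle(cfg)
  expect_true(all(org$truth_snvs$effect == "NONCODING"))
})

test_that("marker/contig truth covers confirmed, extended and filtered", {
  mc <- simulate_markers_and_contigs(sim_config(seed = 31))
  expect_equal(mc$truth$status,
               c("confirmed", "extended", "extended", "extended", "filtered"))
  expect_equal(mc$truth$overhang, c(0L, 55L, 874L, 2995L, 0L))
  expect_equal(Biostrings::width(mc$contigs)[2] -
                 (min(2000L, 2800L)), 55L)
})

test_that("repeat assignments land at the configured fractions", {
  cfg <- sim_config(seed = 37)
  ra <- simulate_repeat_assignments(cfg, n_pairs = 20000L)
  fr <- attr(ra, "fractions")
  counts <- table(ra$class)
  for (cl in names(fr))
    expect_equal(as.integer(counts[cl]), as.integer(round(fr[cl] * 20000)))
})
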