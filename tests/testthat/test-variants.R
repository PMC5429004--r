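pileup_row <- function(pos, ref, counts, ref_id = "org") {
  full <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  full[names(counts)] <- counts
  data.frame(ref_id = ref_id, pos = pos, ref_base = ref,
             A = full["A"], C = full["C"], G = full["G"], T = full["T"],
             N = full["N"], del = 0L,
             depth = sum(full), row.names = NULL)
}

test_that("calling respects depth and allele-fraction thresholds", {
  # 50/50 site below fraction threshold
  p <- pileup_row(99L, "A", c(A = 25L, C = 25L))
  expect_equal(nrow(call_snvs(p)), 0L)
  # fixed alt
  p2 <- pileup_row(99L, "A", c(C = 50L))
  calls <- call_snvs(p2)
  expect_equal(calls$pos, 100L)   # reported 1-based
  expect_equal(calls$alt, "C")
  expect_equal(calls$alt_fraction, 1.0)
  # depth floor
  expect_equal(nrow(call_snvs(pileup_row(9L, "A", c(C = 9L)))), 0L)
  # alphabetical tie-break between equal alt counts
  p3 <- pileup_row(5L, "A", c(C = 10L, G = 10L))
  p3$depth <- 20L
  got <- call_snvs(p3, min_alt_fraction = 0.5)
  expect_equal(got$alt, "C")
})

test_that("codon-level annotation handles strand, SYN, missense and stops", {
  # gene on +: ATG AAA GGA TAA at 10..22; on -: revcomp at 40..52
  ref <- paste0(strrep("T", 10), "ATGAAAGGATAA", strrep("C", 18),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString("ATGAAAGGATAA"))), strrep("T", 10))
  genes <- list(gene_model("gp", "org", cbind(10L, 22L), "+", "CDS"),
                gene_model("gm", "org", cbind(40L, 52L), "-", "CDS"))
  # + strand: first codon ATG, A->C gives CTG = Leu (M->L)
  snv <- data.frame(ref_id = "org", pos = 11L, ref = "A", alt = "C",
                    depth = 50L, alt_fraction = 1)
  eff <- annotate_effects(snv, genes, ref)
  expect_equal(eff$effect, "MISSENSE")
  expect_equal(eff$aa_change, "M->L")
  expect_equal(eff$codon_index, 1L)
  # third position of GGA (4-fold degenerate): GGA->GGT is SYN
  snv2 <- data.frame(ref_id = "org", pos = 19L, ref = "A", alt = "T",
                     depth = 50L, alt_fraction = 1)
  expect_equal(annotate_effects(snv2, genes, ref)$effect, "SYN")
  # AAA -> TAA is a stop gain (K->STOP)
  snv3 <- data.frame(ref_id = "org", pos = 14L, ref = "A", alt = "T",
                     depth = 50L, alt_fraction = 1)
  e3 <- annotate_effects(snv3, genes, ref)
  expect_equal(e3$effect, "STOP_GAIN")
  expect_equal(e3$aa_change, "K->STOP")
  # intergenic position
  snv4 <- data.frame(ref_id = "org", pos = 5L, ref = "T", alt = "A",
                     depth = 50L, alt_fraction = 1)
  expect_equal(annotate_effects(snv4, genes, ref)$effect, "NONCODING")
  # minus-strand gene: genomic base at its last genomic position is the
  # complement of the first codon base; same M->L change as on plus
  snv5 <- data.frame(ref_id = "org", pos = 52L,
                     ref = substring(ref, 52, 52),
                     alt = "G",  # genomic A->G is CDS T->C? compute below
                     depth = 50L, alt_fraction = 1)
  e5 <- annotate_effects(snv5, genes, ref)
  oracle5 <- effect_by_translation(51L, substring(ref, 52, 52), "G", genes, ref)
  expect_equal(e5$effect, oracle5$effect)
  expect_equal(e5$ref_aa, oracle5$ref_aa)
  expect_equal(e5$alt_aa, oracle5$alt_aa)
})

test_that("strand symmetry: minus-strand annotation equals the plus-strand image", {
  set.seed(83)
  cds <- paste0("ATG", paste(sample(c("AAA", "GGA", "CTT", "TCA", "GAC"),
                                    30, TRUE), collapse = ""), "TAA")
  L <- 200L
  pad_l <- 50L
  plus_ref <- paste0(random_dna_str(pad_l), cds,
                     random_dna_str(L - pad_l - nchar(cds)))
  minus_ref <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus_ref)))
  iv_plus <- cbind(pad_l, pad_l + nchar(cds))
  iv_minus <- cbind(L - (pad_l + nchar(cds)), L - pad_l)
  g_plus <- list(gene_model("g", "org", iv_plus, "+", "CDS"))
  g_minus <- list(gene_model("g", "org", iv_minus, "-", "CDS"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (off in c(0L, 1L, 2L, 31L, 50L)) {
    pos_p <- pad_l + off                    # 0-based on plus reference
    pos_m <- L - 1L - pos_p                 # mirrored position
    refb <- substring(plus_ref, pos_p + 1L, pos_p + 1L)
    altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
    sp <- data.frame(ref_id = "org", pos = pos_p + 1L, ref = refb, alt = altb,
                     depth = 50L, alt_fraction = 1)
    sm <- data.frame(ref_id = "org", pos = pos_m + 1L,
                     ref = unname(comp[refb]), alt = unname(comp[altb]),
                     depth = 50L, alt_fraction = 1)
    ep <- annotate_effects(sp, g_plus, plus_ref)
    em <- annotate_effects(sm, g_minus, minus_ref)
    expect_equal(em$effect, ep$effect)
    expect_equal(em$ref_aa, ep$ref_aa)
    expect_equal(em$alt_aa, ep$alt_aa)
    expect_equal(em$codon_index, ep$codon_index)
  }
})

test_that("a CDS whose length is not divisible by 3 is a fatal annotation error", {
  expect_error(
    annotate_effects(
      data.frame(ref_id = "org", pos = 3L, ref = "A", alt = "C",
                 depth = 20L, alt_fraction = 1),
      list(gene_model("bad", "org", cbind(0L, 10L), "+", "CDS")),
      paste0("A", strrep("G", 99))),
    "divisible by 3")
})

test_that("simulated organelle: caller recovery and oracle equivalence", {
  cfg <- sim_config(seed = 89, organelle_len = 30000L, n_cds = 10, n_trna = 2,
                    n_rrna = 1, organelle_depth = 25, n_snvs = 10,
                    snv_where = "mixed")
  org <- simulate_organelle(cfg)
  sam <- tempfile(fileext = ".sam")
  write_alignments(org$alignments, sam)
  calls <- call_snvs(build_pileup(sam, org$genome))
  expect_setequal(calls$pos, org$truth_snvs$pos + 1L)   # recall & precision 1
  eff <- annotate_effects(calls, org$genes, org$genome)
  m <- match(eff$pos, org$truth_snvs$pos + 1L)
  expect_equal(eff$effect, org$truth_snvs$effect[m])
  expect_equal(eff$gene_id, org$truth_snvs$gene_id[m])
  # zero planted SNVs yield an empty call set
  cfg0 <- sim_config(seed = 89, organelle_len = 20000L, n_cds = 5, n_trna = 1,
                     n_rrna = 1, organelle_depth = 20, n_snvs = 0)
  org0 <- simulate_organelle(cfg0)
  sam0 <- tempfile(fileext = ".sam")
  write_alignments(org0$alignments, sam0)
  expect_equal(nrow(call_snvs(build_pileup(sam0, org0$genome))), 0L)
})

test_that("gene models round-trip through GFF3", {
  cfg <- sim_config(seed = 97, organelle_len = 20000L, n_cds = 5, n_trna = 2,
                    n_rrna = 1, organelle_depth = 10, n_snvs = 0)
  org <- simulate_organelle(cfg)
  gff <- tempfile(fileext = ".gff3")
  rtracklayer::export(org$gff, gff, format = "GFF3")
  back <- gene_models_from_gff(gff)
  expect_equal(length(back), length(org$genes))
  for (k in seq_along(back)) {
    orig <- org$genes[[which(vapply(org$genes, function(g) g$gene_id, "") ==
                               back[[k]]$gene_id)]]
    expect_equal(back[[k]]$intervals, orig$intervals)
    expect_equal(back[[k]]$strand, orig$strand)
    expect_equal(back[[k]]$kind, orig$kind)
  }
})

test_that("variant tables render amino-acid changes and round-trip as VCF", {
  cfg <- sim_config(seed = 101, organelle_len = 30000L, n_cds = 10, n_trna = 3,
                    n_rrna = 1, organelle_depth = 20, n_snvs = 8,
                    snv_where = "mixed")
  org <- simulate_organelle(cfg)
  sam <- tempfile(fileext = ".sam")
  write_alignments(org$alignments, sam)
  calls <- call_snvs(build_pileup(sam, org$genome))
  eff <- annotate_effects(calls, org$genes, org$genome)
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  tab <- write_variant_table(eff, tsv, vcf,
                             ref_lengths = attr(org$alignments, "ref_lengths"))
  expect_true(file.exists(tsv) && file.exists(vcf))
  back <- read_variant_vcf(vcf)
  expect_equal(back$pos, eff$pos)
  expect_equal(back$ref, eff$ref)
  expect_equal(back$alt, eff$alt)
  expect_equal(back$effect, eff$effect)
  expect_equal(back$aa_change, eff$aa_change)
  # STOP_GAIN renders as X->STOP
  sg <- eff[eff$effect == "STOP_GAIN", ]
  if (nrow(sg)) expect_true(all(grepl("->STOP$", sg$aa_change)))
  # empty effect list still writes a header-only TSV and a valid VCF
  e0 <- eff[0, ]
  tsv0 <- tempfile(fileext = ".tsv"); vcf0 <- tempfile(fileext = ".vcf")
  write_variant_table(e0, tsv0, vcf0, ref_lengths = c(organelle_1 = 1000L))
  expect_equal(nrow(read.delim(tsv0)), 0L)
  expect_equal(nrow(read_variant_vcf(vcf0)), 0L)
})
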