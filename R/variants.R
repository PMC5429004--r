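# Organelle SNV calling and codon-level effect annotation. Positions inside
# SnvRecord tables are 1-based (the reporting/VCF convention); gene model
# intervals are internal 0-based half-open.

#' Gene model constructor
#'
#' @param gene_id Unique feature id.
#' @param ref_id Reference sequence the feature lies on.
#' @param intervals Two-column matrix of 0-based half-open intervals, sorted
#'   by genomic start, non-overlapping. Their total width must be divisible
#'   by 3 for CDS features.
#' @param strand `"+"` or `"-"`.
#' @param kind Feature kind: `"CDS"`, `"tRNA"`, `"rRNA"`, or `"other"`.
#' @param gene_name Display name (defaults to `gene_id`).
#' @param codon_table Genetic code id; only the standard code (1) is
#'   supported.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, ref_id, intervals, strand, kind = "CDS",
                       gene_name = gene_id, codon_table = 1L) {
  intervals <- matrix(as.integer(intervals), ncol = 2)
  stopifnot(all(intervals[, 2] > intervals[, 1]),
            strand %in% c("+", "-"),
            kind %in% c("CDS", "tRNA", "rRNA", "other"),
            codon_table == 1L)
  if (nrow(intervals) > 1 &&
      any(intervals[-1, 1] < intervals[-nrow(intervals), 2]))
    .stopf("gene '%s': overlapping or unsorted CDS intervals", gene_id)
  structure(list(gene_id = gene_id, gene_name = gene_name, ref_id = ref_id,
                 intervals = intervals, strand = strand, kind = kind,
                 codon_table = 1L),
            class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Keeps `CDS`, `tRNA` and `rRNA` features, grouping multi-interval CDS by
#' their `ID` attribute. GFF3 1-based closed coordinates are converted to
#' the internal 0-based half-open convention.
#'
#' @param path GFF3 file path, or a `GRanges` already imported.
#' @return List of [gene_model()] objects.
#' @export
gene_models_from_gff <- function(path) {
  gr <- if (is.character(path)) rtracklayer::import(path, format = "GFF3") else path
  gr <- gr[gr$type %in% c("CDS", "tRNA", "rRNA")]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) .stopf("GFF3 features need ID attributes")
  nm <- if (!is.null(gr$Name)) gr$Name else ids
  out <- lapply(split(seq_along(gr), ids), function(i) {
    sub <- gr[i]
    o <- order(GenomicRanges::start(sub))
    sub <- sub[o]
    gene_model(
      gene_id = ids[i][1], ref_id = as.character(GenomicRanges::seqnames(sub))[1],
      intervals = cbind(GenomicRanges::start(sub) - 1L, GenomicRanges::end(sub)),
      strand = as.character(GenomicRanges::strand(sub))[1],
      kind = as.character(sub$type)[1], gene_name = nm[i][1])
  })
  unname(out[order(vapply(out, function(g) g$intervals[1, 1], 0))])
}

.ref_char <- function(ref, ref_id) {
  if (is.character(ref) && length(ref) == 1L && !file.exists(ref)) return(ref)
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  names(ref) <- sub("\\s.*$", "", names(ref))
  as.character(ref[[ref_id]])
}

# Spliced CDS sequence in reading orientation (character).
.cds_sequence <- function(gene, refseq) {
  parts <- apply(gene$intervals, 1, function(iv)
    substring(refseq, iv[1] + 1L, iv[2]))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# Plain table-1 translation; no initiator-codon special-casing, so a start
# codon mutated away from ATG is classified like any other codon change.
.translate_chr <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "solve"))
}

.find_gene <- function(pos0, genes) {
  for (g in genes) {
    if (any(pos0 >= g$intervals[, 1] & pos0 < g$intervals[, 2])) return(g)
  }
  NULL
}

# CDS-relative 0-based offset of a genomic position, in reading orientation.
.cds_offset <- function(gene, pos0) {
  widths <- gene$intervals[, 2] - gene$intervals[, 1]
  total <- sum(widths)
  hit <- which(pos0 >= gene$intervals[, 1] & pos0 < gene$intervals[, 2])
  fwd <- sum(widths[seq_len(hit - 1L)]) + (pos0 - gene$intervals[hit, 1])
  if (gene$strand == "+") fwd else total - 1L - fwd
}

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Call single-nucleotide variants from pileup columns
#'
#' Emits a call where the most frequent non-reference base reaches the
#' allele-fraction and depth thresholds; the defaults (depth >= 10,
#' fraction >= 0.8) target near-homoplasmic organelle variants. One alt per
#' site: highest count, ties broken alphabetically.
#'
#' @param pileup Data frame from [build_pileup()].
#' @param min_depth Minimum column depth for a call.
#' @param min_alt_fraction Minimum alt count / depth.
#' @return Data frame `ref_id`, `pos` (1-based), `ref`, `alt`, `depth`,
#'   `alt_fraction`, sorted by position.
#' @export
call_snvs <- function(pileup, min_depth = 10L, min_alt_fraction = 0.8) {
  bases <- c("A", "C", "G", "T")
  empty <- data.frame(ref_id = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(),
                      alt_fraction = numeric())
  if (nrow(pileup) == 0L) return(empty)
  cnt <- as.matrix(pileup[, bases])
  ridx <- match(pileup$ref_base, bases)
  ok <- !is.na(ridx)
  cnt_alt <- cnt
  cnt_alt[cbind(seq_len(nrow(cnt)), ridx)[ok, , drop = FALSE]] <- -1L
  best <- max.col(cnt_alt, ties.method = "first")   # alphabetical tie-break
  alt_count <- cnt_alt[cbind(seq_len(nrow(cnt)), best)]
  frac <- ifelse(pileup$depth > 0, alt_count / pileup$depth, 0)
  call <- ok & alt_count > 0L & pileup$depth >= min_depth &
    frac >= min_alt_fraction
  if (!any(call)) return(empty)
  out <- data.frame(ref_id = pileup$ref_id[call],
                    pos = pileup$pos[call] + 1L,
                    ref = pileup$ref_base[call],
                    alt = bases[best[call]],
                    depth = pileup$depth[call],
                    alt_fraction = frac[call])
  out[order(out$ref_id, out$pos), , drop = FALSE]
}

#' Annotate the codon-level effect of SNVs
#'
#' Locates the feature containing each variant; for CDS hits, splices the
#' CDS, reverse-complements minus-strand genes, and translates the
#' reference and alternate codons under the standard genetic code.
#' Substitutions in tRNA/rRNA genes get `NON_CODING_GENE` (printed as a
#' dash), and positions outside any feature get `NONCODING`.
#'
#' @param snvs Data frame from [call_snvs()] (`pos` 1-based).
#' @param genes List of [gene_model()] objects.
#' @param ref Reference sequence: FASTA path, `DNAStringSet`, or a bare
#'   sequence string.
#' @return `snvs` with added columns `gene_id`, `gene_name`, `codon_index`
#'   (1-based; `NA` outside CDS), `ref_aa`, `alt_aa`, `effect`
#'   (`SYN`/`MISSENSE`/`STOP_GAIN`/`STOP_LOSS`/`NON_CODING_GENE`/`NONCODING`),
#'   and `aa_change` (e.g. `"M->L"`, `"G->STOP"`, `"-"` otherwise).
#' @export
annotate_effects <- function(snvs, genes, ref) {
  n <- nrow(snvs)
  out <- data.frame(gene_id = rep(NA_character_, n), gene_name = NA_character_,
                    codon_index = NA_integer_, ref_aa = NA_character_,
                    alt_aa = NA_character_, effect = NA_character_,
                    aa_change = "-", stringsAsFactors = FALSE)
  if (n == 0L) return(cbind(snvs, out))
  refseq <- NULL
  for (k in seq_len(n)) {
    pos0 <- snvs$pos[k] - 1L
    if (is.null(refseq) || attr(refseq, "id") != snvs$ref_id[k]) {
      refseq <- structure(.ref_char(ref, snvs$ref_id[k]), id = snvs$ref_id[k])
    }
    if (pos0 < 0L || pos0 >= nchar(refseq))
      .stopf("SNV position %d outside reference '%s'", snvs$pos[k], snvs$ref_id[k])
    g <- .find_gene(pos0, Filter(function(x) x$ref_id == snvs$ref_id[k], genes))
    if (is.null(g)) { out$effect[k] <- "NONCODING"; next }
    out$gene_id[k] <- g$gene_id
    out$gene_name[k] <- g$gene_name
    if (g$kind != "CDS") { out$effect[k] <- "NON_CODING_GENE"; next }
    total <- sum(g$intervals[, 2] - g$intervals[, 1])
    if (total %% 3L != 0L)
      .stopf("gene '%s': CDS length %d not divisible by 3", g$gene_id, total)
    off <- .cds_offset(g, pos0)
    ci <- off %/% 3L
    cds <- .cds_sequence(g, refseq)
    codon <- substring(cds, ci * 3L + 1L, ci * 3L + 3L)
    within <- off %% 3L
    alt_in_cds <- if (g$strand == "+") snvs$alt[k] else unname(.comp[snvs$alt[k]])
    alt_codon <- codon
    substr(alt_codon, within + 1L, within + 1L) <- alt_in_cds
    ref_aa <- .translate_chr(codon)
    alt_aa <- .translate_chr(alt_codon)
    out$codon_index[k] <- ci + 1L
    out$ref_aa[k] <- ref_aa
    out$alt_aa[k] <- alt_aa
    out$effect[k] <-
      if (ref_aa == alt_aa) "SYN"
      else if (alt_aa == "*") "STOP_GAIN"
      else if (ref_aa == "*") "STOP_LOSS"
      else "MISSENSE"
    out$aa_change[k] <- switch(out$effect[k],
      SYN = "-",
      STOP_GAIN = paste0(ref_aa, "->STOP"),
      STOP_LOSS = paste0("STOP->", alt_aa),
      MISSENSE = paste0(ref_aa, "->", alt_aa))
  }
  cbind(snvs, out)
}

#' Brute-force SNV effect by full-CDS translation
#'
#' Independent route to the effect call: mutate the whole reference,
#' re-splice, translate the entire CDS on both alleles, and compare the
#' protein sequences. Used to build simulator truth tables and as the
#' oracle that codon-level annotation must match.
#'
#' @param pos0 0-based genomic position of the substitution.
#' @param ref_base,alt_base Reference and alternate bases.
#' @param genes List of [gene_model()]s.
#' @param refseq Reference sequence as a bare character string.
#' @return List with `gene_id`, `effect`, `ref_aa`, `alt_aa`, `codon_index`.
#' @export
effect_by_translation <- function(pos0, ref_base, alt_base, genes, refseq) {
  if (substring(refseq, pos0 + 1L, pos0 + 1L) != ref_base)
    .stopf("reference base mismatch at %d", pos0)
  g <- .find_gene(pos0, genes)
  if (is.null(g))
    return(list(gene_id = NA_character_, effect = "NONCODING",
                ref_aa = NA_character_, alt_aa = NA_character_,
                codon_index = NA_integer_))
  if (g$kind != "CDS")
    return(list(gene_id = g$gene_id, effect = "NON_CODING_GENE",
                ref_aa = NA_character_, alt_aa = NA_character_,
                codon_index = NA_integer_))
  mut <- refseq
  substr(mut, pos0 + 1L, pos0 + 1L) <- alt_base
  p_ref <- .translate_chr(.cds_sequence(g, refseq))
  p_alt <- .translate_chr(.cds_sequence(g, mut))
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (!length(d))
    return(list(gene_id = g$gene_id, effect = "SYN",
                ref_aa = NA_character_, alt_aa = NA_character_,
                codon_index = .cds_offset(g, pos0) %/% 3L + 1L))
  ra <- substring(p_ref, d[1], d[1]); aa <- substring(p_alt, d[1], d[1])
  eff <- if (aa == "*") "STOP_GAIN" else if (ra == "*") "STOP_LOSS" else "MISSENSE"
  list(gene_id = g$gene_id, effect = eff, ref_aa = ra, alt_aa = aa,
       codon_index = d[1])
}

#' Write an annotated variant table as TSV and VCF v4.2
#'
#' @param effects Data frame from [annotate_effects()] (optionally with a
#'   `provean_score` column carried from an external predictor).
#' @param tsv Output TSV path (`NULL` to skip).
#' @param vcf Output VCF path (`NULL` to skip).
#' @param ref_lengths Named integer vector for the VCF contig header lines.
#' @return Invisibly, the TSV-shaped data frame.
#' @export
write_variant_table <- function(effects, tsv = NULL, vcf = NULL,
                                ref_lengths = NULL) {
  prov <- if ("provean_score" %in% names(effects)) effects$provean_score else
    rep(NA_real_, nrow(effects))
  tab <- data.frame(gene_id = effects$gene_id, gene_name = effects$gene_name,
                    position = effects$pos, ref = effects$ref,
                    alt = effects$alt, effect = effects$effect,
                    aa_change = effects$aa_change, provean_score = prov,
                    stringsAsFactors = FALSE)
  if (!is.null(tsv))
    write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(vcf)) {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=fabatools",
             if (!is.null(ref_lengths))
               sprintf("##contig=<ID=%s,length=%d>", names(ref_lengths),
                       as.integer(ref_lengths)),
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pileup depth\">",
             "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele fraction\">",
             "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Codon-level effect\">",
             "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Containing gene\">",
             "##INFO=<ID=AAC,Number=1,Type=String,Description=\"Amino acid change\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    dp <- if ("depth" %in% names(effects)) effects$depth else rep(".", nrow(effects))
    af <- if ("alt_fraction" %in% names(effects))
      sprintf("%.4f", effects$alt_fraction) else rep(".", nrow(effects))
    info <- sprintf("DP=%s;AF=%s;EFFECT=%s;GENE=%s;AAC=%s",
                    dp, af, effects$effect,
                    ifelse(is.na(effects$gene_id), ".", effects$gene_id),
                    effects$aa_change)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    effects$ref_id, effects$pos, effects$ref, effects$alt, info)
    writeLines(c(hdr, body), vcf)
  }
  invisible(tab)
}

#' Read SNV records back from a VCF written by [write_variant_table()]
#'
#' @param path VCF path.
#' @return Data frame `ref_id`, `pos` (1-based), `ref`, `alt`, `effect`,
#'   `gene_id`, `aa_change` (plus `depth`/`alt_fraction` when present).
#' @export
read_variant_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  info <- VariantAnnotation::info(v)
  alt <- as.character(unlist(rr$ALT))
  out <- data.frame(
    ref_id = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = alt,
    effect = as.character(info$EFFECT),
    gene_id = as.character(info$GENE),
    aa_change = as.character(info$AAC),
    stringsAsFactors = FALSE)
  if (!is.null(info$DP)) out$depth <- as.integer(info$DP)
  if (!is.null(info$AF)) out$alt_fraction <- as.numeric(info$AF)
  rownames(out) <- NULL
  out
}
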