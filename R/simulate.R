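# Truth-based simulator: emits FASTA/GFF3/SAM/VCF inputs directly from a
# known truth set, so every downstream stage can be checked exactly. SAM is
# written from truth geometry (no aligner), which guarantees the softclip
# structure the splice detector looks for.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state, so simulator calls are
#' reproducible without disturbing surrounding code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Bundles every tunable of the input simulator. Defaults describe the
#' sequencing context the pipeline targets: 100 bp reads, unigenes of
#' 300-3000 bp, a 130 kb plastome-like organelle with ~40 CDS, near-fixed
#' organelle SNVs (allele fraction 1), clean reads (error rate 0) at
#' constant base quality Q40.
#'
#' @param seed Master seed; every generator derives its own stream from it.
#'   Fixed seed implies byte-identical output files.
#' @param n_unigenes Number of transcriptome unigenes.
#' @param unigene_len_range Min/max unigene length (bp).
#' @param read_len Read length (bp).
#' @param unigene_classes Optional data frame with one row per unigene and
#'   columns `n_peaks`, `breadth` (target covered fraction), `depth`
#'   (target full-length mean depth). `NULL` designates a feasible mixture
#'   automatically.
#' @param intron_spec Optional named list: unigene id -> vector of 0-based
#'   transcript positions of exon-exon junctions (an intron sits behind
#'   each in the genome).
#' @param organelle_len Organelle reference length (bp).
#' @param n_cds,n_trna,n_rrna Feature counts on the organelle.
#' @param organelle_depth Target mean read depth over the organelle.
#' @param snv_spec Optional data frame `pos` (0-based), `ref`, `alt`,
#'   `fraction`; `NULL` plants `n_snvs` automatically.
#' @param n_snvs Number of SNVs to plant when `snv_spec` is `NULL`.
#' @param snv_where Where auto-planted SNVs go: `"mixed"`, `"cds"`, or
#'   `"intergenic"`.
#' @param snv_fraction Alt allele fraction for auto-planted SNVs.
#' @param marker_spec Data frame `marker_len`, `overhang`, `identity`
#'   (percent) describing one marker/contig pair per row.
#' @param repeat_fractions Named numeric vector of per-class read fractions
#'   (must sum to at most 1).
#' @param error_rate Uniform per-base substitution error rate for reads.
#' @param base_quality Constant Phred quality written for read bases.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_unigenes = 50L,
                       unigene_len_range = c(300L, 3000L),
                       read_len = 100L,
                       unigene_classes = NULL,
                       intron_spec = NULL,
                       organelle_len = 130000L,
                       n_cds = 40L, n_trna = 6L, n_rrna = 2L,
                       organelle_depth = 50,
                       snv_spec = NULL, n_snvs = 7L,
                       snv_where = c("mixed", "cds", "intergenic"),
                       snv_fraction = 1.0,
                       marker_spec = data.frame(
                         marker_len = c(3000L, 3000L, 3000L, 3000L, 3000L),
                         overhang   = c(0L, 55L, 874L, 2995L, 0L),
                         identity   = c(100, 100, 100, 100, 90)),
                       repeat_fractions = c("LTR/Gypsy" = 0.036,
                                            "VicSatellite" = 0.025,
                                            "LTR" = 0.021,
                                            "LTR/Copia" = 0.010,
                                            "rRNA" = 0.002),
                       error_rate = 0,
                       base_quality = 40L) {
  snv_where <- match.arg(snv_where)
  if (unigene_len_range[1] > unigene_len_range[2])
    .stopf("degenerate unigene length range (min > max)")
  if (sum(repeat_fractions) > 1)
    .stopf("repeat fractions sum to more than 1")
  if (error_rate < 0 || error_rate > 1) .stopf("error_rate outside [0,1]")
  cfg <- list(seed = as.integer(seed), n_unigenes = as.integer(n_unigenes),
              unigene_len_range = as.integer(unigene_len_range),
              read_len = as.integer(read_len),
              unigene_classes = unigene_classes, intron_spec = intron_spec,
              organelle_len = as.integer(organelle_len),
              n_cds = as.integer(n_cds), n_trna = as.integer(n_trna),
              n_rrna = as.integer(n_rrna), organelle_depth = organelle_depth,
              snv_spec = snv_spec, n_snvs = as.integer(n_snvs),
              snv_where = snv_where, snv_fraction = snv_fraction,
              marker_spec = marker_spec, repeat_fractions = repeat_fractions,
              error_rate = error_rate, base_quality = as.integer(base_quality))
  class(cfg) <- "sim_config"
  cfg
}

.qual_string <- function(len, q) strrep(rawToChar(as.raw(q + 33L)), len)

.apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate a reference transcriptome
#'
#' Uniform-random unigene sequences with deterministic ids
#' `unigene_0001`, ... at the configured seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `unigenes` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data frame `unigene_id`, `length`).
#' @export
simulate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 101L, {
    n <- cfg$n_unigenes
    if (n == 0L) {
      return(list(unigenes = Biostrings::DNAStringSet(),
                  truth = data.frame(unigene_id = character(), length = integer())))
    }
    lens <- sample(seq(cfg$unigene_len_range[1], cfg$unigene_len_range[2]),
                   n, replace = TRUE)
    seqs <- vapply(lens, .random_dna, "")
    ids <- sprintf("unigene_%04d", seq_len(n))
    ug <- Biostrings::DNAStringSet(seqs)
    names(ug) <- ids
    list(unigenes = ug, truth = data.frame(unigene_id = ids, length = lens))
  })
}

# Designate a feasible (peaks, breadth, depth) class per unigene, cycling
# through the bin structure of the verification table.
.designate_classes <- function(lens, read_len) {
  peak_opts <- c(1L, 2L, 4L, 11L)
  breadth_opts <- c(0.98, 0.70, 0.30)
  depth_opts <- c(5, 30, 150)
  n <- length(lens)
  cls <- data.frame(
    n_peaks = peak_opts[(seq_len(n) - 1L) %% 4L + 1L],
    breadth = breadth_opts[((seq_len(n) - 1L) %/% 4L) %% 3L + 1L],
    depth   = depth_opts[((seq_len(n) - 1L) %/% 12L) %% 3L + 1L])
  # shrink the peak count until the blocks (each >= read_len, gaps >= 1) fit
  for (i in seq_len(n)) {
    while (cls$n_peaks[i] > 1L &&
           (cls$n_peaks[i] * read_len > floor(cls$breadth[i] * lens[i]) ||
            cls$n_peaks[i] * (read_len + 1L) - 1L > lens[i]))
      cls$n_peaks[i] <- max(1L, cls$n_peaks[i] - 3L)
  }
  cls
}

# Lay out n disjoint covered blocks totalling ~breadth*len positions.
.layout_blocks <- function(len, n_blocks, breadth, read_len) {
  total_cov <- max(read_len * n_blocks, round(breadth * len))
  total_cov <- min(total_cov, len)
  base_len <- total_cov %/% n_blocks
  blk_len <- rep(base_len, n_blocks)
  blk_len[1] <- blk_len[1] + total_cov - sum(blk_len)
  gap_total <- len - total_cov
  # spread blocks with at least 1 bp gaps (guaranteed feasible by caller)
  n_gaps <- n_blocks - 1L
  gaps <- if (n_gaps > 0L) {
    g <- rep(max(1L, gap_total %/% (n_gaps + 1L)), n_gaps)
    g
  } else integer()
  starts <- integer(n_blocks)
  pos <- 0L
  for (b in seq_len(n_blocks)) {
    starts[b] <- pos
    pos <- pos + blk_len[b] + if (b <= n_gaps) gaps[b] else 0L
  }
  if (pos - (if (n_gaps > 0L) gaps[n_gaps] else 0L) > len) {
    starts <- pmin(starts, len - blk_len)
  }
  data.frame(start = starts, end = starts + blk_len)
}

#' Simulate genomic-read alignments against the transcriptome
#'
#' Emits SAM-style alignment records of unspliced genomic reads versus the
#' spliced unigenes. Reads that span a planted exon-exon junction are
#' emitted as two softclip-bearing records (the upstream fragment ends at
#' the junction with a trailing clip, the downstream fragment starts there
#' with a leading clip), so clip boundaries pile up exactly at the
#' junction. Each unigene receives its designated number of disjoint
#' coverage blocks, covered fraction, and full-length mean depth.
#'
#' @param cfg A [sim_config()].
#' @param unigenes Named [Biostrings::DNAStringSet] from
#'   [simulate_transcriptome()].
#' @return List with `alignments` (record data frame, `ref_lengths`
#'   attribute set), `truth_classes` (data frame `unigene_id`, `n_peaks`,
#'   `breadth`, `depth` as designated), and `truth_splice` (data frame
#'   `unigene_id`, `pos` of each planted junction).
#' @export
simulate_genomic_alignments <- function(cfg, unigenes) {
  stopifnot(inherits(cfg, "sim_config"))
  rl <- cfg$read_len
  lens <- Biostrings::width(unigenes)
  ids <- names(unigenes)
  cls <- cfg$unigene_classes
  if (is.null(cls)) cls <- .designate_classes(lens, rl)
  if (nrow(cls) == 1L && length(unigenes) > 1L)
    cls <- cls[rep(1L, length(unigenes)), , drop = FALSE]
  if (nrow(cls) != length(unigenes))
    .stopf("unigene_classes must have one row per unigene")
  min_clip <- 5L
  for (id in names(cfg$intron_spec)) {
    j <- cfg$intron_spec[[id]]
    L <- lens[match(id, ids)]
    if (any(j < rl / 4 | j > L - rl / 4))
      .stopf("junction in '%s' closer than read_len/4 to a unigene end", id)
  }
  with_seed(cfg$seed + 202L, {
    recs <- vector("list", length(unigenes))
    truth_splice <- list()
    for (i in seq_along(unigenes)) {
      id <- ids[i]; L <- lens[i]
      useq <- as.character(unigenes[[i]])
      blocks <- .layout_blocks(L, cls$n_peaks[i], cls$breadth[i], rl)
      junctions <- sort(cfg$intron_spec[[id]])
      if (length(junctions))
        truth_splice[[id]] <- data.frame(unigene_id = id, pos = junctions)
      # deterministic tiling guarantees every block position is covered
      starts <- integer()
      for (b in seq_len(nrow(blocks))) {
        bs <- blocks$start[b]; be <- blocks$end[b]
        tile <- seq(bs, be - rl, by = rl)
        if (max(tile) < be - rl) tile <- c(tile, be - rl)
        tile <- c(tile, be - rl)
        starts <- c(starts, unique(tile))
      }
      n_reads <- max(length(starts), round(cls$depth[i] * L / rl))
      extra <- n_reads - length(starts)
      if (extra > 0L) {
        wts <- blocks$end - blocks$start - rl + 1L
        pick <- sample.int(nrow(blocks), extra, replace = TRUE, prob = pmax(wts, 1))
        starts <- c(starts, blocks$start[pick] +
                      floor(stats::runif(extra) * pmax(wts[pick], 1)))
      }
      # keep junctions clear of read ends so clips are >= min_clip
      if (length(junctions)) {
        for (j in junctions) {
          near_end <- starts > j - rl & starts <= j - rl + min_clip
          starts[near_end] <- j - rl            # read ends exactly at j
          near_start <- starts >= j - min_clip & starts < j
          starts[near_start] <- j               # read starts exactly at j
        }
      }
      n <- length(starts)
      strand_rev <- stats::runif(n) < 0.5
      qn <- sprintf("%s_read_%05d", id, seq_len(n))
      cross <- rep(NA_integer_, n)
      for (j in junctions)
        cross[is.na(cross) & starts < j & starts + rl > j] <- j
      plain <- is.na(cross)
      out <- list()
      if (any(plain)) {
        s <- starts[plain]
        out$plain <- data.frame(
          query_id = qn[plain], flag = ifelse(strand_rev[plain], 16L, 0L),
          ref_id = id, ref_start = s, mapq = 60L,
          cigar = sprintf("%dM", rl),
          strand = ifelse(strand_rev[plain], "-", "+"),
          seq = substring(useq, s + 1L, s + rl),
          qual = .qual_string(rl, cfg$base_quality),
          stringsAsFactors = FALSE)
      }
      if (any(!plain)) {
        s <- starts[!plain]; j <- cross[!plain]
        up_m <- j - s            # matched length of the upstream fragment
        dn_m <- rl - up_m
        intron_up <- vapply(dn_m, .random_dna, "")
        intron_dn <- vapply(up_m, .random_dna, "")
        out$up <- data.frame(
          query_id = paste0(qn[!plain], "_5p"),
          flag = ifelse(strand_rev[!plain], 16L, 0L),
          ref_id = id, ref_start = s, mapq = 60L,
          cigar = sprintf("%dM%dS", up_m, dn_m),
          strand = ifelse(strand_rev[!plain], "-", "+"),
          seq = paste0(substring(useq, s + 1L, j), intron_up),
          qual = .qual_string(rl, cfg$base_quality),
          stringsAsFactors = FALSE)
        out$dn <- data.frame(
          query_id = paste0(qn[!plain], "_3p"),
          flag = ifelse(strand_rev[!plain], 16L, 0L),
          ref_id = id, ref_start = j, mapq = 60L,
          cigar = sprintf("%dS%dM", up_m, dn_m),
          strand = ifelse(strand_rev[!plain], "-", "+"),
          seq = paste0(intron_dn, substring(useq, j + 1L, j + dn_m)),
          qual = .qual_string(rl, cfg$base_quality),
          stringsAsFactors = FALSE)
      }
      recs[[i]] <- do.call(rbind, out)
    }
    aln <- do.call(rbind, recs)
    rownames(aln) <- NULL
    aln$seq <- .apply_errors(aln$seq, cfg$error_rate)
    aln$is_unmapped <- FALSE
    aln$is_secondary <- FALSE
    aln$is_paired <- FALSE
    attr(aln, "ref_lengths") <- setNames(lens, ids)
    truth_classes <- data.frame(unigene_id = ids, n_peaks = cls$n_peaks,
                                breadth = cls$breadth, depth = cls$depth)
    ts <- if (length(truth_splice)) do.call(rbind, truth_splice) else
      data.frame(unigene_id = character(), pos = integer())
    rownames(ts) <- NULL
    list(alignments = aln, truth_classes = truth_classes, truth_splice = ts)
  })
}

# ---- organelle -------------------------------------------------------------

.random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  codons[1] <- "ATG"
  for (k in seq(2L, n_codons - 1L)) {
    repeat {
      c3 <- .random_dna(3L)
      if (!c3 %in% stops) break
    }
    codons[k] <- c3
  }
  codons[n_codons] <- sample(stops, 1L)
  paste(codons, collapse = "")
}

#' Simulate an organelle genome, its annotation, reads, and truth variants
#'
#' Builds a circular-organelle-style reference with annotated CDS (valid
#' start/stop on the annotated strand, lengths divisible by 3) plus a few
#' tRNA/rRNA features, plants near-fixed SNVs into uniformly placed reads at
#' the configured allele fraction, and records each SNV's codon effect in a
#' truth table computed by brute-force full-CDS translation.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named [Biostrings::DNAStringSet]),
#'   `genes` (gene model list, see [gene_model()]), `gff` (a
#'   [GenomicRanges::GRanges] exportable as GFF3), `alignments` (record
#'   data frame), and `truth_snvs` (data frame `pos` (0-based), `ref`,
#'   `alt`, `fraction`, `gene_id`, `effect`, `ref_aa`, `alt_aa`).
#' @export
simulate_organelle <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 303L, {
    L <- cfg$organelle_len
    ref_id <- "organelle_1"
    genome <- .random_dna(L)
    # non-overlapping feature placement on a regular grid with jitter
    n_feat <- cfg$n_cds + cfg$n_trna + cfg$n_rrna
    feat_len <- c(3L * sample(100:300, cfg$n_cds, replace = TRUE),
                  rep(75L, cfg$n_trna), rep(1500L, cfg$n_rrna))
    kind <- c(rep("CDS", cfg$n_cds), rep("tRNA", cfg$n_trna),
              rep("rRNA", cfg$n_rrna))
    ord <- sample.int(n_feat)
    feat_len <- feat_len[ord]; kind <- kind[ord]
    slot <- L %/% n_feat
    if (max(feat_len) + 2L > slot)
      .stopf("organelle too short for the requested features")
    starts <- (seq_len(n_feat) - 1L) * slot +
      floor(stats::runif(n_feat) * (slot - feat_len - 1L))
    strand <- sample(c("+", "-"), n_feat, replace = TRUE)
    genes <- vector("list", n_feat)
    for (i in seq_len(n_feat)) {
      gid <- sprintf("%s_%03d", tolower(kind[i]), i)
      fseq <- if (kind[i] == "CDS") .random_cds(feat_len[i] %/% 3L) else
        .random_dna(feat_len[i])
      ins <- if (strand[i] == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(fseq)))
      else fseq
      substr(genome, starts[i] + 1L, starts[i] + feat_len[i]) <- ins
      genes[[i]] <- gene_model(gid, ref_id,
                               intervals = cbind(starts[i], starts[i] + feat_len[i]),
                               strand = strand[i], kind = kind[i],
                               gene_name = gid)
    }
    # plant SNVs (pairwise distance >= 3 so codon effects are independent)
    spec <- cfg$snv_spec
    if (is.null(spec)) {
      in_cds <- unlist(lapply(genes[kind == "CDS"], function(g)
        seq(g$intervals[1, 1], g$intervals[1, 2] - 1L)))
      intergenic <- setdiff(seq_len(L) - 1L,
                            unlist(lapply(genes, function(g)
                              seq(g$intervals[1, 1], g$intervals[1, 2] - 1L))))
      pool <- switch(cfg$snv_where,
                     cds = in_cds, intergenic = intergenic,
                     mixed = c(sample(in_cds, ceiling(cfg$n_snvs * 0.7)),
                               sample(intergenic, cfg$n_snvs)))
      pos <- integer()
      for (p in sample(pool)) {
        if (length(pos) >= cfg$n_snvs) break
        if (!length(pos) || min(abs(pos - p)) >= 3L) pos <- c(pos, p)
      }
      pos <- sort(pos)
      refb <- if (length(pos)) substring(genome, pos + 1L, pos + 1L) else character()
      altb <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "", USE.NAMES = FALSE)
      spec <- data.frame(pos = pos, ref = refb, alt = as.character(altb),
                         fraction = rep(cfg$snv_fraction, length(pos)))
    } else if (nrow(spec)) {
      refb <- substring(genome, spec$pos + 1L, spec$pos + 1L)
      if (any(refb != spec$ref))
        .stopf("snv_spec reference base mismatches the simulated genome at %d",
               spec$pos[which(refb != spec$ref)[1]])
    }
    # truth effects by brute-force translation of the whole mutated CDS
    eff <- lapply(seq_len(nrow(spec)), function(k)
      effect_by_translation(spec$pos[k], spec$ref[k], spec$alt[k], genes, genome))
    truth <- if (nrow(spec)) {
      cbind(spec, do.call(rbind, lapply(eff, as.data.frame)))
    } else {
      cbind(spec, data.frame(gene_id = character(), effect = character(),
                             ref_aa = character(), alt_aa = character(),
                             codon_index = integer()))
    }
    # reads
    rl <- cfg$read_len
    n_reads <- round(cfg$organelle_depth * L / rl)
    s <- floor(stats::runif(n_reads) * (L - rl + 1L))
    seqs <- substring(genome, s + 1L, s + rl)
    for (k in seq_len(nrow(spec))) {
      p <- spec$pos[k]
      covers <- which(s <= p & s + rl > p)
      carry <- covers[stats::runif(length(covers)) < spec$fraction[k]]
      if (length(carry))
        substr(seqs[carry], p - s[carry] + 1L, p - s[carry] + 1L) <- spec$alt[k]
    }
    seqs <- .apply_errors(seqs, cfg$error_rate)
    strand_rev <- stats::runif(n_reads) < 0.5
    aln <- data.frame(
      query_id = sprintf("org_read_%06d", seq_len(n_reads)),
      flag = ifelse(strand_rev, 16L, 0L), ref_id = ref_id, ref_start = s,
      mapq = 60L, cigar = sprintf("%dM", rl),
      strand = ifelse(strand_rev, "-", "+"), seq = seqs,
      qual = .qual_string(rl, cfg$base_quality), stringsAsFactors = FALSE)
    aln$is_unmapped <- FALSE; aln$is_secondary <- FALSE; aln$is_paired <- FALSE
    attr(aln, "ref_lengths") <- setNames(L, ref_id)
    gseq <- Biostrings::DNAStringSet(genome)
    names(gseq) <- ref_id
    gff <- GenomicRanges::GRanges(
      seqnames = ref_id,
      ranges = IRanges::IRanges(start = starts + 1L, width = feat_len),
      strand = strand,
      type = kind,
      ID = vapply(genes, function(g) g$gene_id, ""),
      Name = vapply(genes, function(g) g$gene_name, ""),
      phase = ifelse(kind == "CDS", 0L, NA_integer_))
    GenomeInfoDb::seqlengths(gff) <- setNames(L, ref_id)
    list(genome = gseq, genes = genes, gff = gff, alignments = aln,
         truth_snvs = truth)
  })
}

# ---- markers & contigs -----------------------------------------------------

#' Simulate linkage markers and de novo contigs with known extension truth
#'
#' Each row of `cfg$marker_spec` yields one marker and one contig. With
#' `overhang = 0` the contig is an internal marker substring (truth
#' "confirmed", 0 bp added); otherwise the contig is the tail of the marker
#' plus `overhang` novel bases (truth `bp_added = overhang`). Identity below
#' 100 is imposed by random substitutions in the marker-matching portion;
#' below the matching criterion the truth label is "filtered". Contigs are
#' reverse-complemented at random.
#'
#' @param cfg A [sim_config()].
#' @return List with `markers`, `contigs` (named
#'   [Biostrings::DNAStringSet]s) and `truth` (data frame `marker_id`,
#'   `contig_id`, `overhang`, `identity`, `status`).
#' @export
simulate_markers_and_contigs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  spec <- cfg$marker_spec
  with_seed(cfg$seed + 404L, {
    n <- nrow(spec)
    markers <- character(n); contigs <- character(n)
    status <- character(n); rc <- logical(n)
    for (i in seq_len(n)) {
      ml <- spec$marker_len[i]; ov <- spec$overhang[i]; idy <- spec$identity[i]
      markers[i] <- .random_dna(ml)
      anchor <- min(2000L, ml - 200L)   # marker-matching portion of the contig
      if (ov == 0L) {
        cs <- 100L
        contig <- substring(markers[i], cs + 1L, cs + anchor)
      } else {
        contig <- paste0(substring(markers[i], ml - anchor + 1L, ml),
                         .random_dna(ov))
      }
      if (idy < 100) {
        nmut <- round((100 - idy) / 100 * anchor)
        at <- sample.int(anchor, nmut)
        ch <- strsplit(contig, "")[[1]]
        ch[at] <- vapply(ch[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        contig <- paste(ch, collapse = "")
      }
      rc[i] <- stats::runif(1) < 0.5
      if (rc[i])
        contig <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(contig)))
      contigs[i] <- contig
      status[i] <- if (idy <= 95) "filtered" else if (ov == 0L) "confirmed" else "extended"
    }
    mids <- sprintf("marker_%03d", seq_len(n))
    cids <- sprintf("contig_%03d", seq_len(n))
    mset <- Biostrings::DNAStringSet(markers); names(mset) <- mids
    cset <- Biostrings::DNAStringSet(contigs); names(cset) <- cids
    list(markers = mset, contigs = cset,
         truth = data.frame(marker_id = mids, contig_id = cids,
                            overhang = spec$overhang, identity = spec$identity,
                            status = status, revcomp = rc))
  })
}

#' Simulate repeat-class assignments for genomic read pairs
#'
#' Assigns read pairs to repeat-element classes at the configured
#' fractions (deterministic counts at fixed seed); the remainder is left
#' uncharacterized (`NA`).
#'
#' @param cfg A [sim_config()].
#' @param n_pairs Number of read pairs.
#' @return Data frame `read_id`, `class` (`NA` = uncharacterized) with the
#'   truth fractions attached as attribute `fractions`.
#' @export
simulate_repeat_assignments <- function(cfg, n_pairs = 10000L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 505L, {
    fr <- cfg$repeat_fractions
    counts <- round(fr * n_pairs)
    cls <- rep(NA_character_, n_pairs)
    idx <- sample.int(n_pairs)
    at <- 0L
    for (k in seq_along(counts)) {
      if (counts[k] > 0L)
        cls[idx[(at + 1L):(at + counts[k])]] <- names(fr)[k]
      at <- at + counts[k]
    }
    out <- data.frame(read_id = sprintf("pair_%06d", seq_len(n_pairs)),
                      class = cls, stringsAsFactors = FALSE)
    attr(out, "fractions") <- fr
    out
  })
}
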