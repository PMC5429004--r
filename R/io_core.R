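#' @import methods
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

# Internal convention: coordinates are 0-based, intervals half-open.
# SAM/GFF3/VCF files are 1-based; conversion happens only at the file
# boundary, in this module.

SAM_FLAG_PAIRED        <- 1L
SAM_FLAG_UNMAPPED      <- 4L
SAM_FLAG_REVERSE       <- 16L
SAM_FLAG_SECONDARY     <- 256L
SAM_FLAG_SUPPLEMENTARY <- 2048L

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.is_sam <- function(path) grepl("\\.sam$", path, ignore.case = TRUE)

# Convert a SAM file to (unsorted, record-order-preserving) BAM; pass BAM
# through untouched.
.as_bam <- function(path, index = FALSE) {
  if (.is_sam(path)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = index),
      error = function(e) .stopf("failed to parse '%s': %s", path, conditionMessage(e))
    )
    bam
  } else {
    if (!index) return(path)
    dest <- tempfile(fileext = "")
    Rsamtools::sortBam(path, dest)
    Rsamtools::indexBam(paste0(dest, ".bam"))
    paste0(dest, ".bam")
  }
}

#' Read alignment records from a SAM or BAM file
#'
#' Parses all records (including unmapped ones, flagged so that read
#' accounting can count them) into a data frame, one row per alignment
#' record, preserving file order. Reference start positions are converted to
#' the package-internal 0-based convention.
#'
#' @param path Path to a SAM (`.sam`) or BAM file with a complete header
#'   (`@SQ` lines naming every reference with its length).
#' @return A data frame with columns `query_id`, `flag`, `ref_id` (`NA` for
#'   unmapped records), `ref_start` (0-based), `mapq`, `cigar`, `strand`,
#'   `seq`, `qual`, and logicals `is_unmapped`, `is_secondary`, `is_paired`.
#'   Reference lengths from the header are attached as the named integer
#'   attribute `ref_lengths`.
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c("@HD\tVN:1.6", "@SQ\tSN:u1\tLN:50",
#'   "r1\t0\tu1\t1\t60\t5M\t*\t0\t0\tACGTA\tIIIII"), sam)
#' aln <- read_alignments(sam)
#' aln$ref_start  # 0: SAM position 1 is internal 0
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) .stopf("alignment file '%s' does not exist", path)
  bam <- .as_bam(path, index = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  flag <- b$flag
  aln <- data.frame(
    query_id  = b$qname,
    flag      = flag,
    ref_id    = as.character(b$rname),
    ref_start = b$pos - 1L,
    mapq      = b$mapq,
    cigar     = b$cigar,
    strand    = ifelse(bitwAnd(flag, SAM_FLAG_REVERSE) > 0L, "-", "+"),
    seq       = as.character(b$seq),
    qual      = as.character(b$qual),
    stringsAsFactors = FALSE
  )
  aln$is_unmapped  <- bitwAnd(flag, SAM_FLAG_UNMAPPED) > 0L
  aln$is_secondary <- bitwAnd(flag, SAM_FLAG_SECONDARY + SAM_FLAG_SUPPLEMENTARY) > 0L
  aln$is_paired    <- bitwAnd(flag, SAM_FLAG_PAIRED) > 0L
  mapped <- !aln$is_unmapped
  if (any(mapped & is.na(aln$ref_id)))
    .stopf("mapped record with reference absent from the header in '%s'", path)
  bad <- mapped & (aln$ref_start + cigar_ref_width(aln$cigar) >
                     unname(hdr[aln$ref_id]))
  if (any(bad, na.rm = TRUE))
    .stopf("record '%s' extends past the end of reference '%s'",
           aln$query_id[which(bad)[1]], aln$ref_id[which(bad)[1]])
  attr(aln, "ref_lengths") <- hdr
  aln
}

#' Write alignment records to a SAM file
#'
#' Inverse of [read_alignments()]: every retained field round-trips
#' bit-exactly. Mandatory SAM columns not carried by the record data frame
#' (`RNEXT`, `PNEXT`, `TLEN`) are written as unavailable.
#'
#' @param aln Alignment data frame as returned by [read_alignments()] (or
#'   built by the simulator).
#' @param path Output SAM path.
#' @param ref_lengths Named integer vector of reference lengths for the
#'   `@SQ` header lines; defaults to the `ref_lengths` attribute of `aln`.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path, ref_lengths = attr(aln, "ref_lengths")) {
  if (is.null(ref_lengths)) .stopf("ref_lengths required to write a SAM header")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths)))
  unmapped <- aln$is_unmapped
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  aln$query_id, aln$flag,
                  ifelse(unmapped, "*", aln$ref_id),
                  ifelse(unmapped, 0L, aln$ref_start + 1L),
                  ifelse(is.na(aln$mapq), 0L, aln$mapq),
                  ifelse(unmapped, "*", aln$cigar),
                  aln$seq, aln$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' CIGAR helpers
#'
#' `cigar_ref_width()` and `cigar_query_width()` give the number of
#' reference (M/D) and query (M/I/S) positions each CIGAR consumes;
#' `cigar_ops()` explodes one CIGAR into its ordered (op, length) list.
#'
#' @param cigar Character vector of CIGAR strings (`"*"` or `NA` give 0 / an
#'   empty op list).
#' @return Integer vector (widths) or a data frame with columns `op`, `len`.
#' @export
cigar_ref_width <- function(cigar) {
  w <- integer(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  w[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  w
}

#' @rdname cigar_ref_width
#' @export
cigar_query_width <- function(cigar) {
  w <- integer(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  w[ok] <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar[ok],
                                                        after.soft.clipping = FALSE)
  w
}

#' @rdname cigar_ref_width
#' @export
cigar_ops <- function(cigar) {
  stopifnot(length(cigar) == 1L)
  if (is.na(cigar) || cigar == "*")
    return(data.frame(op = character(), len = integer()))
  data.frame(op  = GenomicAlignments::explodeCigarOps(cigar)[[1]],
             len = GenomicAlignments::explodeCigarOpLengths(cigar)[[1]],
             stringsAsFactors = FALSE)
}

.usable <- function(aln, include_secondary = FALSE) {
  keep <- !aln$is_unmapped
  if (!include_secondary) keep <- keep & !aln$is_secondary
  keep
}

#' Per-base coverage over one reference
#'
#' Depth at position `i` (0-based) is the number of records whose
#' reference-consuming span (alignment matches and deletions; not softclips)
#' covers `i`. Secondary/supplementary alignments are excluded by default.
#'
#' @param aln Alignment data frame ([read_alignments()]).
#' @param ref_id Reference to profile.
#' @param ref_len Its length; defaults to the `ref_lengths` attribute.
#' @param include_secondary Count secondary/supplementary records too.
#' @return Integer vector of length `ref_len` (a coverage profile).
#' @export
compute_coverage <- function(aln, ref_id, ref_len = NULL,
                             include_secondary = FALSE) {
  if (is.null(ref_len)) ref_len <- attr(aln, "ref_lengths")[[ref_id]]
  if (is.null(ref_len) || ref_len <= 0) .stopf("ref_len must be positive")
  ref_len <- as.integer(ref_len)
  keep <- .usable(aln, include_secondary) & aln$ref_id %in% ref_id
  start0 <- aln$ref_start[keep]
  w <- cigar_ref_width(aln$cigar[keep])
  if (any(start0 + w > ref_len))
    .stopf("alignment extends past reference '%s' (length %d)", ref_id, ref_len)
  ir <- IRanges::IRanges(start = start0 + 1L, width = w)
  as.integer(IRanges::coverage(ir, width = ref_len))
}

#' Coverage profiles for every reference in one pass
#'
#' @inheritParams compute_coverage
#' @param ref_lengths Named integer vector; defaults to the attribute on `aln`.
#' @return Named list of integer coverage profiles, one per reference.
#' @export
coverage_profiles <- function(aln, ref_lengths = attr(aln, "ref_lengths"),
                              include_secondary = FALSE) {
  if (is.null(ref_lengths)) .stopf("ref_lengths required")
  keep <- .usable(aln, include_secondary)
  sub <- aln[keep, , drop = FALSE]
  w <- cigar_ref_width(sub$cigar)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(sub$ref_id, levels = names(ref_lengths)),
    ranges = IRanges::IRanges(start = sub$ref_start + 1L, width = w),
    seqlengths = ref_lengths)
  cov <- GenomicRanges::coverage(gr)
  lapply(setNames(names(ref_lengths), names(ref_lengths)),
         function(r) as.integer(cov[[r]]))
}

#' Pileup columns from an alignment file
#'
#' mpileup-style per-position base tallies over a reference, the substrate
#' of SNV calling. Base counts come from aligned (match/mismatch) bases
#' only; insertions and softclips are excluded, and deletion-spanning reads
#' count towards `depth` but contribute no base. Bases below the quality
#' floor are dropped. Positions with zero usable coverage are omitted.
#'
#' @param path SAM or BAM file of reads aligned to `ref`.
#' @param ref Reference as a [Biostrings::DNAStringSet] or FASTA path.
#' @param min_base_quality Phred floor for a base to be counted (default 13).
#' @param min_mapq Minimum mapping quality (default 0).
#' @param include_secondary Include secondary/supplementary records.
#' @param max_depth Per-position depth cap (set high; default 100000).
#' @return Data frame with columns `ref_id`, `pos` (0-based), `ref_base`,
#'   base counts `A`, `C`, `G`, `T`, `N`, `del` (deletion-spanning reads),
#'   and `depth` (sum of all seven tallies).
#' @export
build_pileup <- function(path, ref, min_base_quality = 13L, min_mapq = 0L,
                         include_secondary = FALSE, max_depth = 100000L) {
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  names(ref) <- sub("\\s.*$", "", names(ref))
  bam <- .as_bam(path, index = TRUE)
  flags <- if (include_secondary) {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  } else {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE)
  }
  pp <- Rsamtools::PileupParam(
    max_depth = as.integer(max_depth),
    min_base_quality = as.integer(min_base_quality),
    min_mapq = as.integer(min_mapq),
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    ignore_query_Ns = FALSE,
    include_deletions = TRUE,
    include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, scanBamParam = Rsamtools::ScanBamParam(flag = flags),
                         pileupParam = pp)
  if (nrow(p) == 0L) {
    return(data.frame(ref_id = character(), pos = integer(),
                      ref_base = character(), A = integer(), C = integer(),
                      G = integer(), T = integer(), N = integer(),
                      del = integer(), depth = integer()))
  }
  p$ref_id <- as.character(p$seqnames)
  key <- paste(p$ref_id, p$pos)
  ukey <- !duplicated(key)
  out <- data.frame(ref_id = p$ref_id[ukey], pos = p$pos[ukey] - 1L,
                    stringsAsFactors = FALSE)
  rownames(out) <- key[ukey]
  for (b in c("A", "C", "G", "T", "N", "-")) {
    cnt <- integer(nrow(out))
    sel <- p$nucleotide == b
    if (any(sel)) {
      tl <- tapply(p$count[sel], key[sel], sum)
      cnt[match(names(tl), rownames(out))] <- as.integer(tl)
    }
    out[[if (b == "-") "del" else b]] <- cnt
  }
  out$depth <- out$A + out$C + out$G + out$T + out$N + out$del
  rb <- character(nrow(out))
  for (r in unique(out$ref_id)) {
    i <- out$ref_id == r
    if (!r %in% names(ref)) .stopf("reference '%s' absent from FASTA", r)
    rb[i] <- strsplit(as.character(ref[[r]]), "")[[1]][out$pos[i] + 1L]
  }
  out$ref_base <- rb
  rownames(out) <- NULL
  out <- out[order(out$ref_id, out$pos), ]
  out[, c("ref_id", "pos", "ref_base", "A", "C", "G", "T", "N", "del", "depth")]
}

#' Round half away from zero at a fixed number of decimals
#'
#' Printed tables in this field round 0.005 up to 0.01; base `round()`
#' rounds half to even, so tallies use this helper.
#'
#' @param x Numeric vector (non-negative expected).
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}
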