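# Linkage-marker contig extension: match de novo contigs to full-length
# marker sequences under the 95/95 identity/coverage criterion, classify
# confirmed vs extending matches, and build merged locus sequences.

.revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

.nuc_matrix <- function(match, mismatch)
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = TRUE)

#' Match de novo contigs against linkage markers
#'
#' Local alignment of each contig (both strands) against each marker;
#' the best match per contig (highest identity x coverage) is kept.
#' Identity is matches / alignment columns (gaps count as mismatches).
#' Coverage is measured over the *alignable* portion of the contig: contig
#' bases whose projection falls beyond a marker end (the overhang that an
#' extension would add) are excluded from the denominator, so a contig
#' that fully spans a marker and hangs off one end still scores 100%.
#'
#' @param contigs,markers Named [Biostrings::DNAStringSet]s.
#' @param min_identity,min_coverage Match thresholds in percent (default
#'   95/95; matches must exceed them strictly).
#' @param min_contig_len Contigs shorter than this are skipped (default
#'   1000 bp, the usual pre-filter).
#' @param match,mismatch,gap_opening,gap_extension Local alignment scoring
#'   (defaults +1/-2/5/2; gap penalties are positive magnitudes).
#' @return Data frame with one row per retained contig: `contig_id`,
#'   `marker_id`, `identity_pct`, `contig_coverage_pct`, `orientation`
#'   (`forward`/`reverse-complement`), 0-based half-open spans
#'   `contig_start`, `contig_end` (in the oriented contig), `marker_start`,
#'   `marker_end`, `score`, and `passed`. Duplicate sequence ids are fatal.
#' @export
match_contigs <- function(contigs, markers, min_identity = 95,
                          min_coverage = 95, min_contig_len = 1000L,
                          match = 1, mismatch = -2,
                          gap_opening = 5, gap_extension = 2) {
  if (anyDuplicated(names(contigs)) || anyDuplicated(names(markers)))
    .stopf("duplicate sequence ids")
  submat <- .nuc_matrix(match, mismatch)
  contigs <- contigs[Biostrings::width(contigs) >= min_contig_len]
  rows <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    cid <- names(contigs)[i]
    cseq <- contigs[[i]]
    clen <- length(cseq)
    best <- NULL
    for (m in seq_along(markers)) {
      mseq <- markers[[m]]
      mlen <- length(mseq)
      for (orient in c("forward", "reverse-complement")) {
        q <- if (orient == "forward") cseq else
          Biostrings::reverseComplement(cseq)
        pa <- Biostrings::pairwiseAlignment(
          q, mseq, type = "local", substitutionMatrix = submat,
          gapOpening = gap_opening, gapExtension = gap_extension)
        cols <- nchar(as.character(Biostrings::pattern(pa)))
        if (cols == 0L) next
        idy <- 100 * Biostrings::nmatch(pa) / cols
        cs <- Biostrings::start(Biostrings::pattern(pa))
        ce <- Biostrings::end(Biostrings::pattern(pa))
        ms <- Biostrings::start(Biostrings::subject(pa))
        me <- Biostrings::end(Biostrings::subject(pa))
        ov_l <- max(0L, (cs - 1L) - (ms - 1L))
        ov_r <- max(0L, (clen - ce) - (mlen - me))
        alignable <- clen - ov_l - ov_r
        cov <- 100 * (ce - cs + 1L) / alignable
        cand <- data.frame(
          contig_id = cid, marker_id = names(markers)[m],
          identity_pct = idy, contig_coverage_pct = cov,
          orientation = orient,
          contig_start = cs - 1L, contig_end = ce,
          marker_start = ms - 1L, marker_end = me,
          score = Biostrings::score(pa),
          stringsAsFactors = FALSE)
        if (is.null(best) ||
            cand$identity_pct * cand$contig_coverage_pct >
              best$identity_pct * best$contig_coverage_pct)
          best <- cand
      }
    }
    rows[[i]] <- best
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(contig_id = character(), marker_id = character(),
                      identity_pct = numeric(), contig_coverage_pct = numeric(),
                      orientation = character(), contig_start = integer(),
                      contig_end = integer(), marker_start = integer(),
                      marker_end = integer(), score = numeric(),
                      passed = logical()))
  out$passed <- out$identity_pct > min_identity &
    out$contig_coverage_pct > min_coverage
  rownames(out) <- NULL
  out
}

#' Extend one marker with a matched contig
#'
#' A match whose contig lies entirely within the marker span confirms the
#' marker (`bp_added = 0`); contig bases projecting beyond either marker
#' end are appended (already in marker orientation, since reverse matches
#' are handled on the reverse-complemented contig) to form the merged
#' locus sequence.
#'
#' @param match One row of [match_contigs()] output (must have passed).
#' @param contig_seq,marker_seq The sequences (`DNAString` or character).
#' @return List `marker_id`, `contig_id`, `status`
#'   (`confirmed`/`extended`/`filtered`), `original_len`, `extended_len`,
#'   `bp_added`, `merged_sequence`.
#' @export
extend_marker <- function(match, contig_seq, marker_seq) {
  cs <- as.character(contig_seq)
  ms <- as.character(marker_seq)
  if (match$orientation == "reverse-complement") cs <- .revcomp_chr(cs)
  clen <- nchar(cs); mlen <- nchar(ms)
  if (!isTRUE(match$passed))
    return(list(marker_id = match$marker_id, contig_id = match$contig_id,
                status = "filtered", original_len = mlen, extended_len = mlen,
                bp_added = 0L, merged_sequence = ms))
  ov_l <- max(0L, match$contig_start - match$marker_start)
  ov_r <- max(0L, (clen - match$contig_end) - (mlen - match$marker_end))
  merged <- paste0(if (ov_l > 0L) substring(cs, 1L, ov_l) else "",
                   ms,
                   if (ov_r > 0L) substring(cs, clen - ov_r + 1L, clen) else "")
  bp <- ov_l + ov_r
  list(marker_id = match$marker_id, contig_id = match$contig_id,
       status = if (bp == 0L) "confirmed" else "extended",
       original_len = mlen, extended_len = mlen + bp, bp_added = bp,
       merged_sequence = merged)
}

#' Extend all markers from a match table
#'
#' One extension per marker end: when several passing contigs would extend
#' the same marker, overhangs are applied greedily longest-first and a
#' later contig whose overhang conflicts with an already-extended end is
#' reported as `filtered` (reason `conflicting-overhang`).
#'
#' @param matches [match_contigs()] output.
#' @param contigs,markers Named [Biostrings::DNAStringSet]s.
#' @return Data frame `marker_id`, `contig_id`, `status`, `original_len`,
#'   `extended_len`, `bp_added`, `reason`, plus the merged sequences as the
#'   attribute `merged` (named character vector, one per processed match).
#' @export
extend_markers <- function(matches, contigs, markers) {
  res <- list(); merged <- character()
  ord <- order(-(pmax(0L, matches$contig_start - matches$marker_start) +
                   pmax(0L, (Biostrings::width(contigs)[
                     match(matches$contig_id, names(contigs))] -
                       matches$contig_end) -
                     (Biostrings::width(markers)[
                       match(matches$marker_id, names(markers))] -
                        matches$marker_end))))
  used_end <- list()
  for (i in ord) {
    m <- matches[i, , drop = FALSE]
    ext <- extend_marker(m, contigs[[m$contig_id]], markers[[m$marker_id]])
    reason <- ""
    if (ext$status == "extended") {
      key_l <- paste0(m$marker_id, ":L"); key_r <- paste0(m$marker_id, ":R")
      ov_l <- max(0L, m$contig_start - m$marker_start)
      ov_r <- ext$bp_added - ov_l
      clash <- (ov_l > 0L && isTRUE(used_end[[key_l]])) ||
        (ov_r > 0L && isTRUE(used_end[[key_r]]))
      if (clash) {
        ext$status <- "filtered"; reason <- "conflicting-overhang"
        ext$bp_added <- 0L; ext$extended_len <- ext$original_len
        ext$merged_sequence <- as.character(markers[[m$marker_id]])
      } else {
        if (ov_l > 0L) used_end[[key_l]] <- TRUE
        if (ov_r > 0L) used_end[[key_r]] <- TRUE
      }
    }
    res[[length(res) + 1L]] <- data.frame(
      marker_id = ext$marker_id, contig_id = ext$contig_id,
      status = ext$status, original_len = ext$original_len,
      extended_len = ext$extended_len, bp_added = ext$bp_added,
      reason = reason, stringsAsFactors = FALSE)
    merged[paste(ext$marker_id, ext$contig_id, sep = "|")] <- ext$merged_sequence
  }
  out <- do.call(rbind, res)
  out <- out[order(out$marker_id, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "merged") <- merged
  out
}

#' Contig length histogram
#'
#' Counts contigs in fixed-width length bins between the shortest and
#' longest contig, with log10 abundance; zero-count bins carry `NA` in
#' `log10_count`.
#'
#' @param contigs A [Biostrings::DNAStringSet] (or integer lengths).
#' @param bin_width Bin width in bp (> 0).
#' @return Data frame `bin_start`, `bin_end`, `count`, `log10_count`.
#' @export
length_histogram <- function(contigs, bin_width = 100L) {
  if (bin_width <= 0) .stopf("bin_width must be positive")
  lens <- if (is.numeric(contigs)) as.integer(contigs) else
    Biostrings::width(contigs)
  if (!length(lens))
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer(), log10_count = numeric()))
  lo <- (min(lens) %/% bin_width) * bin_width
  hi <- ((max(lens) %/% bin_width) + 1L) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  cnt <- as.integer(table(cut(lens, breaks = breaks, right = FALSE,
                              include.lowest = TRUE)))
  data.frame(bin_start = breaks[-length(breaks)],
             bin_end = breaks[-1],
             count = cnt,
             log10_count = ifelse(cnt > 0L, log10(cnt), NA_real_))
}
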