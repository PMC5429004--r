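# Splice-point detection: unspliced genomic reads aligned to a spliced
# transcriptome leave softclips whose boundaries pile up at exon-exon
# junctions; clustered boundaries within a small window are called as
# putative splice points.

#' Collect softclip boundary positions
#'
#' For a leading softclip the boundary is the alignment start; for a
#' trailing softclip it is the alignment end (start + reference-consumed
#' length). Both ends of a doubly-clipped record are counted. Clips shorter
#' than `min_clip_len` are ignored as alignment noise.
#'
#' @param aln Alignment data frame ([read_alignments()]).
#' @param min_clip_len Minimum clip length to count (default 5).
#' @return Data frame `unigene_id`, `pos` (0-based boundary), `count`.
#' @export
collect_clip_boundaries <- function(aln, min_clip_len = 5L) {
  keep <- .usable(aln) & grepl("S", aln$cigar, fixed = TRUE)
  empty <- data.frame(unigene_id = character(), pos = integer(),
                      count = integer())
  if (!any(keep)) return(empty)
  sub <- aln[keep, , drop = FALSE]
  ops <- GenomicAlignments::explodeCigarOps(sub$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(sub$cigar)
  first_op <- vapply(ops, `[`, "", 1L)
  last_op <- vapply(ops, function(o) o[length(o)], "")
  first_len <- vapply(lens, `[`, 0L, 1L)
  last_len <- vapply(lens, function(l) l[length(l)], 0L)
  refw <- cigar_ref_width(sub$cigar)
  lead <- first_op == "S" & first_len >= min_clip_len
  trail <- last_op == "S" & last_len >= min_clip_len &
    !(lengths(ops) == 1L)   # a pure-S CIGAR cannot happen for mapped reads
  b <- rbind(
    data.frame(unigene_id = sub$ref_id[lead], pos = sub$ref_start[lead]),
    data.frame(unigene_id = sub$ref_id[trail],
               pos = sub$ref_start[trail] + refw[trail]))
  if (nrow(b) == 0L) return(empty)
  agg <- stats::aggregate(list(count = rep(1L, nrow(b))),
                          by = list(unigene_id = b$unigene_id, pos = b$pos),
                          FUN = sum)
  agg <- agg[order(agg$unigene_id, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Call splice points from clustered clip boundaries
#'
#' Slides a window of `window_size` positions over each unigene's boundary
#' counts; a window qualifies when its summed clip count reaches
#' `min_support` and also `min_fraction` of the local total (depth at the
#' modal boundary plus the clips, since clipped fragments need not count in
#' depth there). Qualifying windows are merged greedily (highest support
#' first, ties to the leftmost); each call is placed at the modal boundary
#' within its window. No two calls lie within `window_size` of each other.
#'
#' @param boundaries Data frame from [collect_clip_boundaries()].
#' @param profiles Named list of coverage profiles
#'   ([coverage_profiles()]), for the local-depth term.
#' @param window_size Window width in bp (default 2).
#' @param min_support Minimum summed clips in the window (default 5).
#' @param min_fraction Minimum clips / (local depth + clips) (default 0.1).
#' @return Data frame `unigene_id`, `pos` (0-based modal boundary),
#'   `support`, `window_start`, `window_end`, `local_depth`, sorted by
#'   unigene and position.
#' @export
call_splice_points <- function(boundaries, profiles, window_size = 2L,
                               min_support = 5L, min_fraction = 0.1) {
  if (window_size < 1L) .stopf("window_size must be at least 1")
  empty <- data.frame(unigene_id = character(), pos = integer(),
                      support = integer(), window_start = integer(),
                      window_end = integer(), local_depth = integer())
  if (nrow(boundaries) == 0L) return(empty)
  out <- list()
  for (id in unique(boundaries$unigene_id)) {
    b <- boundaries[boundaries$unigene_id == id, , drop = FALSE]
    prof <- profiles[[id]]
    cnt <- setNames(b$count, b$pos)
    positions <- b$pos
    # candidate windows: any window start that captures >= 1 boundary
    starts <- sort(unique(unlist(lapply(positions, function(p)
      (p - window_size + 1L):p))))
    starts <- starts[starts >= 0L]
    cand <- lapply(starts, function(ws) {
      inw <- positions >= ws & positions < ws + window_size
      if (!any(inw)) return(NULL)
      support <- sum(b$count[inw])
      inpos <- positions[inw]
      modal <- inpos[which.max(b$count[inw])]       # tie -> leftmost
      ld <- if (!is.null(prof) && modal + 1L <= length(prof))
        prof[modal + 1L] else 0L
      if (support < min_support) return(NULL)
      if (support < min_fraction * (ld + support)) return(NULL)
      data.frame(unigene_id = id, pos = modal, support = support,
                 window_start = ws, window_end = ws + window_size,
                 local_depth = ld)
    })
    cand <- do.call(rbind, cand)
    if (is.null(cand) || nrow(cand) == 0L) next
    # greedy merge: highest support first, ties leftmost
    cand <- cand[order(-cand$support, cand$pos), , drop = FALSE]
    taken <- integer()
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!length(taken) || all(abs(cand$pos[i] - taken) >= window_size)) {
        keep[i] <- TRUE
        taken <- c(taken, cand$pos[i])
      }
    }
    sel <- cand[keep, , drop = FALSE]
    sel <- sel[!duplicated(sel$pos), , drop = FALSE]
    out[[id]] <- sel
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$unigene_id, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' End-to-end splice-point detection from an alignment set
#'
#' @param aln Alignment data frame.
#' @param ref_lengths Named reference lengths (defaults to the attribute).
#' @inheritParams call_splice_points
#' @param min_clip_len Passed to [collect_clip_boundaries()].
#' @return List with `points` (the call table) and `summary` (one row:
#'   `unigenes_with_points`, `total_points`).
#' @export
detect_splice_points <- function(aln, ref_lengths = attr(aln, "ref_lengths"),
                                 window_size = 2L, min_support = 5L,
                                 min_fraction = 0.1, min_clip_len = 5L) {
  boundaries <- collect_clip_boundaries(aln, min_clip_len)
  profiles <- coverage_profiles(aln, ref_lengths)
  pts <- call_splice_points(boundaries, profiles, window_size,
                            min_support, min_fraction)
  list(points = pts,
       summary = data.frame(
         unigenes_with_points = length(unique(pts$unigene_id)),
         total_points = nrow(pts)))
}
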