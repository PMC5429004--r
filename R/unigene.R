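# Unigene verification: classify each unigene by number of coverage peaks,
# breadth bin and depth bin, and tabulate the composition.

PEAK_BINS    <- c("0", "1", "2-3", "4-10", ">10")
BREADTH_BINS <- c(">95%", "50-95%", "<50%")
DEPTH_BINS   <- c("<10", "10-100", ">100")

#' Find coverage peaks in a profile
#'
#' A peak is a maximal run of positions with depth at least `min_depth`;
#' runs separated by at most `max_gap` below-threshold positions are
#' merged. Peaks are treated as independent read clusters, so the default
#' `max_gap = 0` requires strict contiguity.
#'
#' @param profile Integer coverage vector (0-based positions).
#' @param min_depth Minimum depth for a position to count as covered.
#' @param max_gap Maximum uncovered gap merged into one peak.
#' @return Data frame `start`, `end` (0-based half-open), `mean_depth`
#'   (mean over the peak span); zero rows when nothing is covered.
#' @export
find_peaks <- function(profile, min_depth = 1L, max_gap = 0L) {
  covered <- profile >= min_depth
  if (!any(covered))
    return(data.frame(start = integer(), end = integer(), mean_depth = numeric()))
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (max_gap > 0L && nrow(runs) > 1L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L <= max_gap)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  data.frame(start = runs$start - 1L, end = runs$end,
             mean_depth = vapply(seq_len(nrow(runs)), function(i)
               mean(profile[runs$start[i]:runs$end[i]]), 0))
}

.peak_bin <- function(n) {
  if (n == 0L) "0" else if (n == 1L) "1" else if (n <= 3L) "2-3"
  else if (n <= 10L) "4-10" else ">10"
}
.breadth_bin <- function(b) {
  if (b > 95) ">95%" else if (b >= 50) "50-95%" else "<50%"
}
.depth_bin <- function(d) {
  if (d < 10) "<10" else if (d <= 100) "10-100" else ">100"
}

#' Classify one unigene from its coverage profile
#'
#' Breadth is the percentage of positions covered by at least one read;
#' mean depth is averaged over the full unigene length (the strict reading
#' of "average coverage per base"). Bin boundaries: breadth exactly 95 or
#' 50 falls in the middle bin; depth exactly 10 or 100 falls in `10-100`.
#'
#' @param profile Integer coverage vector.
#' @param unigene_id Id carried into the result.
#' @param min_depth,max_gap Passed to [find_peaks()].
#' @return One-row data frame `unigene_id`, `n_peaks`, `peak_bin`,
#'   `breadth_pct`, `breadth_bin`, `mean_depth`, `depth_bin`.
#' @export
classify_unigene <- function(profile, unigene_id = NA_character_,
                             min_depth = 1L, max_gap = 0L) {
  if (length(profile) == 0L) .stopf("zero-length unigene")
  peaks <- find_peaks(profile, min_depth, max_gap)
  breadth <- 100 * sum(profile >= 1L) / length(profile)
  md <- mean(profile)
  data.frame(unigene_id = unigene_id, n_peaks = nrow(peaks),
             peak_bin = .peak_bin(nrow(peaks)),
             breadth_pct = breadth, breadth_bin = .breadth_bin(breadth),
             mean_depth = md, depth_bin = .depth_bin(md),
             stringsAsFactors = FALSE)
}

#' Classify every unigene in an alignment set
#'
#' @param aln Alignment data frame ([read_alignments()]).
#' @param ref_lengths Named reference lengths (defaults to the attribute).
#' @param min_depth,max_gap Passed to [find_peaks()].
#' @return Data frame with one [classify_unigene()] row per reference.
#' @export
classify_unigenes <- function(aln, ref_lengths = attr(aln, "ref_lengths"),
                              min_depth = 1L, max_gap = 0L) {
  profs <- coverage_profiles(aln, ref_lengths)
  out <- do.call(rbind, lapply(names(profs), function(id)
    classify_unigene(profs[[id]], id, min_depth, max_gap)))
  rownames(out) <- NULL
  out
}

#' Tabulate unigene classes into the peaks x breadth x depth matrix
#'
#' @param classes Data frame of [classify_unigene()] rows.
#' @return Data frame with one row per (peak_bin, breadth_bin) and columns
#'   for the three depth bins plus `total`; every unigene falls in exactly
#'   one cell, so the cells sum to `nrow(classes)`.
#' @export
tabulate_classes <- function(classes) {
  pb <- factor(classes$peak_bin, levels = PEAK_BINS)
  bb <- factor(classes$breadth_bin, levels = BREADTH_BINS)
  db <- factor(classes$depth_bin, levels = DEPTH_BINS)
  tab <- table(pb, bb, db)
  grid <- expand.grid(breadth_bin = BREADTH_BINS, peak_bin = PEAK_BINS,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  out <- data.frame(grid,
                    `<10` = mapply(function(p, b) tab[p, b, "<10"],
                                   grid$peak_bin, grid$breadth_bin),
                    `10-100` = mapply(function(p, b) tab[p, b, "10-100"],
                                      grid$peak_bin, grid$breadth_bin),
                    `>100` = mapply(function(p, b) tab[p, b, ">100"],
                                    grid$peak_bin, grid$breadth_bin),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$total <- out$`<10` + out$`10-100` + out$`>100`
  rownames(out) <- NULL
  out
}
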