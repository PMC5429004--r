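# Compartment and repeat-class read bookkeeping: the partition of the
# genomic read pairs among chloroplast / mitochondrion / transcriptome /
# repeat databases / unaligned, with percentages at printed precision.

#' Compartment read accounting
#'
#' Partitions the total read pairs among disjoint compartment categories
#' (priority applied upstream: chloroplast > mitochondrion > transcriptome >
#' repeat database > unaligned) and reports each as a percentage of the
#' total, rounded half-up to two decimals. If the categories do not exhaust
#' the total, an `unaligned` residual row is appended so the rows always
#' partition the total.
#'
#' @param counts Named integer-ish vector of read-pair counts per category.
#' @param total_pairs Total number of read pairs (> 0).
#' @param depth Optional named numeric vector of depth estimates to carry
#'   per category (see [estimate_depth()]).
#' @return Data frame `category`, `pairs`, `percent` (2 dp), `depth`.
#' @export
account_compartments <- function(counts, total_pairs, depth = NULL) {
  if (total_pairs <= 0) .stopf("total_pairs must be positive")
  counts <- round(counts)
  if (sum(counts) > total_pairs)
    .stopf("category counts (%.0f) exceed the total (%.0f)",
           sum(counts), total_pairs)
  if (sum(counts) < total_pairs && !"unaligned" %in% names(counts))
    counts <- c(counts, unaligned = total_pairs - sum(counts))
  out <- data.frame(category = names(counts),
                    pairs = unname(counts),
                    percent = round_half_up(unname(counts) / total_pairs * 100, 2L),
                    stringsAsFactors = FALSE)
  out$depth <- if (is.null(depth)) NA_real_ else
    unname(depth[match(out$category, names(depth))])
  attr(out, "total_pairs") <- total_pairs
  out
}

#' Repeat-element tally
#'
#' Tallies best-hit repeat-class assignments per read pair into per-class
#' counts and percentages of the total (six decimals, the precision repeat
#' surveys print), with a repeat-total row (two decimals) and an
#' uncharacterized remainder.
#'
#' @param assignments Either a data frame with a `class` column (`NA` =
#'   uncharacterized), one row per read pair, or a named vector of
#'   per-class pair counts.
#' @param total_pairs Total read pairs the percentages are relative to.
#' @return List with `per_class` (data frame `class`, `pairs`, `percent`),
#'   `repeat_total` (`pairs`, `percent`) and `uncharacterized`
#'   (`pairs`, `percent`).
#' @export
tally_repeats <- function(assignments, total_pairs) {
  if (is.data.frame(assignments)) {
    cls <- assignments$class
    counts <- table(cls[!is.na(cls)])
    counts <- setNames(as.integer(counts), names(counts))
  } else {
    counts <- assignments
  }
  counts <- sort(counts, decreasing = TRUE)
  per_class <- data.frame(
    class = names(counts), pairs = unname(counts),
    percent = round_half_up(unname(counts) / total_pairs * 100, 6L),
    stringsAsFactors = FALSE)
  rt <- sum(counts)
  list(per_class = per_class,
       repeat_total = data.frame(
         pairs = rt, percent = round_half_up(rt / total_pairs * 100, 2L)),
       uncharacterized = data.frame(
         pairs = total_pairs - rt,
         percent = round_half_up((total_pairs - rt) / total_pairs * 100, 2L)))
}

#' Mean aligned depth over a reference
#'
#' @param aligned_bases Total aligned bases over the reference.
#' @param ref_len Reference length (> 0).
#' @return `aligned_bases / ref_len` (a coverage multiple, "x").
#' @export
estimate_depth <- function(aligned_bases, ref_len) {
  if (ref_len <= 0) .stopf("ref_len must be positive")
  aligned_bases / ref_len
}

#' Printed read-accounting inputs shipped with the package
#'
#' Loads the compartment and repeat-class paired-read counts used by the
#' worked accounting examples (from `inst/extdata/`): `compartments` gives
#' per-compartment pair counts plus the grand total; `repeats` gives the
#' per-class repeat counts.
#'
#' @param which `"compartments"` or `"repeats"`.
#' @return Data frame as stored.
#' @export
faba_read_counts <- function(which = c("compartments", "repeats")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("faba_", which, "_read_counts.tsv"),
                   package = "fabatools", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE)
}
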