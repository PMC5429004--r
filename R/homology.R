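# Inter-species organelle gene comparison: core gene sets across annotated
# references, deterministic global alignment of gene pairs, 10 bp frame
# identity maps, and multiway per-gene identity averages.

#' Canonicalize gene names
#'
#' Case-folds and resolves synonyms/locus-tag variants through an editable
#' table; unresolved names pass through (case-folded) verbatim.
#'
#' @param names Character vector of gene names.
#' @param synonyms Two-column data frame `alias`, `canonical`; defaults to
#'   the table shipped in `inst/extdata/gene_synonyms.tsv`.
#' @return Character vector of canonical names.
#' @export
canonical_gene_name <- function(names, synonyms = NULL) {
  if (is.null(synonyms)) {
    f <- system.file("extdata", "gene_synonyms.tsv", package = "fabatools",
                     mustWork = TRUE)
    synonyms <- read.delim(f, stringsAsFactors = FALSE)
  }
  low <- tolower(names)
  hit <- match(low, tolower(synonyms$alias))
  ifelse(!is.na(hit), tolower(synonyms$canonical[hit]), low)
}

#' Build a species gene set
#'
#' @param species_label Short species tag (e.g. `"V.faba"`).
#' @param genes Named [Biostrings::DNAStringSet] (or named character
#'   vector) of spliced, strand-resolved CDS sequences; names are
#'   canonicalized.
#' @param synonyms Optional synonym table for [canonical_gene_name()].
#' @return List of class `species_gene_set` with `species_label` and
#'   `genes` (a `DNAStringSet` with canonical names).
#' @export
species_gene_set <- function(species_label, genes, synonyms = NULL) {
  if (is.character(genes)) genes <- Biostrings::DNAStringSet(genes)
  if (is.null(names(genes)) || !length(genes))
    .stopf("species '%s': gene set is empty or unnamed", species_label)
  names(genes) <- canonical_gene_name(names(genes), synonyms)
  structure(list(species_label = species_label, genes = genes),
            class = "species_gene_set")
}

#' Core gene set across species
#'
#' Genes whose canonical name is annotated in every species' set.
#'
#' @param sets List of [species_gene_set()]s (at least 2).
#' @return Sorted character vector of canonical gene names.
#' @export
core_gene_set <- function(sets) {
  if (length(sets) < 2L) .stopf("need at least two species")
  name_lists <- lapply(sets, function(s) {
    if (!length(s$genes)) .stopf("species '%s' has an empty gene set",
                                 s$species_label)
    unique(names(s$genes))
  })
  sort(Reduce(intersect, name_lists))
}

#' Deterministic global alignment of a gene pair
#'
#' Needleman-Wunsch with end gaps penalized (match +1, mismatch -1, gap
#' open 4, gap extend 1 per gapped column), so regions absent from one
#' species' coding sequence appear as gap columns rather than being
#' clipped.
#'
#' @param seq_a,seq_b Sequences (`DNAString`, character).
#' @param match,mismatch,gap_opening,gap_extension Scoring (penalties are
#'   positive magnitudes).
#' @return List `aligned_a`, `aligned_b` (equal-length strings with `-`
#'   gaps), `score`.
#' @export
align_gene_pair <- function(seq_a, seq_b, match = 1, mismatch = -1,
                            gap_opening = 4, gap_extension = 1) {
  a <- Biostrings::DNAString(as.character(seq_a))
  b <- Biostrings::DNAString(as.character(seq_b))
  if (length(a) == 0L || length(b) == 0L) .stopf("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = .nuc_matrix(match, mismatch),
    gapOpening = gap_opening, gapExtension = gap_extension)
  list(aligned_a = as.character(Biostrings::pattern(pa)),
       aligned_b = as.character(Biostrings::subject(pa)),
       score = Biostrings::score(pa))
}

#' Frame identity map over a pairwise alignment
#'
#' Partitions alignment columns into consecutive non-overlapping frames of
#' `frame_size` (the last frame may be short; identity is over its actual
#' width). Per frame, identity = 100 x matching columns / frame width, so
#' a single polymorphism in a 10 bp frame gives 90%. Frames consisting
#' entirely of gap-versus-base columns are flagged absent and score 0; the
#' mean identity includes them.
#'
#' @param alignment List from [align_gene_pair()] (or any list with
#'   `aligned_a`, `aligned_b`).
#' @param frame_size Frame width in alignment columns (>= 1).
#' @param gene_name,species_pair Labels carried into the result.
#' @return List of class `homology_map`: `gene_name`, `species_pair`,
#'   `frame_identity` (percent per frame), `absent_mask`, `frame_width`,
#'   `mean_identity`, `n_frames`.
#' @export
frame_identity <- function(alignment, frame_size = 10L,
                           gene_name = NA_character_,
                           species_pair = c(NA_character_, NA_character_)) {
  if (frame_size < 1L) .stopf("frame_size must be at least 1")
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  stopifnot(length(a) == length(b))
  n <- length(a)
  frame <- (seq_len(n) - 1L) %/% frame_size + 1L
  is_match <- a == b & a != "-"
  gap_vs_base <- xor(a == "-", b == "-")
  fw <- as.integer(table(frame))
  fid <- 100 * as.numeric(tapply(is_match, frame, sum)) / fw
  absent <- as.logical(tapply(gap_vs_base, frame, all))
  fid[absent] <- 0
  structure(list(gene_name = gene_name, species_pair = species_pair,
                 frame_identity = fid, absent_mask = absent,
                 frame_width = fw, mean_identity = mean(fid),
                 n_frames = length(fid)),
            class = "homology_map")
}

#' Align a gene between two species and map its frame identity
#'
#' @inheritParams align_gene_pair
#' @inheritParams frame_identity
#' @return A `homology_map` (see [frame_identity()]).
#' @export
gene_pair_map <- function(seq_a, seq_b, frame_size = 10L,
                          gene_name = NA_character_,
                          species_pair = c(NA_character_, NA_character_)) {
  frame_identity(align_gene_pair(seq_a, seq_b), frame_size,
                 gene_name, species_pair)
}

#' Multiway per-gene identity summary
#'
#' For each gene, aligns it between every pair of species (n species give
#' n(n-1)/2 pairwise comparisons) and averages the pairwise mean
#' identities.
#'
#' @param sets List of [species_gene_set()]s.
#' @param gene_names Genes to summarize; default the [core_gene_set()].
#'   A gene absent from any species is fatal.
#' @param frame_size Passed to [frame_identity()].
#' @return Data frame `gene`, `mean_identity`, `n_pairs`, sorted by gene.
#' @export
multiway_summary <- function(sets, gene_names = core_gene_set(sets),
                             frame_size = 10L) {
  n <- length(sets)
  pairs <- utils::combn(n, 2L)
  rows <- lapply(sort(gene_names), function(g) {
    vals <- apply(pairs, 2L, function(p) {
      ga <- sets[[p[1]]]$genes; gb <- sets[[p[2]]]$genes
      if (!g %in% names(ga) || !g %in% names(gb))
        .stopf("gene '%s' absent from species '%s'", g,
               if (!g %in% names(ga)) sets[[p[1]]]$species_label
               else sets[[p[2]]]$species_label)
      gene_pair_map(ga[[g]], gb[[g]], frame_size, g,
                    c(sets[[p[1]]]$species_label,
                      sets[[p[2]]]$species_label))$mean_identity
    })
    data.frame(gene = g, mean_identity = mean(vals), n_pairs = ncol(pairs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
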