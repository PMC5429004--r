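# Independent oracles used across the suite: deliberately naive
# implementations (hand parsing, per-base loops, exhaustive DP) kept free
# of the package's own code paths.

# Hand-parse a CIGAR string into (op, len) pairs.
oracle_parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  parts <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  data.frame(op = sub("^\\d+", "", parts),
             len = as.integer(sub("[A-Z=]$", "", parts)),
             stringsAsFactors = FALSE)
}

oracle_query_len <- function(cigar) {
  ops <- oracle_parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

oracle_ref_len <- function(cigar) {
  ops <- oracle_parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

# Brute-force per-base coverage from (0-based start, cigar) records.
oracle_coverage <- function(starts, cigars, ref_len) {
  depth <- integer(ref_len)
  for (i in seq_along(starts)) {
    w <- oracle_ref_len(cigars[i])
    if (w > 0)
      depth[(starts[i] + 1):(starts[i] + w)] <-
        depth[(starts[i] + 1):(starts[i] + w)] + 1L
  }
  depth
}

# Brute-force base tally at one 0-based position from alignment records
# (plain xM records only, as the organelle simulator emits).
oracle_base_tally <- function(aln, pos0) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  for (i in seq_len(nrow(aln))) {
    w <- oracle_ref_len(aln$cigar[i])
    s <- aln$ref_start[i]
    if (s <= pos0 && pos0 < s + w) {
      b <- substring(aln$seq[i], pos0 - s + 1L, pos0 - s + 1L)
      counts[b] <- counts[b] + 1L
    }
  }
  counts
}

# Exhaustive affine-gap global alignment score (Gotoh), end gaps
# penalized. A gap of length L costs open + L * ext, matching the
# package's stated scoring convention.
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                open = 4, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (b consumed)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in seq_len(m) + 1) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_dna_str <- function(len)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

# Write alignment records + header to a temporary SAM and read them back.
roundtrip_sam <- function(aln) {
  f <- tempfile(fileext = ".sam")
  fabatools::write_alignments(aln, f)
  fabatools::read_alignments(f)
}
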