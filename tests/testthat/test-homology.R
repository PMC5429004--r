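test_that("global aligner score equals the exhaustive DP optimum", {
  set.seed(103)
  for (k in 1:40) {
    la <- sample(5:50, 1); lb <- sample(5:50, 1)
    a <- random_dna_str(la)
    b <- if (k %% 3 == 0) {
      # related pair: mutate/delete from a
      s <- strsplit(a, "")[[1]]
      drop <- sample(la, min(la - 3, sample(0:8, 1)))
      if (length(drop)) s <- s[-drop]
      paste(s, collapse = "")
    } else random_dna_str(lb)
    got <- align_gene_pair(a, b)$score
    expect_equal(got, oracle_global_score(a, b), label = paste(a, b))
  }
})

test_that("alignment recovers identity and indel structure", {
  set.seed(107)
  a <- random_dna_str(200)
  al <- align_gene_pair(a, a)
  expect_equal(al$aligned_a, al$aligned_b)
  expect_false(grepl("-", al$aligned_a))
  # internal 30 bp deletion gives one 30-column gap block
  b <- paste0(substring(a, 1, 100), substring(a, 131, 200))
  al2 <- align_gene_pair(a, b)
  gaps <- gregexpr("-+", al2$aligned_b)[[1]]
  expect_equal(sum(attr(gaps, "match.length")), 30L)
  expect_error(align_gene_pair("", "ACGT"), "empty")
})

test_that("frame identity implements the one-mismatch-is-90% rule", {
  al <- list(aligned_a = "ACGTACGTAC", aligned_b = "ACGTACGTAC")
  expect_equal(frame_identity(al, 10L)$frame_identity, 100)
  al2 <- list(aligned_a = "ACGTACGTAC", aligned_b = "ACGAACGTAC")
  expect_equal(frame_identity(al2, 10L)$frame_identity, 90)
  # frame of gap-vs-base columns is absent and scores 0
  al3 <- list(aligned_a = "ACGTACGTAC----------",
              aligned_b = "ACGTACGTACGGGGGGGGGG")
  hm <- frame_identity(al3, 10L)
  expect_equal(hm$frame_identity, c(100, 0))
  expect_equal(hm$absent_mask, c(FALSE, TRUE))
  expect_equal(hm$mean_identity, 50)
})

test_that("width-weighted frame identity reconstructs overall identity", {
  set.seed(109)
  for (k in 1:10) {
    a <- random_dna_str(sample(80:300, 1))
    s <- strsplit(a, "")[[1]]
    at <- sample(length(s), round(0.1 * length(s)))
    s[at] <- vapply(s[at], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
    drop <- sample(length(s), 10)
    b <- paste(s[-drop], collapse = "")
    al <- align_gene_pair(a, b)
    hm <- frame_identity(al, 10L)
    cols <- strsplit(al$aligned_a, "")[[1]]
    colsb <- strsplit(al$aligned_b, "")[[1]]
    overall <- 100 * sum(cols == colsb & cols != "-") / length(cols)
    expect_equal(sum(hm$frame_identity * hm$frame_width) / sum(hm$frame_width),
                 overall, tolerance = 1e-9)
  }
})

test_that("frame map and mean are symmetric in the species pair", {
  set.seed(113)
  a <- random_dna_str(300)
  s <- strsplit(a, "")[[1]]
  b <- paste(s[-sample(300, 15)], collapse = "")
  h1 <- gene_pair_map(a, b)
  h2 <- gene_pair_map(b, a)
  expect_equal(h1$frame_identity, h2$frame_identity)
  expect_equal(h1$mean_identity, h2$mean_identity)
})

test_that("planted divergence is recovered by mean identity", {
  set.seed(127)
  for (r in c(0.02, 0.10)) {
    a <- random_dna_str(1000)
    s <- strsplit(a, "")[[1]]
    at <- sample(1000, round(r * 1000))
    s[at] <- vapply(s[at], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
    hm <- gene_pair_map(a, paste(s, collapse = ""))
    expect_lt(abs(hm$mean_identity - 100 * (1 - r)), 3)
  }
  # disjoint random sequences align poorly
  expect_lt(gene_pair_map(random_dna_str(300),
                          random_dna_str(300))$mean_identity, 60)
})

test_that("core gene sets intersect canonical names across species", {
  s1 <- species_gene_set("A", c(psbA = "ATGAAA", rbcL = "ATGCCC",
                                clpP = "ATGGGG"))
  s2 <- species_gene_set("B", c(PSBA = "ATGAAA", rbcL = "ATGCCA"))
  s3 <- species_gene_set("C", c(psba = "ATGAAT", clpP = "ATGGGG",
                                rbcl = "ATGCCC"))
  # clpP is missing from one of three species and drops out
  expect_equal(core_gene_set(list(s1, s2, s3)), c("psba", "rbcl"))
  expect_equal(core_gene_set(list(s1, s3)), c("clpp", "psba", "rbcl"))
  expect_error(core_gene_set(list(s1)), "two species")
  expect_error(species_gene_set("D", character()), "empty")
  # synonym table resolves locus-tag variants
  expect_equal(canonical_gene_name(c("rrn26.r01", "Nad4.CDS.3", "trnQ-UUG")),
               c("rrn26", "nad4", "trnq"))
})

test_that("multiway summaries use n(n-1)/2 pairwise comparisons", {
  set.seed(131)
  genes <- c(psbA = random_dna_str(120), cox3 = random_dna_str(150))
  mk <- function(lbl) {
    mut <- vapply(genes, function(g) {
      s <- strsplit(g, "")[[1]]
      at <- sample(length(s), 2)
      s[at] <- vapply(s[at], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
      paste(s, collapse = "")
    }, "")
    species_gene_set(lbl, mut)
  }
  sets11 <- lapply(sprintf("S%02d", 1:11), mk)
  sum11 <- multiway_summary(sets11)
  expect_equal(unique(sum11$n_pairs), 55L)
  sets6 <- sets11[1:6]
  expect_equal(unique(multiway_summary(sets6)$n_pairs), 15L)
  # identical gene sets give 100% for every gene
  twin <- list(species_gene_set("X", genes), species_gene_set("Y", genes))
  st <- multiway_summary(twin)
  expect_equal(st$mean_identity, c(100, 100))
  expect_equal(st$gene, c("cox3", "psba"))
  # a gene missing from one species is fatal when requested explicitly
  s_miss <- species_gene_set("Z", genes[1])
  expect_error(multiway_summary(list(twin[[1]], s_miss),
                                gene_names = c("psba", "cox3")), "absent")
})
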