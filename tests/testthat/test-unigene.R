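test_that("peaks are maximal covered runs, optionally gap-merged", {
  expect_equal(nrow(find_peaks(integer(100))), 0L)
  one <- find_peaks(rep(20L, 500))
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(0L, 500L))
  expect_equal(one$mean_depth, 20)
  prof <- integer(1000)
  prof[1:100] <- 10L; prof[201:300] <- 10L
  two <- find_peaks(prof)
  expect_equal(two$start, c(0L, 200L))
  expect_equal(two$end, c(100L, 300L))
  # a 1 bp gap merges when max_gap allows it
  prof2 <- c(rep(1L, 10), 0L, rep(1L, 10))
  expect_equal(nrow(find_peaks(prof2, max_gap = 0L)), 2L)
  expect_equal(nrow(find_peaks(prof2, max_gap = 1L)), 1L)
  # peak union equals the covered set at max_gap 0 (property, random profiles)
  set.seed(11)
  for (rep in 1:20) {
    p <- as.integer(stats::rpois(200, 0.7))
    pk <- find_peaks(p)
    cov_set <- which(p >= 1L) - 1L
    in_peaks <- unlist(mapply(function(s, e) seq.int(s, e - 1L),
                              pk$start, pk$end, SIMPLIFY = FALSE))
    expect_equal(sort(as.integer(in_peaks)), cov_set)
  }
})

test_that("classification applies the stated bin boundaries", {
  full <- rep(50L, 200)
  cls <- classify_unigene(full, "u")
  expect_equal(cls[, c("peak_bin", "breadth_bin", "depth_bin")],
               data.frame(peak_bin = "1", breadth_bin = ">95%",
                          depth_bin = "10-100"))
  zero <- classify_unigene(integer(100), "u")
  expect_equal(zero$n_peaks, 0L)
  expect_equal(zero$breadth_pct, 0)
  expect_equal(zero$depth_bin, "<10")
  # two runs covering 60%, mean depth ~7 -> (2-3, 50-95%, <10)
  prof <- integer(1000)
  prof[1:300] <- 12L; prof[501:800] <- 11L
  cls2 <- classify_unigene(prof, "u")
  expect_equal(cls2$peak_bin, "2-3")
  expect_equal(cls2$breadth_bin, "50-95%")
  expect_equal(cls2$depth_bin, "<10")
  # boundary cases: breadth exactly 95 and 50 -> middle bin; depth 10, 100
  b95 <- c(rep(1L, 95), integer(5))
  expect_equal(classify_unigene(b95)$breadth_bin, "50-95%")
  b50 <- c(rep(1L, 50), integer(50))
  expect_equal(classify_unigene(b50)$breadth_bin, "50-95%")
  expect_equal(classify_unigene(rep(10L, 10))$depth_bin, "10-100")
  expect_equal(classify_unigene(rep(100L, 10))$depth_bin, "10-100")
  expect_equal(classify_unigene(rep(101L, 10))$depth_bin, ">100")
  expect_error(classify_unigene(integer(0)), "zero-length")
})

test_that("every (peaks, breadth, depth) triple maps to exactly one cell", {
  set.seed(13)
  cases <- data.frame(n_peaks = sample(0:15, 50, TRUE),
                      breadth = stats::runif(50, 0, 100),
                      depth = stats::runif(50, 0, 200))
  for (i in seq_len(nrow(cases))) {
    pb <- fabatools:::.peak_bin(cases$n_peaks[i])
    bb <- fabatools:::.breadth_bin(cases$breadth[i])
    db <- fabatools:::.depth_bin(cases$depth[i])
    expect_length(pb, 1L); expect_length(bb, 1L); expect_length(db, 1L)
    expect_true(pb %in% fabatools:::PEAK_BINS)
    expect_true(bb %in% fabatools:::BREADTH_BINS)
    expect_true(db %in% fabatools:::DEPTH_BINS)
  }
})

test_that("tabulation is exhaustive and matches designated classes exactly", {
  empty <- tabulate_classes(data.frame(peak_bin = character(),
                                       breadth_bin = character(),
                                       depth_bin = character()))
  expect_equal(sum(empty$total), 0L)
  one <- tabulate_classes(data.frame(peak_bin = "1", breadth_bin = ">95%",
                                     depth_bin = "10-100"))
  expect_equal(sum(one$total), 1L)
  expect_equal(one$`10-100`[one$peak_bin == "1" & one$breadth_bin == ">95%"], 1L)

  cfg <- sim_config(seed = 47, n_unigenes = 36)
  tx <- simulate_transcriptome(cfg)
  ga <- simulate_genomic_alignments(cfg, tx$unigenes)
  sam <- tempfile(fileext = ".sam")
  write_alignments(ga$alignments, sam)
  cls <- classify_unigenes(read_alignments(sam))
  tab <- tabulate_classes(cls)
  expect_equal(sum(tab$total), 36L)
  truth <- ga$truth_classes
  truth_cls <- data.frame(
    peak_bin = vapply(truth$n_peaks, fabatools:::.peak_bin, ""),
    breadth_bin = vapply(truth$breadth * 100, fabatools:::.breadth_bin, ""),
    depth_bin = vapply(truth$depth, fabatools:::.depth_bin, ""))
  expect_equal(tab, tabulate_classes(truth_cls))
})
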