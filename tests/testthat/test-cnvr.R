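one_chrom_genome <- function(len = 1e5) {
  g <- list(chromosomes = data.frame(chrom = "chr1", length = len,
                                     stringsAsFactors = FALSE),
            features = list())
  class(g) <- "GenomeModel"
  g
}

smoothed_df <- function(starts, m, probe_len = 60) {
  data.frame(chrom = "chr1", start = starts, end = starts + probe_len,
             smoothed = m, stringsAsFactors = FALSE)
}

test_that("the consecutive-probe rule delineates cores and extends flanks", {
  g <- one_chrom_genome(1e5)
  d <- smoothed_df(c(10000, 18000, 26000), rep(0.7, 3))
  out <- call_cores(d, "S1", g)
  expect_equal(nrow(out), 1L)
  expect_equal(out$status, "gain")
  expect_equal(out$core_start, 10000)
  expect_equal(out$core_end, 26060)
  expect_equal(out$start, 5000)
  expect_equal(out$end, 31060)
  expect_equal(out$n_probes, 3L)

  # two probes above threshold are not enough
  d2 <- smoothed_df(c(10000, 18000, 26000, 34000), c(0, 0.9, 0.9, 0))
  expect_equal(nrow(call_cores(d2, "S1", g)), 0L)

  # four consecutive losses make one loss CNVR
  d3 <- smoothed_df(seq(10000, by = 8000, length.out = 4), rep(-0.6, 4))
  out3 <- call_cores(d3, "S1", g)
  expect_equal(out3$status, "loss")
  expect_equal(out3$n_probes, 4L)
})

test_that("flank extension clamps to chromosome bounds", {
  g <- one_chrom_genome(30000)
  d <- smoothed_df(c(1000, 9000, 17000), rep(0.8, 3))
  out <- call_cores(d, "S1", g)
  expect_equal(out$start, 0)
  expect_equal(out$end, 22060)  # core_end 17060 + 5000, within the chromosome
  g2 <- one_chrom_genome(20000)
  out2 <- call_cores(d, "S1", g2)
  expect_equal(out2$end, 20000)
})

test_that("unsorted probes are rejected", {
  g <- one_chrom_genome(1e5)
  d <- smoothed_df(c(20000, 10000, 30000), rep(0.7, 3))
  expect_error(call_cores(d, "S1", g), "sorted")
})

test_that("runs broken by sub-threshold probes or gap rule do not merge", {
  g <- one_chrom_genome(2e5)
  m <- c(0.7, 0.7, 0.7, 0.2, 0.7, 0.7, 0.7)
  d <- smoothed_df(seq(10000, by = 8000, length.out = 7), m)
  out <- call_cores(d, "S1", g)
  # the sub-threshold probe breaks the run; the extensions stay > 5 Kb apart
  expect_equal(nrow(out), 2L)
  expect_equal(out$n_probes, c(3L, 3L))
  # with a max-gap rule the far-apart probes cannot form a run
  d2 <- smoothed_df(c(10000, 18000, 80000), rep(0.7, 3))
  expect_equal(nrow(call_cores(d2, "S1", g, max_gap = 20000)), 0L)
  expect_equal(nrow(call_cores(d2, "S1", g)), 1L)
})

test_that("every probe in a called core exceeds the threshold properly", {
  set.seed(33)
  m <- rnorm(200, 0, 0.3)
  m[50:60] <- 0.9
  m[120:130] <- -0.9
  d <- smoothed_df(seq(5000, by = 8000, length.out = 200), m)
  g <- one_chrom_genome(5000 + 200 * 8000)
  out <- call_cores(d, "S1", g)
  for (i in seq_len(nrow(out))) {
    inside <- d$start >= out$core_start[i] & d$end <= out$core_end[i]
    if (out$status[i] == "gain") expect_true(all(d$smoothed[inside] > 0.5))
    else expect_true(all(d$smoothed[inside] < -0.5))
  }
})

test_that("cross-sample union merging is status-stratified", {
  base <- data.frame(chrom = "chr1", start = 1e5, end = 2e5, status = "gain",
                     core_start = 105000, core_end = 195000, n_probes = 5L,
                     mean_smoothed_M = 0.8, sample_id = "s1",
                     stringsAsFactors = FALSE)
  s2 <- base; s2$start <- 1.5e5; s2$end <- 3e5; s2$sample_id <- "s2"
  merged <- merge_to_nonredundant(list(base, s2))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 1e5)
  expect_equal(merged$end, 3e5)
  expect_equal(merged$supporting_samples, "s1,s2")
  expect_equal(merged$name, "cnv.gain.1")

  # identical sets: idempotent union with support = 3
  trip <- lapply(c("s1", "s2", "s3"), function(s) { b <- base; b$sample_id <- s; b })
  m3 <- merge_to_nonredundant(trip)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$n_samples, 3L)
  expect_equal(m3$start, base$start)
  expect_equal(m3$end, base$end)

  # a loss never merges with an overlapping gain
  l2 <- s2; l2$status <- "loss"
  ml <- merge_to_nonredundant(list(base, l2))
  expect_equal(nrow(ml), 2L)
  expect_setequal(ml$status, c("gain", "loss"))
  expect_equal(ml$start[ml$status == "gain"], 1e5)
  expect_equal(ml$end[ml$status == "gain"], 2e5)

  # book-ended regions merge
  b2 <- base; b2$start <- 2e5; b2$end <- 2.5e5; b2$sample_id <- "s2"
  mb <- merge_to_nonredundant(list(base, b2))
  expect_equal(nrow(mb), 1L)
  expect_equal(mb$end, 2.5e5)
})

test_that("adding a sample never shrinks the non-redundant coverage", {
  set.seed(35)
  mk <- function(s, n) {
    st <- sort(sample(seq(0, 9e5, by = 1e4), n))
    data.frame(chrom = "chr1", start = st, end = st + 5e4,
               status = sample(c("gain", "loss"), n, TRUE),
               core_start = st, core_end = st + 5e4, n_probes = 3L,
               mean_smoothed_M = 0.7, sample_id = s, stringsAsFactors = FALSE)
  }
  sets <- list(mk("s1", 5), mk("s2", 5), mk("s3", 5))
  cov2 <- swapCGH:::merged_length_df(merge_to_nonredundant(sets[1:2])[, c("chrom", "start", "end")])
  cov3 <- swapCGH:::merged_length_df(merge_to_nonredundant(sets)[, c("chrom", "start", "end")])
  expect_gte(cov3, cov2)
  single <- max(vapply(sets, function(s)
    swapCGH:::merged_length_df(s[, c("chrom", "start", "end")]), numeric(1)))
  expect_gte(cov3, single)
})
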