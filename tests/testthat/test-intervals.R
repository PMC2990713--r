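iv <- function(start, end, chrom = "chr1")
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)

test_that("merge_intervals collapses overlaps and preserves disjoint input", {
  out <- merge_intervals(iv(c(0, 50), c(100, 150)))
  expect_equal(out, iv(0, 150), ignore_attr = TRUE)

  disj <- iv(c(0, 200), c(100, 300))
  expect_equal(merge_intervals(disj), disj, ignore_attr = TRUE)

  expect_error(merge_intervals(iv(100, 100)), "start < end")
})

test_that("merged length matches a per-bp mask on random intervals", {
  set.seed(23)
  chrom_len <- 50000
  st <- sample(chrom_len - 200, 1000, replace = TRUE)
  df <- iv(st, st + sample(200, 1000, replace = TRUE))
  merged <- merge_intervals(df)
  expect_equal(sum(merged$end - merged$start), mask_union_length(df, chrom_len))
  # disjointness after merging
  expect_true(all(merged$start[-1] > merged$end[-nrow(merged)] |
                    merged$start[-1] >= merged$end[-nrow(merged)]))
})

test_that("overlap_length is the symmetric intersection length", {
  expect_equal(overlap_length(iv(0, 100), iv(50, 150)), 50)
  expect_equal(overlap_length(iv(0, 100), iv(200, 300)), 0)
  set.seed(29)
  chrom_len <- 20000
  mk <- function(n) {
    st <- sample(chrom_len - 300, n, replace = TRUE)
    iv(st, st + sample(300, n, replace = TRUE))
  }
  a <- mk(200); b <- mk(150)
  expect_equal(overlap_length(a, b), mask_overlap_length(a, b, chrom_len))
  expect_equal(overlap_length(a, b), overlap_length(b, a))
  expect_lte(overlap_length(a, b),
             min(swapCGH:::merged_length_df(a), swapCGH:::merged_length_df(b)))
})

test_that("coverage_table partitions CNVR length into gene and intergenic", {
  genome <- list(chromosomes = data.frame(chrom = "chr1", length = 1e6),
                 features = list())
  class(genome) <- "GenomeModel"
  cnvrs <- data.frame(chrom = "chr1", start = c(0, 500000),
                      end = c(100000, 600000),
                      status = c("gain", "loss"), stringsAsFactors = FALSE)
  genes <- iv(c(50000, 550000), c(150000, 560000))
  tab <- coverage_table(cnvrs, genes, genome)
  gain <- tab[tab$region == "gain", ]
  expect_equal(gain$length_bp, 1e5)
  expect_equal(gain$gene_bp, 5e4)
  expect_equal(gain$gene_pct, 50)
  expect_equal(gain$intergenic_bp, 5e4)
  tot <- tab[tab$region == "total", ]
  expect_equal(tot$gene_bp, 6e4)
  expect_equal(tot$gene_pct + tot$intergenic_pct, 100)

  # CNVRs entirely inside genes: intergenic 0, gene 100%
  tab2 <- coverage_table(cnvrs[1, ], iv(0, 2e5), genome)
  expect_equal(tab2$gene_pct[tab2$region == "gain"], 100)
  expect_equal(tab2$intergenic_bp[tab2$region == "gain"], 0)
})

test_that("genes_overlapping applies the 1-bp half-open rule", {
  cnvrs <- data.frame(chrom = "chr1", start = c(199, 200), end = c(300, 300),
                      status = c("gain", "loss"), stringsAsFactors = FALSE)
  genes <- data.frame(chrom = "chr1", start = 100, end = 200, id = "g1",
                      stringsAsFactors = FALSE)
  got <- genes_overlapping(cnvrs, genes)
  expect_equal(got$gain, "g1")     # overlaps [199,200)
  expect_equal(got$loss, character(0))  # book-ended at 200: no overlap

  # planted genes inside CNVs are recovered exactly
  set.seed(3)
  g <- fix_genome()
  tr <- plant_cnvs(g, n_per_sample = 8, length_range = c(1e5, 2e5), seed = 17)
  cn <- unique(tr[, c("chrom", "start", "end", "copy_state")])
  cn$status <- ifelse(cn$copy_state == 3, "gain", "loss")
  genes <- g$features$genes
  expected <- genes_overlapping(cn, genes)
  manual <- list(gain = character(0), loss = character(0))
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(cn)))
    if (genes$chrom[i] == cn$chrom[j] && genes$start[i] < cn$end[j] &&
        cn$start[j] < genes$end[i])
      manual[[cn$status[j]]] <- c(manual[[cn$status[j]]], genes$id[i])
  expect_equal(expected$gain, sort(unique(manual$gain)))
  expect_equal(expected$loss, sort(unique(manual$loss)))
})

test_that("random placement covers features proportionally to coverage", {
  # doubling the feature fraction roughly doubles the expected null overlap
  genome <- list(chromosomes = data.frame(chrom = "chr1", length = 1e6),
                 features = list())
  class(genome) <- "GenomeModel"
  q <- iv(seq(0, 29) * 2e4, seq(0, 29) * 2e4 + 5e3)
  f1 <- iv(0, 1e5)
  f2 <- iv(0, 2e5)
  r1 <- random_interval_test(q, f1, genome, n_rounds = 1000, seed = 31)
  r2 <- random_interval_test(q, f2, genome, n_rounds = 1000, seed = 32)
  expect_equal(r2$expected / r1$expected, 2, tolerance = 0.05)
})

test_that("degenerate feature sets give the forced depletion p of 1", {
  genome <- list(chromosomes = data.frame(chrom = "chr1", length = 1e5),
                 features = list())
  class(genome) <- "GenomeModel"
  q <- iv(c(1000, 50000), c(3000, 54000))
  full <- iv(0, 1e5)
  res <- random_interval_test(q, full, genome, n_rounds = 100, seed = 2)
  expect_true(all(res$null_overlaps == res$observed))
  expect_equal(res$observed, 6000)
  expect_equal(res$p_value, 1)
  expect_equal(res$expected, 6000)
})

test_that("observed overlap is consistent and p is never exactly zero", {
  genome <- list(chromosomes = data.frame(chrom = "chr1", length = 1e6),
                 features = list())
  class(genome) <- "GenomeModel"
  st <- seq(0, 19) * 4e4
  q <- iv(st, st + 1e4)
  feats <- iv(c(0, 5e5), c(1e5, 6e5))
  res <- random_interval_test(q, feats, genome, n_rounds = 200, seed = 7)
  expect_equal(res$observed, overlap_length(merge_intervals(q), feats))
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_equal(res$expected, mean(res$null_overlaps))
  # deterministic for fixed seed
  res2 <- random_interval_test(q, feats, genome, n_rounds = 200, seed = 7)
  expect_identical(res$null_overlaps, res2$null_overlaps)
  # an interval longer than every chromosome cannot be placed
  expect_error(random_interval_test(iv(0, 2e6), feats, genome), "longer")
})
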