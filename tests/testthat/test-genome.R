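test_that("make_genome handles the empty case and rejects bad configs", {
  g <- make_genome(genome_config(chrom_lengths = c(chr1 = 1e7),
                                 gene_fraction = 0), seed = 5)
  expect_equal(nrow(g$chromosomes), 1L)
  expect_equal(nrow(g$features$genes), 0L)

  expect_error(make_genome(genome_config(chrom_lengths = c(chr1 = -5))),
               "positive")
  expect_error(make_genome(genome_config(gene_fraction = 1.2)), "gene_fraction")
  expect_error(make_genome(genome_config(chrom_lengths = numeric(0))),
               "at least one")
})

test_that("make_genome is deterministic and respects feature invariants", {
  cfg <- genome_config(chrom_lengths = setNames(rep(4e6, 2), c("chrA", "chrB")))
  g1 <- make_genome(cfg, seed = 1)
  g2 <- make_genome(cfg, seed = 1)
  expect_identical(g1, g2)

  for (nm in names(g1$features)) {
    f <- g1$features[[nm]]
    if (nrow(f) == 0) next
    expect_true(all(f$start >= 0))
    expect_true(all(f$start < f$end))
    expect_true(all(f$end <= chrom_length(g1, f$chrom)))
    expect_false(anyDuplicated(f$id) > 0)
  }
})

test_that("merged gene coverage tracks the configured genome fraction", {
  # summation oracle: sort and walk the intervals, independent of IRanges
  g <- make_genome(genome_config(chrom_lengths = setNames(rep(6e6, 3),
                                                          paste0("chr", 1:3)),
                                 gene_fraction = 0.21), seed = 7)
  genes <- g$features$genes
  covered <- 0
  for (ch in unique(genes$chrom)) {
    d <- genes[genes$chrom == ch, ]
    d <- d[order(d$start), ]
    hi <- -Inf
    for (i in seq_len(nrow(d))) {
      covered <- covered + max(0, d$end[i] - max(d$start[i], hi))
      hi <- max(hi, d$end[i])
    }
  }
  frac <- covered / sum(g$chromosomes$length)
  expect_gt(frac, 0.18)
  expect_lt(frac, 0.24)
  # the package's own merged accounting agrees with the oracle
  expect_equal(swapCGH:::merged_length_df(genes), covered)
})

test_that("plant_cnvs places shared and private CNVs as configured", {
  g <- fix_genome()
  expect_equal(nrow(plant_cnvs(g, n_per_sample = 0, seed = 1)), 0L)

  tr1 <- plant_cnvs(g, n_per_sample = 5, shared_fraction = 1, seed = 2)
  sets <- split(tr1[, c("chrom", "start", "end", "copy_state")], tr1$sample_id)
  for (s in sets) expect_equal(unname(as.matrix(s)), unname(as.matrix(sets[[1]])))

  # counting oracle: CNV ids present in every sample
  big <- make_genome(genome_config(
    chrom_lengths = setNames(rep(3e7, 4), paste0("chr", 1:4))), seed = 9)
  tr <- plant_cnvs(big, n_per_sample = 100, shared_fraction = 0.7,
                   length_range = c(2e4, 1e5), seed = 3)
  per_id <- table(tr$cnv_id)
  n_samples <- length(unique(tr$sample_id))
  expect_equal(sum(per_id == n_samples), 70)
  expect_equal(sum(tr$sample_id == "GK1"), 100)

  # within-sample disjointness and bounds
  for (s in unique(tr$sample_id)) {
    d <- tr[tr$sample_id == s, ]
    expect_true(all(d$end <= chrom_length(big, d$chrom)))
    for (ch in unique(d$chrom)) {
      dd <- d[d$chrom == ch, ]
      dd <- dd[order(dd$start), ]
      if (nrow(dd) > 1) expect_true(all(dd$start[-1] >= dd$end[-nrow(dd)]))
    }
  }
  expect_true(all(c(1L, 3L) %in% tr$copy_state))
})

test_that("plant_cnvs errors when the genome cannot host the request", {
  tiny <- make_genome(genome_config(chrom_lengths = c(chr1 = 2e5),
                                    gene_fraction = 0), seed = 1)
  expect_error(plant_cnvs(tiny, n_per_sample = 50,
                          length_range = c(5e4, 1e5), seed = 1,
                          max_tries = 50),
               "could not place")
})

test_that("tile_probes spacing, counts and grid invariants hold", {
  g1 <- make_genome(genome_config(chrom_lengths = c(chr1 = 1e6),
                                  gene_fraction = 0), seed = 1)
  lay <- tile_probes(g1, target_spacing = 1e5, probe_length = 60, seed = 1)
  expect_true(abs(nrow(lay) - 10) <= 1)

  g10 <- make_genome(genome_config(chrom_lengths = c(chr1 = 1e7),
                                   gene_fraction = 0), seed = 1)
  lay10 <- tile_probes(g10, seed = 3)
  expect_gte(median_spacing(lay10), 7100)
  expect_lte(median_spacing(lay10), 8700)

  short <- make_genome(genome_config(chrom_lengths = c(chr1 = 3000),
                                     gene_fraction = 0), seed = 1)
  lay_s <- tile_probes(short, target_spacing = 7900, seed = 1)
  expect_gte(nrow(lay_s), 1L)

  expect_error(tile_probes(g1, target_spacing = 50, probe_length = 60),
               "exceed")

  expect_false(anyDuplicated(lay10[, c("grid_row", "grid_col")]) > 0)
  expect_false(is.unsorted(lay10$start))
  expect_true(all(lay10$end <= 1e7))
})

test_that("replicate probes share a locus but occupy distinct spots", {
  g <- make_genome(genome_config(chrom_lengths = c(chr1 = 2e6),
                                 gene_fraction = 0), seed = 1)
  lay <- tile_probes(g, replicate_fraction = 0.1, seed = 5)
  dup <- lay$locus_id[duplicated(lay$locus_id)]
  expect_gt(length(dup), 0)
  expect_false(anyDuplicated(lay$probe_id) > 0)
  one <- lay[lay$locus_id == dup[1], ]
  expect_equal(length(unique(one$start)), 1L)
  expect_false(anyDuplicated(one[, c("grid_row", "grid_col")]) > 0)
})
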