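# columns ordered forward-first for closed-form readability
design_ff <- data.frame(
  array_id = paste0("a", 1:6),
  sample_id = rep(c("S1", "S2", "S3"), 2),
  orientation = rep(c("forward", "reverse"), each = 3),
  stringsAsFactors = FALSE)

m_row <- function(vals) matrix(vals, 1, 6, dimnames = list("p1", paste0("a", 1:6)))

test_that("balanced OLS recovers the closed-form alpha and beta", {
  fit <- fit_dye_model(m_row(c(1, 1, 1, 0, 0, 0)), design_ff)
  expect_equal(fit$alpha, 0.5)
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$df, 4)

  flat <- fit_dye_model(m_row(rep(0.37, 6)), design_ff)
  expect_equal(flat$alpha, 0.37)
  expect_equal(flat$beta, 0, tolerance = 1e-12)
})

test_that("correction removes the dye component and refits to beta = 0", {
  M <- m_row(c(1, 1, 1, 0, 0, 0))
  fit <- fit_dye_model(M, design_ff)
  Mc <- correct_dye_bias(M, fit, design_ff)
  expect_equal(as.vector(Mc), rep(0.5, 6))
  refit <- fit_dye_model(Mc, design_ff)
  expect_lt(abs(refit$beta), 1e-12)

  nobias <- m_row(c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2))
  fit0 <- fit_dye_model(nobias, design_ff)
  expect_equal(as.vector(correct_dye_bias(nobias, fit0, design_ff)),
               rep(0.2, 6))
})

test_that("coefficients agree with an independent linear-model fit", {
  skip_if_not_installed("limma")
  set.seed(21)
  M <- matrix(rnorm(500 * 6), 500, 6,
              dimnames = list(sprintf("p%03d", 1:500), paste0("a", 1:6)))
  ours <- fit_dye_model(M, design_ff)
  X <- cbind(alpha = 1, beta = ifelse(design_ff$orientation == "forward", 1, -1))
  lf <- limma::lmFit(M, design = X)
  expect_equal(ours$alpha, unname(lf$coefficients[, "alpha"]), tolerance = 1e-10)
  expect_equal(ours$beta, unname(lf$coefficients[, "beta"]), tolerance = 1e-10)
})

test_that("corrected M is invariant to relabeling the dye codes", {
  set.seed(22)
  M <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(sprintf("p%03d", 1:200), paste0("a", 1:6)))
  d1 <- design_ff
  d2 <- design_ff
  d2$orientation <- ifelse(d1$orientation == "forward", "reverse", "forward")
  f1 <- fit_dye_model(M, d1)
  f2 <- fit_dye_model(M, d2)
  expect_equal(f2$beta, -f1$beta)
  expect_equal(correct_dye_bias(M, f1, d1), correct_dye_bias(M, f2, d2),
               ignore_attr = TRUE)
})

test_that("planted bias is recovered within the design's noise floor", {
  fx <- fix_experiment()
  spots <- lapply(fx$scans, preprocess_scan)
  M <- build_m_matrix(spots, fx$design)
  fits <- fit_dye_model(M, fx$design)
  err <- abs(fits$beta - fx$bias)
  expect_lt(mean(err, na.rm = TRUE), 0.15 / sqrt(3))
})

test_that("spots with one dye level are skipped; partial spots still fit", {
  M <- rbind(m_row(c(1, 1, 1, 0, 0, 0)), m_row(c(1, 1, 1, 0, 0, 0)))
  rownames(M) <- c("p1", "p2")
  M["p1", 4:6] <- NA                       # forward-only
  M["p2", c(1, 4)] <- NA                   # 4 arrays, both levels
  fits <- fit_dye_model(M, design_ff)
  expect_true(is.na(fits$beta[1]))
  expect_equal(attr(fits, "skipped"), "p1")
  expect_equal(fits$alpha[2], 0.5)
  expect_equal(fits$beta[2], 0.5)
  # unfit spots pass through correction unchanged
  Mc <- correct_dye_bias(M, fits, design_ff)
  expect_equal(Mc["p1", ], M["p1", ])
})

test_that("null dye-bias t-test is calibrated at the nominal level", {
  set.seed(11)
  M <- matrix(rnorm(2000 * 6), 2000, 6,
              dimnames = list(sprintf("p%04d", 1:2000), paste0("a", 1:6)))
  fits <- fit_dye_model(M, design_ff)
  frac <- dye_bias_fraction(fits, 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("identical arrays merge first in the clustering diagnostic", {
  set.seed(23)
  M <- matrix(rnorm(300 * 6), 300, 6,
              dimnames = list(sprintf("p%03d", 1:300), paste0("a", 1:6)))
  M[, 2] <- M[, 1]
  cl <- cluster_arrays(M)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))
  expect_equal(cl$hclust$height[1], 0)
  expect_match(cl$newick, "^\\(")
  expect_error(cluster_arrays(M[, 1, drop = FALSE]), "at least 2")
})

test_that("merge_samples averages dye-swap pairs and replicate probes", {
  lay <- data.frame(probe_id = c("p1", "p2", "p3"),
                    chrom = "chr1", start = c(100, 100, 500),
                    end = c(160, 160, 560),
                    grid_row = 1:3, grid_col = 1L,
                    locus_id = c("L1", "L1", "L2"),
                    stringsAsFactors = FALSE)
  M <- matrix(c(0.4, 0.6, 0.0, 0.2, 0.1, 0.3), 3, 2, byrow = FALSE,
              dimnames = list(lay$probe_id, c("S1_forward", "S1_reverse")))
  des <- data.frame(array_id = c("S1_forward", "S1_reverse"),
                    sample_id = "S1",
                    orientation = c("forward", "reverse"),
                    stringsAsFactors = FALSE)
  pmv <- merge_samples(M, des, lay)
  # L1: mean over pair then over replicates: mean(c(mean(.4,.2), mean(.6,.1)))
  expect_equal(pmv$S1[pmv$locus_id == "L1"], mean(c(0.3, 0.35)))
  expect_equal(pmv$S1[pmv$locus_id == "L2"], mean(c(0.0, 0.3)))
  expect_false(is.unsorted(pmv$start))

  unpaired <- des[1, ]
  expect_error(merge_samples(M[, 1, drop = FALSE], unpaired, lay),
               "dye-swap pair")
})

test_that("merged per-sample M equals the planted truth on clean data", {
  g <- fix_genome()
  tr <- plant_cnvs(g, n_per_sample = 4, length_range = c(1e5, 3e5), seed = 31)
  lay <- tile_probes(g, seed = 2)
  ex <- simulate_dyeswap_experiment(lay, tr, bias = 0, noise_sd = 0, seed = 6)
  spots <- lapply(ex$scans, preprocess_scan)
  M <- build_m_matrix(spots, ex$design)
  fits <- fit_dye_model(M, ex$design)
  pmv <- merge_samples(correct_dye_bias(M, fits, ex$design), ex$design, lay)
  for (s in unique(tr$sample_id)) {
    truth_m <- log2(swapCGH:::probe_copy_states(lay, tr, s) / 2)
    ord <- match(pmv$locus_id, lay$locus_id)
    expect_equal(pmv[[s]], truth_m[ord], tolerance = 1e-9)
  }
})
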