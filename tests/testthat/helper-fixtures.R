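# Shared small fixtures, built once per test run.

fix_genome <- function() {
  make_genome(genome_config(
    chrom_lengths = setNames(rep(6e6, 3), paste0("chr", 1:3))), seed = 7)
}

# small dye-swap experiment with planted CNVs and strong spot-specific bias
fix_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- fix_genome()
    tr <- plant_cnvs(g, n_per_sample = 6, length_range = c(1e5, 3e5),
                     shared_fraction = 0.5, seed = 3)
    lay <- tile_probes(g, seed = 2)
    bias <- make_dye_bias(lay, sd = 0.05, frac_large = 0.25,
                          large_mean = 0.4, seed = 4)
    ex <- simulate_dyeswap_experiment(lay, tr, bias = bias,
                                      noise_sd = 0.15, seed = 5)
    cache <<- list(genome = g, truth = tr, layout = lay, bias = bias,
                   scans = ex$scans, design = ex$design)
    cache
  }
})

# hand-built scan for arithmetic checks
manual_scan <- function(red_fg, red_bg, green_fg, green_bg,
                        orientation = "forward") {
  n <- length(red_fg)
  side <- ceiling(sqrt(n))
  scan <- data.frame(probe_id = sprintf("p%03d", seq_len(n)),
                     grid_row = ((seq_len(n) - 1) %/% side) + 1L,
                     grid_col = ((seq_len(n) - 1) %% side) + 1L,
                     ch_red_fg = red_fg, ch_red_bg = red_bg,
                     ch_green_fg = green_fg, ch_green_bg = green_bg,
                     qc_flag = "pass", stringsAsFactors = FALSE)
  attr(scan, "array_id") <- paste0("manual_", orientation)
  attr(scan, "sample_id") <- "manual"
  attr(scan, "orientation") <- orientation
  class(scan) <- c("ArrayScan", "data.frame")
  scan
}

# independent union-length oracle: per-bp boolean mask on one small chromosome
mask_union_length <- function(df, chrom_len) {
  mask <- logical(chrom_len)
  for (i in seq_len(nrow(df)))
    mask[(df$start[i] + 1):df$end[i]] <- TRUE
  sum(mask)
}

mask_overlap_length <- function(a, b, chrom_len) {
  ma <- logical(chrom_len); mb <- logical(chrom_len)
  for (i in seq_len(nrow(a))) ma[(a$start[i] + 1):a$end[i]] <- TRUE
  for (i in seq_len(nrow(b))) mb[(b$start[i] + 1):b$end[i]] <- TRUE
  sum(ma & mb)
}

# exhaustive-search oracle for the circular max-T statistic; same guarded
# formula, scanning every arc directly
brute_max_t <- function(x) {
  n <- length(x); S <- c(0, cumsum(x)); Q <- c(0, cumsum(x^2))
  best <- -1; bi <- 0; bj <- 1
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    k <- j - i
    if (k == n) next
    sin_ <- S[j + 1] - S[i + 1]; qin <- Q[j + 1] - Q[i + 1]
    sout <- S[n + 1] - sin_; qout <- Q[n + 1] - qin; ko <- n - k
    sp2 <- max((qin - sin_^2 / k + qout - sout^2 / ko) / (n - 2), 0)
    den <- max(sqrt(sp2 * (1 / k + 1 / ko)), 1e-12)
    diff <- abs(sin_ / k - sout / ko)
    if (diff < 1e-9) diff <- 0
    t <- diff / den
    if (t > best) { best <- t; bi <- i; bj <- j }
  }
  list(i = bi, j = bj, T = best)
}

# an arc's induced cut set on the linear sequence (complement arcs induce
# the same segmentation)
arc_cuts <- function(res, n) setdiff(c(res$i, res$j), c(0L, n))
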