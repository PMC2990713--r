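## Two-color hybridization simulator.
##
## Signal model per spot, on the log2 scale. Let s = +1 for a forward array
## (test dyed Cy5/red, reference Cy3/green) and s = -1 for a reverse array.
## The red/green log ratio written to the scan is
##
##   M_raw = s * (log2(copy/2) + eps) + bias + gradient + block_noise
##
## where eps ~ N(0, noise_sd) is multiplicative noise on the test-sample
## abundance (it rides on the test sample, so it flips with the dye
## assignment and survives the later orientation adjustment unchanged),
## `bias` is a spot-specific dye offset on the red/green ratio (a property
## of the spot, identical across arrays), `gradient` is a smooth chip-level
## spatial artifact, and `block_noise` is extra variance inside simulated
## low-quality rectangles. Channels are reconstructed from (M_raw, A) as
## red = 2^(A + M_raw/2), green = 2^(A - M_raw/2) and a lognormal background
## is added to both, so background subtraction recovers the net signal.

#' Spot-specific dye-bias vector for a chip layout
#'
#' Most spots receive a small zero-mean normal dye offset; a configurable
#' fraction receives an additional large fixed-magnitude offset of random
#' sign, emulating the subpopulation of strongly dye-biased spots seen on
#' real two-color chips. The vector is a property of the layout and must be
#' reused for every array of an experiment.
#'
#' @param layout a \code{ChipLayout}.
#' @param sd SD of the baseline offset (log2 units).
#' @param frac_large fraction of spots with an extra large offset.
#' @param large_mean magnitude of the large offset (log2 units).
#' @param seed integer seed.
#' @return numeric vector, one offset per layout spot, with attribute
#'   \code{large} marking the strongly biased spots.
#' @export
make_dye_bias <- function(layout, sd = 0.05, frac_large = 0.25,
                          large_mean = 0.4, seed = 1L) {
  set.seed(seed)
  n <- nrow(layout)
  bias <- stats::rnorm(n, 0, sd)
  large <- logical(n)
  if (frac_large > 0) {
    idx <- sample.int(n, round(frac_large * n))
    bias[idx] <- bias[idx] + sample(c(-1, 1), length(idx), replace = TRUE) * large_mean
    large[idx] <- TRUE
  }
  attr(bias, "large") <- large
  bias
}

#' Smooth spatial gradient specification
#'
#' A low-order polynomial in the normalized grid coordinates
#' \eqn{u = row/nrow - 1/2}, \eqn{v = col/ncol - 1/2}:
#' \code{coef_row*u + coef_col*v + coef_rowcol*u*v} (log2 units).
#'
#' @param coef_row,coef_col,coef_rowcol polynomial coefficients.
#' @return a list of class \code{gradient_spec}.
#' @export
gradient_spec <- function(coef_row = 0, coef_col = 0, coef_rowcol = 0) {
  structure(list(coef_row = coef_row, coef_col = coef_col,
                 coef_rowcol = coef_rowcol), class = "gradient_spec")
}

eval_gradient <- function(gradient, layout) {
  if (is.null(gradient)) return(numeric(nrow(layout)))
  u <- layout$grid_row / max(layout$grid_row) - 0.5
  v <- layout$grid_col / max(layout$grid_col) - 0.5
  gradient$coef_row * u + gradient$coef_col * v + gradient$coef_rowcol * u * v
}

# copy state (1/2/3) of each layout probe for one sample, by midpoint lookup
probe_copy_states <- function(layout, truth, sample_id) {
  states <- rep(2L, nrow(layout))
  tr <- truth[truth$sample_id == sample_id, , drop = FALSE]
  if (nrow(tr) == 0) return(states)
  mid <- (layout$start + layout$end) / 2
  for (ch in unique(tr$chrom)) {
    sel <- which(layout$chrom == ch)
    if (length(sel) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(floor(mid[sel]) + 1, width = 1L),
      IRanges::IRanges(tr$start[tr$chrom == ch] + 1, tr$end[tr$chrom == ch]))
    states[sel[S4Vectors::queryHits(ov)]] <-
      tr$copy_state[tr$chrom == ch][S4Vectors::subjectHits(ov)]
  }
  states
}

#' Simulate one dye-swap hybridization scan
#'
#' Generates per-spot two-channel foreground/background intensities for one
#' array, given the chip layout, the sample's planted copy-number truth and
#' the array's dye orientation. For a noise-free, bias-free simulation the
#' orientation-adjusted M of a probe in a 3-copy region is exactly
#' \code{log2(3/2)}, in a 1-copy region \code{log2(1/2) = -1}, and 0
#' elsewhere.
#'
#' @param layout a \code{ChipLayout}.
#' @param truth a \code{TruthSet} (may be empty for an all-diploid sample).
#' @param sample_id test-sample id; must be one of the truth set's samples.
#' @param orientation \code{"forward"} (test in red) or \code{"reverse"}.
#' @param bias numeric per-spot dye-bias vector (see
#'   \code{\link{make_dye_bias}}) or a single 0 for no bias.
#' @param gradient a \code{\link{gradient_spec}} or NULL.
#' @param noise_sd SD of the test-abundance noise, log2 units.
#' @param bad_blocks optional data.frame (\code{row0,row1,col0,col1,extra_sd})
#'   of low-quality grid rectangles with inflated variance.
#' @param frac_dead fraction of spots with zero net signal in both channels
#'   (foreground equal to background), for QC exercises.
#' @param a_mean,a_sd mean and SD of the per-spot average log2 intensity A.
#' @param seed integer seed; scans are bit-identical for a fixed seed.
#' @return an \code{ArrayScan} data.frame: \code{probe_id}, \code{grid_row},
#'   \code{grid_col}, \code{ch_red_fg}, \code{ch_red_bg}, \code{ch_green_fg},
#'   \code{ch_green_bg}, \code{qc_flag}; attributes \code{array_id},
#'   \code{sample_id}, \code{orientation}.
#' @export
simulate_hybridization <- function(layout, truth, sample_id,
                                   orientation = c("forward", "reverse"),
                                   bias = 0, gradient = NULL, noise_sd = 0.15,
                                   bad_blocks = NULL, frac_dead = 0,
                                   a_mean = 10, a_sd = 1, seed = 1L) {
  orientation <- match.arg(orientation)
  known <- attr(truth, "samples")
  if (!is.null(known) && !(sample_id %in% known))
    stop("unknown sample_id: ", sample_id, call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  n <- nrow(layout)
  if (length(bias) == 1L) bias <- rep(bias, n)
  stopifnot(length(bias) == n)
  bias <- as.vector(bias)    # drop bookkeeping attributes before arithmetic

  true_m <- log2(probe_copy_states(layout, truth, sample_id) / 2)
  s <- if (orientation == "forward") 1 else -1
  eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  grad <- eval_gradient(gradient, layout)

  block_noise <- numeric(n)
  if (!is.null(bad_blocks) && nrow(bad_blocks) > 0) {
    for (b in seq_len(nrow(bad_blocks))) {
      inb <- layout$grid_row >= bad_blocks$row0[b] & layout$grid_row <= bad_blocks$row1[b] &
        layout$grid_col >= bad_blocks$col0[b] & layout$grid_col <= bad_blocks$col1[b]
      block_noise[inb] <- stats::rnorm(sum(inb), 0, bad_blocks$extra_sd[b])
    }
  }

  m_raw <- s * (true_m + eps) + bias + grad + block_noise
  a <- stats::rnorm(n, a_mean, a_sd)
  red_net <- 2^(a + m_raw / 2)
  green_net <- 2^(a - m_raw / 2)
  red_bg <- 2^(a_mean - 5) * stats::rlnorm(n, 0, 0.2)
  green_bg <- 2^(a_mean - 5) * stats::rlnorm(n, 0, 0.2)
  if (frac_dead > 0) {
    dead <- sample.int(n, round(frac_dead * n))
    red_net[dead] <- 0
    green_net[dead] <- 0
  }
  scan <- data.frame(probe_id = layout$probe_id,
                     grid_row = layout$grid_row, grid_col = layout$grid_col,
                     ch_red_fg = red_net + red_bg, ch_red_bg = red_bg,
                     ch_green_fg = green_net + green_bg, ch_green_bg = green_bg,
                     qc_flag = "pass", stringsAsFactors = FALSE)
  attr(scan, "array_id") <- paste0(sample_id, "_", orientation)
  attr(scan, "sample_id") <- sample_id
  attr(scan, "orientation") <- orientation
  class(scan) <- c("ArrayScan", "data.frame")
  scan
}

#' Simulate a complete dye-swap experiment
#'
#' One forward and one reverse array per sample, all sharing the layout's
#' spot-specific dye-bias vector; per-array sub-seeds are derived from the
#' experiment seed so the whole experiment is reproducible from one integer.
#'
#' @param layout a \code{ChipLayout}.
#' @param truth a \code{TruthSet}.
#' @param samples sample ids (default: the truth set's samples).
#' @param bias per-spot dye-bias vector (see \code{\link{make_dye_bias}}).
#' @param gradients optional list of \code{\link{gradient_spec}}, one per
#'   array (recycled); NULL for no gradient.
#' @param noise_sd,bad_blocks,frac_dead,a_mean,a_sd passed to
#'   \code{\link{simulate_hybridization}}; \code{bad_blocks} may be a list
#'   (one element per array, NULL entries allowed).
#' @param seed experiment seed.
#' @return list with \code{scans} (named list of \code{ArrayScan}),
#'   \code{design} (data.frame \code{array_id}, \code{sample_id},
#'   \code{orientation}, \code{dye}), and \code{bias}.
#' @export
simulate_dyeswap_experiment <- function(layout, truth,
                                        samples = attr(truth, "samples"),
                                        bias = 0, gradients = NULL,
                                        noise_sd = 0.15, bad_blocks = NULL,
                                        frac_dead = 0, a_mean = 10, a_sd = 1,
                                        seed = 1L) {
  if (is.null(samples)) samples <- unique(truth$sample_id)
  design <- data.frame(
    array_id = as.vector(t(outer(samples, c("forward", "reverse"), paste, sep = "_"))),
    sample_id = rep(samples, each = 2),
    orientation = rep(c("forward", "reverse"), length(samples)),
    stringsAsFactors = FALSE)
  design$dye <- ifelse(design$orientation == "forward", 1L, -1L)

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, nrow(design))
  scans <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    grad <- if (is.null(gradients)) NULL
            else gradients[[(i - 1L) %% length(gradients) + 1L]]
    bb <- if (is.null(bad_blocks)) NULL
          else if (is.data.frame(bad_blocks)) bad_blocks
          else bad_blocks[[(i - 1L) %% length(bad_blocks) + 1L]]
    scans[[i]] <- simulate_hybridization(
      layout, truth, design$sample_id[i], design$orientation[i],
      bias = bias, gradient = grad, noise_sd = noise_sd, bad_blocks = bb,
      frac_dead = frac_dead, a_mean = a_mean, a_sd = a_sd, seed = sub_seeds[i])
  }
  names(scans) <- design$array_id
  list(scans = scans, design = design, bias = bias)
}
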