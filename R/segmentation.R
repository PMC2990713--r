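## Circular binary segmentation of per-sample probe M values.

#' Max-T change-point statistic of a circularized sequence
#'
#' Scans every arc (i, j] of the circularized sequence (0-based boundary
#' convention: the arc contains elements i+1 .. j in 1-based indexing) and
#' returns the arc maximizing the two-sample t-like statistic comparing the
#' values inside the arc against those outside, with the pooled-SD
#' denominator floored at 1e-12 so a perfectly clean step yields a large
#' finite statistic. Ties break toward the smallest i, then smallest j.
#'
#' @param values numeric vector of at least 4 ordered M values.
#' @return list with \code{i}, \code{j} (integer arc boundaries) and
#'   \code{T} (the statistic).
#' @export
max_t_statistic <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  if (anyNA(values)) stop("missing values must be dropped first", call. = FALSE)
  .cbs_max_t(values)
}

# permutation p-value of the observed max T within one stretch, with early
# stopping once significance is out of reach
cbs_perm_p <- function(x, t_obs, alpha, nperm) {
  kstop <- as.integer(ceiling(alpha * (nperm + 1) - 1))
  res <- .cbs_perm_count(x, as.integer(nperm), t_obs, max(kstop, 1L))
  count <- res[1]; done <- res[2]
  if (done < nperm) {
    # aborted: p is at least alpha by construction
    list(p = (count + 1) / (done + 1), significant = FALSE)
  } else {
    p <- (count + 1) / (nperm + 1)
    list(p = p, significant = p < alpha)
  }
}

# recursive CBS on one chromosome's ordered values; returns boundary vector
# (0-based cut positions, excluding 0 and n)
cbs_recurse <- function(x, lo, hi, alpha, nperm) {
  m <- hi - lo + 1
  if (m < 4) return(integer(0))
  seg <- x[lo:hi]
  mt <- .cbs_max_t(seg)
  pp <- cbs_perm_p(seg, mt$T, alpha, nperm)
  if (!pp$significant) return(integer(0))
  cuts <- integer(0)
  i <- mt$i; j <- mt$j
  parts <- list()
  if (i > 0) { cuts <- c(cuts, lo - 1 + i); parts <- c(parts, list(c(lo, lo + i - 1))) }
  parts <- c(parts, list(c(lo + i, lo + j - 1)))
  if (j < m) { cuts <- c(cuts, lo - 1 + j); parts <- c(parts, list(c(lo + j, hi))) }
  for (p in parts)
    cuts <- c(cuts, cbs_recurse(x, p[1], p[2], alpha, nperm))
  sort(unique(cuts))
}

# undo spurious splits: repeatedly merge the adjacent segment pair with the
# smallest mean difference while that difference is below merge_tol
merge_close_segments <- function(x, cuts, merge_tol) {
  repeat {
    bounds <- c(0L, cuts, length(x))
    if (length(bounds) <= 2) break
    means <- vapply(seq_len(length(bounds) - 1L), function(k)
      mean(x[(bounds[k] + 1L):bounds[k + 1L]]), numeric(1))
    diffs <- abs(diff(means))
    if (all(diffs >= merge_tol)) break
    drop <- which.min(diffs)
    cuts <- cuts[-drop]
  }
  cuts
}

#' Segment one sample's chromosomes by circular binary segmentation
#'
#' Recursively splits each chromosome's ordered M values at the maximal-T
#' arc whenever the within-stretch permutation p-value of the statistic is
#' below \code{alpha} (permuting probe order within the tested stretch), then
#' undoes splits between adjacent segments whose means differ by less than
#' \code{merge_tol}. Every probe is annotated with its segment mean (the
#' "smoothed" M on which CNVR calling operates).
#'
#' @param pmv a \code{ProbeMValues} data.frame (from
#'   \code{\link{merge_samples}}), or any data.frame with \code{chrom},
#'   \code{start}, \code{end} and sample M columns.
#' @param sample name of the M column to segment.
#' @param alpha permutation significance level for accepting a split.
#' @param nperm permutations per test (>= 100).
#' @param merge_tol minimum mean difference (log2 units) for adjacent
#'   segments to stay separate.
#' @param seed integer seed for the permutation stream.
#' @return list with \code{segments} (data.frame \code{sample_id},
#'   \code{chrom}, \code{first_probe}, \code{last_probe}, \code{start},
#'   \code{end}, \code{n_probes}, \code{seg_mean}) and \code{smoothed}
#'   (\code{pmv} rows with missing M dropped, plus a \code{smoothed} column).
#' @export
segment_sample <- function(pmv, sample, alpha = 0.01, nperm = 10000,
                           merge_tol = 0.05, seed = 1L) {
  if (nperm < 100) stop("nperm must be at least 100", call. = FALSE)
  if (!sample %in% names(pmv)) stop("no column for sample ", sample, call. = FALSE)
  set.seed(seed)
  keep <- !is.na(pmv[[sample]])
  dat <- pmv[keep, , drop = FALSE]
  seg_rows <- list(); sm <- rep(NA_real_, nrow(dat)); k <- 0L
  for (ch in unique(dat$chrom)) {
    idx <- which(dat$chrom == ch)
    x <- dat[[sample]][idx]
    n <- length(x)
    cuts <- if (n >= 4) cbs_recurse(x, 1L, n, alpha, nperm) else integer(0)
    cuts <- merge_close_segments(x, cuts, merge_tol)
    bounds <- c(0L, cuts, n)
    for (b in seq_len(length(bounds) - 1L)) {
      first <- bounds[b] + 1L; last <- bounds[b + 1L]
      mu <- mean(x[first:last])
      sm[idx[first:last]] <- mu
      k <- k + 1L
      seg_rows[[k]] <- data.frame(
        sample_id = sample, chrom = ch, first_probe = first, last_probe = last,
        start = dat$start[idx[first]], end = dat$end[idx[last]],
        n_probes = last - first + 1L, seg_mean = mu, stringsAsFactors = FALSE)
    }
  }
  dat$smoothed <- sm
  segments <- do.call(rbind, seg_rows)
  class(segments) <- c("SegmentTable", "data.frame")
  list(segments = segments, smoothed = dat)
}

#' Segment every sample of a merged M table
#'
#' @param pmv a \code{ProbeMValues} data.frame.
#' @param samples sample column names (default: all non-coordinate columns).
#' @param ... passed to \code{\link{segment_sample}}; per-sample sub-seeds
#'   are derived from \code{seed}.
#' @param seed integer seed.
#' @return named list of \code{\link{segment_sample}} results.
#' @export
segment_all <- function(pmv, samples = setdiff(names(pmv),
                                               c("locus_id", "chrom", "start", "end")),
                        seed = 1L, ...) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max %/% 2L, length(samples))
  out <- lapply(seq_along(samples), function(i)
    segment_sample(pmv, samples[i], seed = sub[i], ...))
  names(out) <- samples
  out
}
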