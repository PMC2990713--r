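## CNVR calling: consecutive-probe rule on smoothed M, flank extension,
## cross-sample union merge.

#' Call per-sample CNVR cores from smoothed M values
#'
#' A core is a maximal run of at least \code{min_probes} consecutive probes
#' (adjacent in genomic order on one chromosome) whose smoothed M values are
#' all above \code{threshold} (gain) or all below \code{-threshold} (loss).
#' The threshold of 0.5 is just below \code{log2(3/2) ~ 0.58}, the expected
#' M of a heterozygous single-copy gain in a diploid-vs-diploid comparison.
#' Each core runs from its first probe's start to its last probe's end and
#' is extended by \code{flank} bp on both sides (about half the median
#' inter-probe spacing, representing one probe's single-sided coverage),
#' clamped to the chromosome; extended same-status regions of one sample
#' that touch or overlap are merged.
#'
#' @param smoothed data.frame of one sample's probes with \code{chrom},
#'   \code{start}, \code{end}, \code{smoothed} (as from
#'   \code{\link{segment_sample}}), ordered by (chrom, start).
#' @param sample_id sample id recorded on the calls.
#' @param genome a \code{GenomeModel} (for chromosome bounds).
#' @param threshold smoothed-M magnitude cutoff.
#' @param min_probes minimum run length.
#' @param flank extension on each side, bp.
#' @param max_gap maximum genomic gap (bp) between consecutive probes of one
#'   run; \code{Inf} (default) imposes no gap rule.
#' @return CNVR data.frame: \code{chrom}, \code{start}, \code{end},
#'   \code{status}, \code{core_start}, \code{core_end}, \code{n_probes},
#'   \code{mean_smoothed_M}, \code{sample_id} (0-based half-open
#'   coordinates).
#' @export
call_cores <- function(smoothed, sample_id, genome, threshold = 0.5,
                       min_probes = 3L, flank = 5000, max_gap = Inf) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      status = character(), core_start = numeric(),
                      core_end = numeric(), n_probes = integer(),
                      mean_smoothed_M = numeric(), sample_id = character(),
                      stringsAsFactors = FALSE)
  rows <- list(); k <- 0L
  for (ch in unique(smoothed$chrom)) {
    d <- smoothed[smoothed$chrom == ch, , drop = FALSE]
    if (is.unsorted(d$start)) stop("probes must be sorted by (chrom, start)",
                                   call. = FALSE)
    clen <- chrom_length(genome, ch)
    state <- ifelse(is.na(d$smoothed), 0L,
                    ifelse(d$smoothed > threshold, 1L,
                           ifelse(d$smoothed < -threshold, -1L, 0L)))
    # break runs at large inter-probe gaps if a gap rule is set
    if (is.finite(max_gap) && nrow(d) > 1) {
      gapbreak <- c(FALSE, (d$start[-1] - d$end[-nrow(d)]) > max_gap)
      run_id <- cumsum(gapbreak)
    } else run_id <- rep(0L, nrow(d))
    r <- rle(paste0(state, ".", run_id))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    st_vals <- as.integer(sub("\\..*", "", r$values))
    for (q in which(st_vals != 0L & r$lengths >= min_probes)) {
      first <- starts[q]; last <- ends[q]
      core_start <- d$start[first]; core_end <- d$end[last]
      k <- k + 1L
      rows[[k]] <- data.frame(
        chrom = ch, start = max(0, core_start - flank),
        end = min(clen, core_end + flank),
        status = if (st_vals[q] > 0) "gain" else "loss",
        core_start = core_start, core_end = core_end,
        n_probes = last - first + 1L,
        mean_smoothed_M = mean(d$smoothed[first:last]),
        sample_id = sample_id, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty)
  out <- do.call(rbind, rows)
  # merge extended same-status regions of this sample that touch or overlap
  merged <- list(); k <- 0L
  for (st in c("gain", "loss")) {
    sub <- out[out$status == st, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (ch in unique(sub$chrom)) {
      s <- sub[sub$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      grp <- cumsum(c(1, s$start[-1] > cummax(s$end[-nrow(s)])))
      for (g in unique(grp)) {
        gg <- s[grp == g, , drop = FALSE]
        k <- k + 1L
        merged[[k]] <- data.frame(
          chrom = ch, start = min(gg$start), end = max(gg$end), status = st,
          core_start = min(gg$core_start), core_end = max(gg$core_end),
          n_probes = sum(gg$n_probes),
          mean_smoothed_M = sum(gg$mean_smoothed_M * gg$n_probes) / sum(gg$n_probes),
          sample_id = sample_id, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("CNVRTable", "data.frame")
  out
}

#' Merge per-sample CNVR sets into the non-redundant set
#'
#' Within each status separately, overlapping or book-ended regions across
#' samples are unioned into one region supported by every contributing
#' sample; gains and losses are never merged with each other. Regions are
#' named \code{cnv.<status>.<k>} in genomic order within status.
#'
#' @param cnvr_sets list of per-sample CNVR data.frames (from
#'   \code{\link{call_cores}}).
#' @return non-redundant CNVR data.frame: \code{chrom}, \code{start},
#'   \code{end}, \code{status}, \code{name}, \code{supporting_samples}
#'   (comma-separated), \code{n_samples}.
#' @export
merge_to_nonredundant <- function(cnvr_sets) {
  all <- do.call(rbind, cnvr_sets)
  out_rows <- list(); k <- 0L
  for (st in c("gain", "loss")) {
    sub <- all[all$status == st, , drop = FALSE]
    if (nrow(sub) == 0) next
    red <- merge_intervals(sub[, c("chrom", "start", "end")])
    if (nrow(red) == 0) next
    for (i in seq_len(nrow(red))) {
      hit <- sub$chrom == red$chrom[i] & sub$start < red$end[i] &
        red$start[i] < sub$end
      supp <- sort(unique(sub$sample_id[hit]))
      k <- k + 1L
      out_rows[[k]] <- data.frame(
        chrom = red$chrom[i], start = red$start[i], end = red$end[i],
        status = st, supporting_samples = paste(supp, collapse = ","),
        n_samples = length(supp), stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      status = character(), name = character(),
                      supporting_samples = character(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out_rows)
  out <- out[order(out$status, out$chrom, out$start), , drop = FALSE]
  out$name <- NA_character_
  for (st in unique(out$status)) {
    ix <- which(out$status == st)
    out$name[ix] <- sprintf("cnv.%s.%d", st, seq_along(ix))
  }
  out <- out[order(out$chrom, out$start, out$status), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("CNVRTable", "data.frame")
  out
}
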