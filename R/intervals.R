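## Interval algebra over 0-based half-open (BED-convention) interval tables.
## Backed by IRanges; the data.frame surface keeps coordinates BED-style and
## conversion to 1-based closed IRanges happens only at the boundary.

df_to_irl <- function(df) {
  if (nrow(df) == 0)
    return(IRanges::IRangesList())
  if (any(df$end <= df$start))
    stop("intervals must satisfy start < end", call. = FALSE)
  spl <- split(IRanges::IRanges(start = df$start + 1, end = df$end), df$chrom)
  methods::as(spl, "IRangesList")
}

irl_to_df <- function(irl) {
  n <- sum(lengths(irl))
  if (n == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  ul <- unlist(irl, use.names = FALSE)
  data.frame(chrom = rep(names(irl), lengths(irl)),
             start = BiocGenerics::start(ul) - 1,
             end = BiocGenerics::end(ul),
             stringsAsFactors = FALSE)
}

merged_length_df <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(as.numeric(unlist(lapply(df_to_irl(df), function(ir)
    sum(as.numeric(BiocGenerics::width(IRanges::reduce(ir))))))))
}

#' Merge an interval set to non-redundant (disjoint) intervals
#'
#' Collapses self-overlapping and book-ended intervals per chromosome into the
#' minimal disjoint covering set, so that downstream length accounting never
#' double-counts.
#'
#' @param df data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based, half-open).
#' @return data.frame of the same shape, sorted, pairwise disjoint per
#'   chromosome, with attribute \code{merged = TRUE}.
#' @export
merge_intervals <- function(df) {
  irl <- df_to_irl(df)
  out <- irl_to_df(methods::as(lapply(irl, IRanges::reduce), "IRangesList"))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "merged") <- TRUE
  out
}

#' Total intersection length of two interval sets
#'
#' @param a,b interval data.frames (\code{chrom}, \code{start}, \code{end});
#'   each is merged internally before intersecting.
#' @return total overlap in bp (symmetric in its arguments).
#' @export
overlap_length <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ia <- lapply(df_to_irl(a), IRanges::reduce)
  ib <- lapply(df_to_irl(b), IRanges::reduce)
  common <- intersect(names(ia), names(ib))
  if (length(common) == 0) return(0)
  sum(vapply(common, function(ch)
    sum(as.numeric(BiocGenerics::width(IRanges::intersect(ia[[ch]], ib[[ch]])))),
    numeric(1)))
}

# Sum over query intervals of each one's own overlap with (merged) features.
# Differs from overlap_length in that mutually overlapping query intervals
# contribute their overlaps separately (summed, not unioned).
summed_overlap <- function(query, features_irl_reduced) {
  if (nrow(query) == 0) return(0)
  tot <- 0
  for (ch in intersect(unique(query$chrom), names(features_irl_reduced))) {
    q <- query[query$chrom == ch, ]
    qr <- IRanges::IRanges(start = q$start + 1, end = q$end)
    ov <- IRanges::findOverlaps(qr, features_irl_reduced[[ch]])
    if (length(ov) == 0) next
    qs <- qr[S4Vectors::queryHits(ov)]
    fs <- features_irl_reduced[[ch]][S4Vectors::subjectHits(ov)]
    tot <- tot + sum(as.numeric(
      pmin(BiocGenerics::end(qs), BiocGenerics::end(fs)) -
        pmax(BiocGenerics::start(qs), BiocGenerics::start(fs)) + 1))
  }
  tot
}

#' Gene/intergenic coverage accounting for a CNVR set
#'
#' Partitions the CNVR length per status (and in total) into its gene-overlap
#' and intergenic parts, and reports the whole-genome gene fraction for
#' comparison, with percentages to two decimals.
#'
#' @param cnvrs CNVR data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{status} (\code{gain}/\code{loss}).
#' @param genes gene interval data.frame (merged internally).
#' @param genome a \code{GenomeModel} (for total genome length).
#' @return data.frame with one row per status plus \code{total} and
#'   \code{genome}: columns \code{length_bp}, \code{gene_bp},
#'   \code{intergenic_bp}, \code{gene_pct}, \code{intergenic_pct}.
#' @export
coverage_table <- function(cnvrs, genes, genome) {
  genes <- merge_intervals(genes)
  row_for <- function(set) {
    len <- merged_length_df(set)
    g <- overlap_length(set, genes)
    data.frame(length_bp = len, gene_bp = g, intergenic_bp = len - g,
               gene_pct = round(100 * g / len, 2),
               intergenic_pct = round(100 * (len - g) / len, 2))
  }
  parts <- lapply(c(gain = "gain", loss = "loss"), function(st)
    row_for(cnvrs[cnvrs$status == st, , drop = FALSE]))
  tot <- row_for(cnvrs)
  gtot <- sum(genome$chromosomes$length)
  glen <- merged_length_df(genes)
  grow <- data.frame(length_bp = gtot, gene_bp = glen, intergenic_bp = gtot - glen,
                     gene_pct = round(100 * glen / gtot, 2),
                     intergenic_pct = round(100 * (gtot - glen) / gtot, 2))
  out <- rbind(gain = parts$gain, loss = parts$loss, total = tot, genome = grow)
  out$region <- rownames(out)
  rownames(out) <- NULL
  out[, c("region", "length_bp", "gene_bp", "intergenic_bp",
          "gene_pct", "intergenic_pct")]
}

#' Genes overlapping CNVRs, per status
#'
#' A gene is reported for a status if it overlaps at least one bp of a CNVR
#' of that status (half-open convention: book-ended intervals do not
#' overlap). A gene may appear under both statuses.
#'
#' @param cnvrs CNVR data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{status}).
#' @param genes gene data.frame with an \code{id} column.
#' @return named list \code{gain}, \code{loss} of sorted gene-id vectors.
#' @export
genes_overlapping <- function(cnvrs, genes) {
  one_status <- function(st) {
    set <- cnvrs[cnvrs$status == st, , drop = FALSE]
    if (nrow(set) == 0 || nrow(genes) == 0) return(character())
    hits <- character()
    for (ch in intersect(unique(set$chrom), unique(genes$chrom))) {
      g <- genes[genes$chrom == ch, ]
      s <- set[set$chrom == ch, ]
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(g$start + 1, g$end),
        IRanges::IRanges(s$start + 1, s$end))
      hits <- c(hits, g$id[unique(S4Vectors::queryHits(ov))])
    }
    sort(unique(hits))
  }
  list(gain = one_status("gain"), loss = one_status("loss"))
}

#' Random-interval permutation test of CNVR/feature overlap
#'
#' Tests whether the observed overlap between a query interval set (typically
#' the non-redundant CNVRs) and a genomic feature set (genes, ultraconserved
#' elements, ...) is smaller (depletion) or larger (enrichment) than expected
#' for randomly placed intervals. Each round places the same number of
#' intervals with the query's exact lengths uniformly over the genome
#' (chromosome chosen with probability proportional to valid start positions;
#' each interval fully within its chromosome; placed intervals may overlap
#' one another and their overlaps with the features are summed, not unioned),
#' and records the summed overlap with the features as the null statistic.
#'
#' @param query interval data.frame (\code{chrom}, \code{start}, \code{end}).
#' @param features feature interval data.frame; merged internally.
#' @param genome a \code{GenomeModel}.
#' @param n_rounds number of null rounds (default 1000).
#' @param tail \code{"depletion"} (observed unusually small) or
#'   \code{"enrichment"}.
#' @param seed integer seed; the null is deterministic for a fixed seed.
#' @return an \code{OverlapResult} list: \code{observed}, \code{null_overlaps}
#'   (length \code{n_rounds}), \code{expected} (null mean), \code{null_sd},
#'   \code{z}, \code{p_value} (pseudocount estimator \eqn{(k+1)/(n+1)}, never
#'   exactly 0), \code{tail}, \code{n_rounds}, \code{seed}.
#' @export
random_interval_test <- function(query, features, genome, n_rounds = 1000,
                                 tail = c("depletion", "enrichment"), seed = 1L) {
  tail <- match.arg(tail)
  set.seed(seed)
  lens <- query$end - query$start
  cl <- stats::setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  if (any(lens > max(cl)))
    stop("a query interval is longer than every chromosome", call. = FALSE)

  feats <- lapply(df_to_irl(features), IRanges::reduce)
  observed <- summed_overlap(query, feats)

  m <- length(lens)
  null_overlaps <- numeric(n_rounds)
  chrom_names <- names(cl)
  for (r in seq_len(n_rounds)) {
    # vectorized placement of all m intervals for this round
    chs <- character(m); sts <- numeric(m)
    for (i in seq_len(m)) {
      valid <- pmax(cl - lens[i] + 1, 0)
      ch <- sample(chrom_names, 1L, prob = valid)
      chs[i] <- ch
      sts[i] <- floor(stats::runif(1, 0, valid[[ch]]))
    }
    placed <- data.frame(chrom = chs, start = sts, end = sts + lens,
                         stringsAsFactors = FALSE)
    null_overlaps[r] <- summed_overlap(placed, feats)
  }
  k <- if (tail == "depletion") sum(null_overlaps <= observed)
       else sum(null_overlaps >= observed)
  res <- list(observed = observed, null_overlaps = null_overlaps,
              expected = mean(null_overlaps), null_sd = stats::sd(null_overlaps),
              z = (observed - mean(null_overlaps)) / stats::sd(null_overlaps),
              p_value = (k + 1) / (n_rounds + 1),
              tail = tail, n_rounds = n_rounds, seed = seed)
  class(res) <- "OverlapResult"
  res
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("Random-interval %s test (%d rounds, seed %d)\n",
              x$tail, x$n_rounds, x$seed))
  cat(sprintf("  observed %.0f bp vs expected %.0f +/- %.0f bp (z = %.2f, p = %.4g)\n",
              x$observed, x$expected, x$null_sd, x$z, x$p_value))
  invisible(x)
}
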