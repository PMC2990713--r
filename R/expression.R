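## Expression-consistency re-analysis: probeset collapsing, per-gene
## two-group t-tests at a relaxed FDR, and CNV/expression direction calls.

#' Collapse probesets to gene-level expression rows
#'
#' For genes measured by several probesets, each probeset is scored by the
#' number of samples in which it attains the gene's maximum intensity (ties
#' within a sample credit every tied probeset). The strict winner's row is
#' kept; if several probesets tie on that count, their intensities are
#' averaged sample-wise. Single-probeset genes pass through.
#'
#' @param mat numeric matrix, probesets x samples, linear-scale intensities.
#' @param map data.frame \code{probeset_id}, \code{gene_id}; probesets
#'   missing from the map are dropped.
#' @return numeric matrix, genes x samples (rownames = gene ids).
#' @export
collapse_probesets <- function(mat, map) {
  map <- map[map$probeset_id %in% rownames(mat), , drop = FALSE]
  genes <- unique(map$gene_id)
  out <- matrix(NA_real_, length(genes), ncol(mat),
                dimnames = list(genes, colnames(mat)))
  for (g in genes) {
    ps <- map$probeset_id[map$gene_id == g]
    sub <- mat[ps, , drop = FALSE]
    if (length(ps) == 1L) {
      out[g, ] <- sub[1, ]
      next
    }
    top <- apply(sub, 2, max)
    wins <- rowSums(sweep(sub, 2, top, "==") * 1)
    best <- which(wins == max(wins))
    out[g, ] <- if (length(best) == 1L) sub[best, ] else colMeans(sub[best, , drop = FALSE])
  }
  out
}

#' Per-gene two-group differential-expression test
#'
#' Intensities are log2-transformed, the per-gene test-minus-control
#' difference of means is the log2 fold change, and a per-gene t-test
#' (Welch by default, pooled optional) yields raw p-values that are
#' BH-adjusted across genes. A gene's direction is the fold-change sign
#' when its FDR is at or below the threshold, \code{"ns"} otherwise.
#' The relaxed default threshold of 0.2 accepts that up to 20 percent of
#' the reported genes may be false discoveries in exchange for sensitivity.
#'
#' @param mat genes x samples matrix of linear-scale intensities.
#' @param groups character vector (one per column) with values
#'   \code{"test"}/\code{"control"}; at least 2 samples per group.
#' @param fdr_threshold BH FDR cutoff for calling a direction.
#' @param var_equal FALSE for Welch (default), TRUE for pooled variance.
#' @return \code{DEResult} data.frame: \code{gene_id}, \code{log2_fc},
#'   \code{t}, \code{df}, \code{raw_p}, \code{fdr}, \code{direction}
#'   (\code{up}/\code{down}/\code{ns}).
#' @export
de_test <- function(mat, groups, fdr_threshold = 0.2, var_equal = FALSE) {
  stopifnot(length(groups) == ncol(mat))
  it <- groups == "test"; ic <- groups == "control"
  if (sum(it) < 2 || sum(ic) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  lx <- log2(mat)
  n1 <- sum(it); n2 <- sum(ic)
  m1 <- rowMeans(lx[, it, drop = FALSE]); m2 <- rowMeans(lx[, ic, drop = FALSE])
  v1 <- apply(lx[, it, drop = FALSE], 1, stats::var)
  v2 <- apply(lx[, ic, drop = FALSE], 1, stats::var)
  lfc <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(mat))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0 & lfc == 0] <- 1
  fdr <- bh_adjust(p)
  out <- data.frame(gene_id = rownames(mat), log2_fc = lfc, t = tstat, df = df,
                    raw_p = p, fdr = fdr,
                    direction = ifelse(fdr <= fdr_threshold,
                                       ifelse(lfc > 0, "up", "down"), "ns"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DEResult", "data.frame")
  out
}

#' CNV-vs-expression direction consistency
#'
#' A gene in a gain CNVR is consistent when up-regulated and inconsistent
#' when down-regulated (and vice versa for losses); genes without a
#' significant direction are untested.
#'
#' @param cnv_genes named list \code{gain}, \code{loss} of gene-id vectors
#'   (as from \code{\link{genes_overlapping}}).
#' @param de a \code{DEResult} data.frame.
#' @return data.frame \code{gene_id}, \code{cnv_status}, \code{direction},
#'   \code{consistency} (\code{consistent}/\code{inconsistent}/
#'   \code{untested}); one row per gene-status assignment.
#' @export
consistency_call <- function(cnv_genes, de) {
  rows <- list(); k <- 0L
  for (st in c("gain", "loss")) {
    for (g in cnv_genes[[st]]) {
      dir <- de$direction[match(g, de$gene_id)]
      if (is.na(dir)) dir <- "ns"
      cons <- if (dir == "ns") "untested"
              else if ((st == "gain") == (dir == "up")) "consistent"
              else "inconsistent"
      k <- k + 1L
      rows[[k]] <- data.frame(gene_id = g, cnv_status = st, direction = dir,
                              consistency = cons, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(gene_id = character(), cnv_status = character(),
                      direction = character(), consistency = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Background-subtracted mean signal summary (miRNA-style probes)
#'
#' Mean foreground minus mean background per probe per group, with no test
#' statistic: a plain descriptive readout of probe-level expression.
#'
#' @param fg,bg probes x samples matrices of foreground and background
#'   intensities.
#' @param groups character vector of group labels per column.
#' @return data.frame \code{probe_id}, one net-mean column per group.
#' @export
probe_signal_summary <- function(fg, bg, groups) {
  stopifnot(identical(dim(fg), dim(bg)), length(groups) == ncol(fg))
  out <- data.frame(probe_id = rownames(fg), stringsAsFactors = FALSE)
  for (g in unique(groups)) {
    sel <- groups == g
    out[[paste0("net_mean_", g)]] <-
      rowMeans(fg[, sel, drop = FALSE]) - rowMeans(bg[, sel, drop = FALSE])
  }
  out
}

#' Simulate a probeset-level expression matrix with planted DE genes
#'
#' Lognormal-intensity two-group matrix where a fraction of genes is shifted
#' by a fixed log2 effect in the test group; genes may carry several
#' probesets. Ground truth is returned for calibration tests.
#'
#' @param n_genes number of genes.
#' @param n_test,n_control samples per group.
#' @param frac_de fraction of genes differentially expressed.
#' @param lfc planted log2 fold change (sign randomized per gene).
#' @param probesets_per_gene maximum probesets per gene (drawn uniformly).
#' @param noise_sd per-sample log2 noise SD.
#' @param seed integer seed.
#' @return list: \code{mat} (probesets x samples, linear scale), \code{map}
#'   (probeset -> gene), \code{groups}, \code{truth} (data.frame
#'   \code{gene_id}, \code{is_de}, \code{true_lfc}).
#' @export
simulate_expression <- function(n_genes = 2000, n_test = 5, n_control = 5,
                                frac_de = 0.1, lfc = 2, probesets_per_gene = 3,
                                noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  is_de <- stats::runif(n_genes) < frac_de
  true_lfc <- ifelse(is_de, sample(c(-1, 1), n_genes, TRUE) * lfc, 0)
  base <- stats::rnorm(n_genes, 8, 1.5)
  nps <- sample.int(probesets_per_gene, n_genes, replace = TRUE)
  map <- data.frame(
    probeset_id = sprintf("ps%06d", seq_len(sum(nps))),
    gene_id = rep(genes, nps), stringsAsFactors = FALSE)
  groups <- c(rep("test", n_test), rep("control", n_control))
  ps_base <- base[match(map$gene_id, genes)] +
    stats::rnorm(nrow(map), 0, 0.3)   # probeset-specific affinity offset
  eff <- true_lfc[match(map$gene_id, genes)]
  lmat <- sapply(seq_along(groups), function(j)
    ps_base + (groups[j] == "test") * eff + stats::rnorm(nrow(map), 0, noise_sd))
  dimnames(lmat) <- list(map$probeset_id,
                         paste0(groups, rep(seq_len(max(n_test, n_control)),
                                            length.out = length(groups))))
  list(mat = 2^lmat, map = map, groups = groups,
       truth = data.frame(gene_id = genes, is_de = is_de, true_lfc = true_lfc,
                          stringsAsFactors = FALSE))
}
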