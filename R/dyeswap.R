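## Per-spot linear model for dye bias in a balanced dye-swap design.
##
## Each spot's oriented M values across the arrays are modeled as
##   M_i = alpha + beta * Dye_i + e_i
## with Dye_i = +1 on forward and -1 on reverse arrays. alpha captures the
## genomic test/reference difference at the spot, beta the spot-specific dye
## bias (which changes sign under orientation adjustment and therefore does
## not cancel in the mean). Both are estimated by ordinary least squares;
## with a balanced design alpha is the grand mean and beta is half the
## forward-minus-reverse mean difference. Correction subtracts beta * Dye_i.

#' Assemble the probe-by-array oriented M matrix
#'
#' @param spots_list named list of oriented \code{SpotMeasurements} (names =
#'   array ids, as from \code{\link{preprocess_scan}}).
#' @param design data.frame with \code{array_id}, \code{sample_id},
#'   \code{orientation} (and optionally \code{dye}).
#' @return numeric matrix, rownames = probe ids, colnames = array ids in
#'   design order; QC-failed spots are NA.
#' @export
build_m_matrix <- function(spots_list, design) {
  if (!all(design$array_id %in% names(spots_list)))
    stop("spots_list is missing arrays named in the design", call. = FALSE)
  ids <- spots_list[[design$array_id[1]]]$probe_id
  M <- sapply(design$array_id, function(a) {
    sp <- spots_list[[a]]
    if (!identical(sp$probe_id, ids))
      stop("arrays disagree on probe order", call. = FALSE)
    sp$M
  })
  rownames(M) <- ids
  M
}

design_dye <- function(design) {
  if (!is.null(design$dye)) return(as.numeric(design$dye))
  ifelse(design$orientation == "forward", 1, -1)
}

validate_design <- function(design) {
  d <- design_dye(design)
  if (!any(d > 0) || !any(d < 0))
    stop("design needs at least one forward and one reverse array", call. = FALSE)
  invisible(design)
}

#' Fit the per-spot dye-bias model
#'
#' Ordinary least squares of each spot's oriented M values on (intercept,
#' Dye), vectorized over spots. Spots observed on fewer than
#' \code{min_arrays} arrays or on only one dye level are skipped (reported
#' via the \code{skipped} attribute). The p-value for beta is an ordinary
#' t-test with n - 2 degrees of freedom.
#'
#' @param M oriented M matrix (probes x arrays), as from
#'   \code{\link{build_m_matrix}}.
#' @param design the array design (one row per column of M).
#' @param min_arrays minimum observations per spot.
#' @return a \code{DyeBiasFit} data.frame: \code{probe_id}, \code{alpha},
#'   \code{beta}, \code{sigma} (residual SD), \code{df}, \code{t},
#'   \code{beta_p}, \code{n_obs}; attribute \code{skipped} holds ids of
#'   unfittable spots.
#' @export
fit_dye_model <- function(M, design, min_arrays = 4L) {
  validate_design(design)
  stopifnot(ncol(M) == nrow(design))
  d <- design_dye(design)

  obs <- !is.na(M)
  n <- rowSums(obs)
  n_f <- rowSums(obs[, d > 0, drop = FALSE])
  n_r <- rowSums(obs[, d < 0, drop = FALSE])
  fit_ok <- n >= min_arrays & n_f >= 1L & n_r >= 1L

  # normal equations per spot: S0 = n, S1 = sum(d), S2 = sum(d^2) over
  # observed entries; Sy = sum(M), Sdy = sum(d * M)
  M0 <- M; M0[!obs] <- 0
  S1 <- as.vector(obs %*% d)
  S2 <- as.vector(obs %*% (d^2))
  Sy <- rowSums(M0)
  Sdy <- as.vector(M0 %*% d)
  det <- n * S2 - S1^2
  beta <- (n * Sdy - S1 * Sy) / det
  alpha <- (Sy - beta * S1) / n

  resid <- M - alpha - outer(beta, d)
  resid[!obs] <- 0
  rss <- rowSums(resid^2)
  df <- n - 2
  sigma2 <- ifelse(df > 0, rss / df, NA_real_)
  # Var(beta_hat) = sigma^2 * n / det for the 2x2 design
  se_beta <- sqrt(sigma2 * n / det)
  tstat <- beta / se_beta
  beta_p <- 2 * stats::pt(-abs(tstat), df)

  out <- data.frame(probe_id = rownames(M), alpha = alpha, beta = beta,
                    sigma = sqrt(sigma2), df = df, t = tstat, beta_p = beta_p,
                    n_obs = n, stringsAsFactors = FALSE)
  out[!fit_ok, c("alpha", "beta", "sigma", "t", "beta_p")] <- NA_real_
  attr(out, "skipped") <- rownames(M)[!fit_ok]
  class(out) <- c("DyeBiasFit", "data.frame")
  out
}

#' Fraction of spots with significant dye bias
#'
#' @param fits a \code{DyeBiasFit}.
#' @param alpha significance level for the per-spot beta t-test.
#' @return fraction of fitted spots with \code{beta_p < alpha}.
#' @export
dye_bias_fraction <- function(fits, alpha = 0.05) {
  mean(fits$beta_p < alpha, na.rm = TRUE)
}

#' Remove the dye-bias component from oriented M values
#'
#' Subtracts \code{beta * Dye_i} from each spot's M on each array. Spots
#' without a fit pass through unchanged (their ids are carried in the
#' \code{uncorrected} attribute). On a balanced design the corrected forward
#' and reverse means agree per spot, and refitting beta on corrected data
#' gives 0.
#'
#' @param M oriented M matrix.
#' @param fits a \code{DyeBiasFit} aligned with M's rows.
#' @param design the array design.
#' @return corrected M matrix with attribute \code{uncorrected}.
#' @export
correct_dye_bias <- function(M, fits, design) {
  stopifnot(identical(rownames(M), fits$probe_id))
  d <- design_dye(design)
  beta <- ifelse(is.na(fits$beta), 0, fits$beta)
  out <- M - outer(beta, d)
  attr(out, "uncorrected") <- fits$probe_id[is.na(fits$beta)]
  out
}

#' Hierarchical clustering diagnostic of the arrays
#'
#' Ward minimum-variance clustering of the arrays on Euclidean distances over
#' complete-case spots. Before dye-bias correction the two-group cut of this
#' tree typically separates forward from reverse arrays; after correction,
#' dye-swap pairs should join before any cross-sample merge.
#'
#' @param M probe-by-array M matrix (oriented or corrected).
#' @return list: \code{hclust} (the merge tree), \code{cut2} (named two-group
#'   labels), \code{newick} (the tree as Newick text).
#' @export
cluster_arrays <- function(M) {
  if (ncol(M) < 2) stop("need at least 2 arrays to cluster", call. = FALSE)
  cc <- stats::complete.cases(M)
  hc <- stats::hclust(stats::dist(t(M[cc, , drop = FALSE])), method = "ward.D2")
  list(hclust = hc,
       cut2 = stats::cutree(hc, k = 2),
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Merge corrected arrays into per-sample M values
#'
#' Averages each sample's forward and reverse corrected M values, then
#' averages on-chip replicate probes of the same locus, producing one M per
#' locus per sample ordered along the genome.
#'
#' @param M corrected M matrix.
#' @param design the array design (each sample must have >= 2 arrays forming
#'   a dye-swap pair).
#' @param layout the \code{ChipLayout} the matrix rows follow.
#' @return a \code{ProbeMValues} data.frame: \code{locus_id}, \code{chrom},
#'   \code{start}, \code{end}, then one M column per sample, sorted by
#'   (chrom, start).
#' @export
merge_samples <- function(M, design, layout) {
  stopifnot(identical(rownames(M), layout$probe_id))
  samples <- unique(design$sample_id)
  for (s in samples) {
    o <- design$orientation[design$sample_id == s]
    if (!("forward" %in% o) || !("reverse" %in% o))
      stop("sample ", s, " lacks a complete dye-swap pair", call. = FALSE)
  }
  per_sample <- sapply(samples, function(s)
    rowMeans(M[, design$sample_id == s, drop = FALSE], na.rm = TRUE))
  per_sample[is.nan(per_sample)] <- NA_real_

  key <- layout$locus_id
  agg <- stats::aggregate(per_sample, by = list(locus_id = key), FUN = mean,
                          na.rm = TRUE)
  loci <- layout[!duplicated(key), c("locus_id", "chrom", "start", "end")]
  out <- merge(loci, agg, by = "locus_id", sort = FALSE)
  out <- out[order(match(out$chrom, unique(layout$chrom)), out$start), ]
  out[sapply(out, is.nan)] <- NA
  rownames(out) <- NULL
  class(out) <- c("ProbeMValues", "data.frame")
  out
}
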