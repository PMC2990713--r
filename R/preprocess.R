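## Spot/region quality control and MA normalization for one array.

#' Spot and region quality control
#'
#' Two rules, neither of which ever unflags a spot or alters intensities:
#' (1) spot-level: nonpositive background-subtracted signal in either channel
#' fails the spot; (2) region-level: the chip grid is scanned with a sliding
#' square window (half-window step); within each window a spot is an outlier
#' when its raw log-ratio deviates from the window median by more than
#' \code{outlier_mads} array-wide MADs, and when the window's outlier
#' fraction exceeds \code{max_outlier_frac} the entire window is flagged.
#' This catches rectangular low-quality chip regions whose variance is
#' inflated relative to the rest of the array.
#'
#' @param scan an \code{ArrayScan}.
#' @param window window side, in grid spots.
#' @param outlier_mads outlier threshold in array-wide MAD units.
#' @param max_outlier_frac window outlier fraction above which the whole
#'   window is flagged.
#' @return the scan with updated \code{qc_flag} (\code{"pass"}/\code{"fail"}).
#' @export
quality_control <- function(scan, window = 10L, outlier_mads = 3,
                            max_outlier_frac = 0.4) {
  red <- scan$ch_red_fg - scan$ch_red_bg
  green <- scan$ch_green_fg - scan$ch_green_bg
  fail <- red <= 0 | green <= 0 | scan$qc_flag == "fail"

  m <- rep(NA_real_, nrow(scan))
  ok <- !fail
  m[ok] <- log2(red[ok] / green[ok])
  scale_mad <- stats::mad(m, na.rm = TRUE)
  if (is.finite(scale_mad) && scale_mad > 0) {
    step <- max(1L, window %/% 2L)
    for (r0 in seq(1L, max(scan$grid_row), by = step)) {
      for (c0 in seq(1L, max(scan$grid_col), by = step)) {
        inw <- which(scan$grid_row >= r0 & scan$grid_row < r0 + window &
                       scan$grid_col >= c0 & scan$grid_col < c0 + window)
        mw <- m[inw]
        if (sum(!is.na(mw)) < 4L) next
        med <- stats::median(mw, na.rm = TRUE)
        out_frac <- mean(abs(mw - med) > outlier_mads * scale_mad, na.rm = TRUE)
        if (out_frac > max_outlier_frac) fail[inw] <- TRUE
      }
    }
  }
  scan$qc_flag <- ifelse(fail, "fail", "pass")
  scan
}

#' Compute M and A values from a scan
#'
#' M is the red/green log2 ratio of the background-subtracted channels (on a
#' forward array: test over reference); A is the average log2 net intensity.
#' QC-failed spots get missing M/A and weight 0. Orientation is handled later
#' by \code{\link{orient_reverse}}.
#'
#' @param scan a quality-controlled \code{ArrayScan}.
#' @return a \code{SpotMeasurements} data.frame: \code{probe_id}, \code{M},
#'   \code{A}, \code{weight}, \code{qc_flag}, carrying the scan's
#'   \code{array_id}/\code{sample_id}/\code{orientation} attributes.
#' @export
compute_m_a <- function(scan) {
  ok <- scan$qc_flag == "pass"
  if (!any(ok)) stop("all spots failed QC; no M values to compute", call. = FALSE)
  red <- scan$ch_red_fg - scan$ch_red_bg
  green <- scan$ch_green_fg - scan$ch_green_bg
  M <- A <- rep(NA_real_, nrow(scan))
  M[ok] <- log2(red[ok] / green[ok])
  A[ok] <- (log2(red[ok]) + log2(green[ok])) / 2
  out <- data.frame(probe_id = scan$probe_id, M = M, A = A,
                    weight = as.numeric(ok & abs(M) <= 1 & !is.na(M)),
                    qc_flag = scan$qc_flag, stringsAsFactors = FALSE)
  for (at in c("array_id", "sample_id", "orientation"))
    attr(out, at) <- attr(scan, at)
  class(out) <- c("SpotMeasurements", "data.frame")
  out
}

# Robust weighted-loess curve of M on A: fit on the weighted spots, iterate
# outlier rejection (|residual| > mads * MAD) and refit; returns fitted values
# at every A (nearest-end extrapolation outside the fitted range).
robust_loess_curve <- function(M, A, use, span, iterations = 3L, mads = 3) {
  keep <- use
  fit <- NULL
  for (it in seq_len(iterations + 1L)) {
    fit <- stats::loess(M[keep] ~ A[keep], span = span, degree = 1,
                        family = "gaussian")
    if (it > iterations) break
    res <- M[keep] - stats::fitted(fit)
    s <- stats::mad(res)
    new_keep <- keep
    new_keep[keep] <- abs(res) <= mads * s + 1e-8
    if (identical(new_keep, keep)) break
    if (sum(new_keep) < 10L) break
    keep <- new_keep
  }
  xs <- A[keep]
  o <- order(xs)
  stats::approx(xs[o], stats::fitted(fit)[o], xout = A, rule = 2, ties = mean)$y
}

#' Weighted-loess MA normalization
#'
#' Fits a loess curve of M on A using only the spots with M between -1 and 1
#' (weight 1; all other spots weight 0), with iterated outlier rejection for
#' robustness, and subtracts the fitted value from every spot's M. The
#' weighted spots' normalized M is centred: its median is within 0.01 of 0.
#'
#' @param spots a \code{SpotMeasurements} data.frame.
#' @param span loess span (default 0.3, local-linear).
#' @param iterations robustness iterations (outlier drop + refit).
#' @return the spots with normalized \code{M} and an \code{A_fit} column of
#'   subtracted fitted values.
#' @export
loess_normalize <- function(spots, span = 0.3, iterations = 3L) {
  use <- spots$weight == 1 & !is.na(spots$M) & !is.na(spots$A)
  if (sum(use) < 10L)
    stop("fewer than 10 weighted spots; cannot normalize", call. = FALSE)
  fitted_at <- rep(NA_real_, nrow(spots))
  okA <- !is.na(spots$A)
  fitted_at[okA] <- robust_loess_curve(spots$M[okA], spots$A[okA], use[okA],
                                       span = span, iterations = iterations)
  spots$M <- spots$M - fitted_at
  spots$A_fit <- fitted_at
  spots
}

#' Orientation adjustment for reverse arrays
#'
#' Reverse-hybridization M values (reference over test) are multiplied by -1
#' so all arrays read test over reference; forward arrays and all A values
#' are unchanged. Applying the adjustment twice to a reverse array restores
#' the original values.
#'
#' @param spots a \code{SpotMeasurements} data.frame.
#' @param orientation \code{"forward"} or \code{"reverse"}; defaults to the
#'   spots' own orientation attribute.
#' @return the spots, with M negated when orientation is reverse.
#' @export
orient_reverse <- function(spots, orientation = attr(spots, "orientation")) {
  orientation <- match.arg(orientation, c("forward", "reverse"))
  if (orientation == "reverse") spots$M <- -spots$M
  spots
}

#' Full single-array preprocessing chain
#'
#' \code{\link{quality_control}} then \code{\link{compute_m_a}} then
#' \code{\link{loess_normalize}} then \code{\link{orient_reverse}}.
#'
#' @param scan an \code{ArrayScan}.
#' @param span loess span.
#' @param qc_window,qc_outlier_frac region-QC parameters.
#' @return oriented, normalized \code{SpotMeasurements}.
#' @export
preprocess_scan <- function(scan, span = 0.3, qc_window = 10L,
                            qc_outlier_frac = 0.4) {
  scan <- quality_control(scan, window = qc_window,
                          max_outlier_frac = qc_outlier_frac)
  spots <- compute_m_a(scan)
  spots <- loess_normalize(spots, span = span)
  orient_reverse(spots)
}
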