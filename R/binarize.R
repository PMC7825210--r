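#' Otsu automatic threshold
#'
#' Selects the global threshold maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} of the intensity histogram,
#' computed from first principles over `n_bins` equal-width bins on
#' `[0, 1]`. Candidate thresholds are the interior bin edges `k / n_bins`;
#' a pixel is foreground when its intensity is `>=` the threshold. Ties are
#' broken toward the lowest qualifying threshold.
#'
#' @param img Grayscale matrix with intensities in `[0, 1]`.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold value in `(0, 1)`.
#' @examples
#' img <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10)
#' otsu_threshold(img)
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  assert_gray(img)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2L) {
    vca_stop("`n_bins` must be a single integer >= 2")
  }
  n_bins <- as.integer(n_bins)
  v <- as.vector(img)
  bins <- pmin(floor(v * n_bins) + 1L, n_bins)
  h <- tabulate(bins, n_bins)
  if (sum(h > 0L) < 2L) {
    vca_stop(paste0(
      "degenerate histogram: the image is constant (single occupied bin); ",
      "supply a manual threshold instead"))
  }
  p <- h / sum(h)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)                 # P(class 0) for threshold after bin k
  mu <- cumsum(p * centers)       # cumulative first moment
  mu_t <- mu[n_bins]
  k <- seq_len(n_bins - 1L)
  num <- (mu_t * w0[k] - mu[k])^2
  den <- w0[k] * (1 - w0[k])
  sigma_b2 <- ifelse(den > 0, num / den, -Inf)
  best <- which.max(sigma_b2)     # first maximum = lowest qualifying threshold
  best / n_bins
}

#' Binarize the extracted vascular network
#'
#' The binary vessel mask is true exactly where a pixel belongs to the
#' extracted network set *and* its intensity reaches the threshold. The
#' threshold is normally the Otsu value of the full region of interest (so
#' it does not depend on growth parameters); see [otsu_threshold()].
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param network Logical matrix marking the grown vascular network
#'   (see [extract_network()]).
#' @param threshold Intensity threshold in `[0, 1]`; foreground is `>=`.
#' @return Logical matrix (the binary microvascular mask).
#' @export
binarize_network <- function(img, network, threshold) {
  assert_gray(img)
  assert_mask(network, dim(img), arg = "network")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    vca_stop("`threshold` must be a single value in [0, 1]")
  }
  network & (img >= threshold)
}
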