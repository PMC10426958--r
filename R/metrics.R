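# Forward-backward filtering with odd-reflection end padding. Plain
# signal::filtfilt zero-pads, which rings badly against signals with a
# nonzero end level (the JR output sits around +7 mV); reflecting the signal
# about its endpoints removes the step discontinuity.
.filtfilt_padded <- function(bf, x, padlen) {
  n <- length(x)
  padlen <- max(1L, min(as.integer(padlen), n - 1L))
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), so the
#' output has no net phase shift.
#'
#' @param signals matrix (regions x samples) or numeric vector.
#' @param low,high band edges (Hz); `high` must be below Nyquist.
#' @param fs sampling rate (Hz).
#' @return filtered signals, same shape as the input.
#' @export
bandpass_filter <- function(signals, low = 8, high = 12, fs) {
  if (fs <= 2 * high) stop("band edge above Nyquist: need fs > 2 * high")
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  vec <- is.null(dim(signals))
  x <- if (vec) matrix(signals, nrow = 1) else as.matrix(signals)
  if (ncol(x) < 3 * fs / low)
    stop("signal shorter than the filter warm-up span")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  padlen <- round(3 * fs / low)  # ~3 cycles of the low edge
  y <- t(apply(x, 1, function(row) .filtfilt_padded(bf, row, padlen)))
  if (vec) drop(y) else y
}

# analytic signal via FFT (one-sided spectrum doubling)
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of band-limited signals
#'
#' Phase of the analytic signal (Hilbert convention), in (-pi, pi]. The first
#' and last second are flagged as edge regions (attribute `edge_samples`) and
#' dropped by [plv_matrix()] by default.
#'
#' @param filtered_signals matrix (regions x samples) or vector, band-limited.
#' @param fs sampling rate (Hz).
#' @return matrix of phases with attribute `edge_samples`.
#' @export
instantaneous_phase <- function(filtered_signals, fs) {
  vec <- is.null(dim(filtered_signals))
  x <- if (vec) matrix(filtered_signals, nrow = 1) else as.matrix(filtered_signals)
  if (any(apply(x, 1, stats::sd) == 0))
    stop("no oscillation: at least one signal is constant")
  ph <- t(apply(x, 1, function(row) Arg(.analytic(row))))
  if (vec) ph <- drop(ph)
  attr(ph, "edge_samples") <- round(fs)
  ph
}

#' Phase-locking-value functional connectivity
#'
#' `PLV_ij = |mean_t exp(i (phi_i(t) - phi_j(t)))|`: 1 for a constant phase
#' lag, near 0 for independent phases.
#'
#' @param phases matrix (regions x samples) of instantaneous phases, e.g. from
#'   [instantaneous_phase()].
#' @param exclude_edges drop the edge regions flagged on `phases` (or 1 s worth
#'   of samples when `fs` is given and no flag is present).
#' @param fs sampling rate, only used to infer the edge span if unflagged.
#' @param band band tag stored on the result (Hz).
#' @param labels optional region labels.
#' @return object of class `fc_matrix`: `values` (symmetric, unit diagonal,
#'   entries in \[0, 1\]), `band`, `labels`.
#' @export
plv_matrix <- function(phases, exclude_edges = TRUE, fs = NULL,
                       band = c(8, 12), labels = NULL) {
  ph <- as.matrix(phases)
  if (nrow(ph) < 2) stop("need at least 2 signals")
  edge <- attr(phases, "edge_samples")
  if (is.null(edge)) edge <- if (!is.null(fs)) round(fs) else 0
  if (exclude_edges && edge > 0) {
    if (ncol(ph) <= 2 * edge) stop("signal shorter than twice the edge span")
    ph <- ph[, (edge + 1):(ncol(ph) - edge), drop = FALSE]
  }
  z <- exp(1i * ph)
  plv <- Mod(z %*% Conj(t(z))) / ncol(ph)
  plv <- pmin(plv, 1)
  plv <- (plv + t(plv)) / 2
  diag(plv) <- 1
  dimnames(plv) <- if (!is.null(labels)) list(labels, labels)
  structure(list(values = plv, band = band, labels = labels),
            class = "fc_matrix")
}

#' Alpha-band PLV functional connectivity of a simulation
#'
#' Convenience pipeline: drop transient, band-pass, phase, PLV.
#'
#' @param sim a `jr_sim` object.
#' @param band band edges (Hz), alpha by default.
#' @return an `fc_matrix`.
#' @export
fc_from_sim <- function(sim, band = c(8, 12)) {
  x <- post_transient(sim)
  filt <- bandpass_filter(x, band[1], band[2], sim$fs)
  ph <- instantaneous_phase(filt, sim$fs)
  plv_matrix(ph, band = band, labels = sim$labels)
}

.fc_values <- function(fc) if (inherits(fc, "fc_matrix")) fc$values else as.matrix(fc)

#' Similarity between two FC matrices
#'
#' Pearson correlation between the strictly-upper-triangle entries of the two
#' matrices after restricting both to `region_mask` (e.g. cortical regions
#' only, mirroring the restriction applied to empirical MEG FC).
#'
#' @param fc_sim,fc_ref `fc_matrix` objects or plain matrices, same region set.
#' @param region_mask logical or integer index of regions to keep (default all).
#' @return Pearson r (scalar).
#' @export
fc_similarity <- function(fc_sim, fc_ref, region_mask = NULL) {
  a <- .fc_values(fc_sim); b <- .fc_values(fc_ref)
  if (!is.null(region_mask)) {
    a <- a[region_mask, region_mask, drop = FALSE]
    b <- b[region_mask, region_mask, drop = FALSE]
  }
  if (!all(dim(a) == dim(b))) stop("FC matrices differ in shape after masking")
  ut <- upper.tri(a)
  va <- a[ut]; vb <- b[ut]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant upper triangle: correlation undefined")
  stats::cor(va, vb)
}

#' Sliding-window dynamical functional connectivity
#'
#' Splits the signal into windows of `window_s` seconds with fractional
#' `overlap`, computes an alpha-band PLV matrix per window, and returns the
#' window-by-window Pearson correlations between the upper triangles of those
#' matrices. The window count is
#' `floor((T - w) / (w (1 - overlap))) + 1` for signal duration `T`.
#' Filtering and phase extraction are done once on the full signal.
#'
#' @param signals matrix (regions x samples).
#' @param fs sampling rate (Hz).
#' @param window_s window length (s).
#' @param overlap fractional overlap in \[0, 1).
#' @param band band edges (Hz).
#' @return object of class `dfc_matrix`: `values` (n_windows x n_windows,
#'   symmetric, unit diagonal), `window_s`, `overlap`, `band`.
#' @export
dfc_matrix <- function(signals, fs, window_s = 4, overlap = 0.5,
                       band = c(8, 12)) {
  x <- as.matrix(signals)
  w <- round(window_s * fs)
  if (ncol(x) < w) stop("signal shorter than one window")
  step <- round(w * (1 - overlap))
  n_win <- floor((ncol(x) - w) / step) + 1
  if (n_win < 2) stop("fewer than 2 windows")
  filt <- bandpass_filter(x, band[1], band[2], fs)
  ph <- instantaneous_phase(filt, fs)
  uts <- lapply(seq_len(n_win), function(k) {
    cols <- (1 + (k - 1) * step):((k - 1) * step + w)
    p <- plv_matrix(ph[, cols, drop = FALSE], exclude_edges = FALSE)$values
    p[upper.tri(p)]
  })
  vals <- diag(1, n_win)
  for (k in seq_len(n_win - 1))
    for (l in (k + 1):n_win)
      vals[k, l] <- vals[l, k] <- stats::cor(uts[[k]], uts[[l]])
  structure(list(values = vals, window_s = window_s, overlap = overlap,
                 band = band), class = "dfc_matrix")
}

#' Dynamical FC of a simulation
#'
#' @param sim a `jr_sim` object.
#' @param region_mask optional region subset (e.g. cortical only).
#' @param ... passed to [dfc_matrix()].
#' @return a `dfc_matrix`.
#' @export
dfc_from_sim <- function(sim, region_mask = NULL, ...) {
  x <- post_transient(sim)
  if (!is.null(region_mask)) x <- x[region_mask, , drop = FALSE]
  dfc_matrix(x, sim$fs, ...)
}

.dfc_values <- function(d) {
  m <- if (inherits(d, "dfc_matrix")) d$values else as.matrix(d)
  if (is.matrix(m) && nrow(m) == ncol(m) && isTRUE(all.equal(m, t(m))))
    m[upper.tri(m)]
  else as.numeric(m)
}

#' Kolmogorov-Smirnov distance between dFC distributions
#'
#' Two-sample KS statistic between the upper-triangle (diagonal-excluded)
#' correlation values of two dFC matrices: 0 for identical distributions, 1
#' for disjoint supports. Plain numeric vectors of correlation samples are
#' also accepted.
#'
#' @param dfc_a,dfc_b `dfc_matrix` objects or numeric samples.
#' @return KS statistic in \[0, 1\].
#' @export
ks_distance <- function(dfc_a, dfc_b) {
  a <- .dfc_values(dfc_a); b <- .dfc_values(dfc_b)
  if (length(a) == 0 || length(b) == 0) stop("empty dFC sample")
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram with 50% segment overlap, per region,
#' plus the region-averaged spectrum, its peak frequency, and band-integrated
#' areas.
#'
#' @param signals matrix (regions x samples) or vector of post-transient
#'   signals.
#' @param fs sampling rate (Hz).
#' @param segment_s Welch segment length (s); frequency resolution is
#'   `1/segment_s`.
#' @param bands named list of `c(low, high)` bands to integrate (Hz).
#' @return list: `freq`, `psd` (regions x freqs), `avg_psd`, `peak_freq`
#'   (argmax of the region-averaged spectrum), `peak_freq_per_node`,
#'   `band_area` (regions x bands), `total_area` (per region).
#' @export
spectral_summary <- function(signals, fs, segment_s = 4,
                             bands = list(alpha = c(8, 12))) {
  x <- if (is.null(dim(signals))) matrix(signals, nrow = 1) else as.matrix(signals)
  nseg <- min(round(segment_s * fs), ncol(x))
  if (ncol(x) < nseg || nseg < 8) stop("signal shorter than one Welch segment")
  step <- max(1, floor(nseg / 2))
  starts <- seq(1, ncol(x) - nseg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  wnorm <- sum(win^2)
  nf <- floor(nseg / 2) + 1
  freq <- (seq_len(nf) - 1) * fs / nseg
  psd <- t(apply(x, 1, function(row) {
    acc <- numeric(nf)
    for (s in starts) {
      seg <- (row[s:(s + nseg - 1)] - mean(row[s:(s + nseg - 1)])) * win
      P <- Mod(stats::fft(seg))^2 / (fs * wnorm)
      half <- P[seq_len(nf)]
      half[2:(nf - 1)] <- 2 * half[2:(nf - 1)]
      acc <- acc + half
    }
    acc / length(starts)
  }))
  avg <- colMeans(psd)
  df <- freq[2] - freq[1]
  band_area <- sapply(bands, function(b) {
    sel <- freq >= b[1] & freq <= b[2]
    rowSums(psd[, sel, drop = FALSE]) * df
  })
  if (is.null(dim(band_area))) band_area <- matrix(band_area, nrow = nrow(x))
  colnames(band_area) <- names(bands)
  list(freq = freq, psd = psd, avg_psd = avg,
       peak_freq = freq[which.max(avg)],
       peak_freq_per_node = freq[apply(psd, 1, which.max)],
       band_area = band_area,
       total_area = rowSums(psd) * df)
}

#' Signal-to-noise ratio of driven nodes
#'
#' Post-transient half peak-to-peak amplitude `(max - min)/2` per node,
#' averaged over `node_set`, divided by the noise standard deviation `eta`.
#'
#' @param signals matrix (regions x samples) of post-transient signals (mV).
#' @param eta noise standard deviation of the nodes in `node_set` (ms^-1),
#'   strictly positive.
#' @param node_set integer or logical index of nodes to average over.
#' @return scalar SNR.
#' @export
snr <- function(signals, eta, node_set = seq_len(nrow(signals))) {
  if (length(eta) != 1 || eta <= 0) stop("SNR undefined: eta must be > 0")
  x <- as.matrix(signals)[node_set, , drop = FALSE]
  amp <- (apply(x, 1, max) - apply(x, 1, min)) / 2
  mean(amp) / eta
}

#' Relative spectral power between two node groups
#'
#' Mean total PSD area over `cortical_set` divided by the mean total PSD area
#' over `driver_set`.
#'
#' @param spectra a [spectral_summary()] result.
#' @param cortical_set,driver_set non-empty node index sets.
#' @return scalar power ratio.
#' @export
relative_power <- function(spectra, cortical_set, driver_set) {
  if (length(cortical_set) == 0 || length(driver_set) == 0)
    stop("node sets must be non-empty")
  mean(spectra$total_area[cortical_set]) / mean(spectra$total_area[driver_set])
}
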