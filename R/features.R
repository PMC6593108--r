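#' Sliding-window specification
#'
#' Analysis windows for the LDA pathway: 150 ms windows with 100 ms overlap
#' (50 ms step) by default. Window length in samples is
#' \code{round(length_ms * rate_hz / 1000)}.
#'
#' @param length_ms Window length, ms.
#' @param overlap_ms Overlap between consecutive windows, ms
#'   (0 <= overlap < length).
#' @param rate_hz Sampling rate.
#' @return An object of class \code{window_spec}.
#' @export
window_spec <- function(length_ms = 150, overlap_ms = 100, rate_hz = 1000) {
  if (overlap_ms < 0 || overlap_ms >= length_ms) {
    stop("overlap_ms must satisfy 0 <= overlap_ms < length_ms")
  }
  structure(list(length_ms = length_ms, overlap_ms = overlap_ms,
                 rate_hz = rate_hz,
                 length_n = round(length_ms * rate_hz / 1000),
                 step_n = round((length_ms - overlap_ms) * rate_hz / 1000)),
            class = "window_spec")
}

#' Enumerate sliding windows
#'
#' Half-open sample-index intervals [start, end) with step
#' \code{length - overlap}; a trailing partial window is dropped.
#'
#' @param n_samples Signal length in samples (>= window length).
#' @param spec A \code{\link{window_spec}}.
#' @return Two-column integer matrix of 1-based \code{start} and (exclusive)
#'   \code{end} indices; \code{end - start} equals the window length.
#' @examples
#' w <- sliding_windows(2000, window_spec())  # 38 windows: starts 1, 51, ...
#' nrow(w)
#' @export
sliding_windows <- function(n_samples, spec) {
  L <- spec$length_n
  if (n_samples < L) stop("signal shorter than one analysis window")
  starts <- seq.int(1L, n_samples - L + 1L, by = spec$step_n)
  cbind(start = starts, end = starts + L)
}

#' Time-domain feature vector of one window
#'
#' The five features used by the LDA classifiers, computed on a single
#' channel's window: mean absolute value
#' \eqn{MAV = \frac{1}{N}\sum |x_i|}, root mean square
#' \eqn{RMS = \sqrt{\frac{1}{N}\sum x_i^2}}, slope sign changes
#' \eqn{SSC = \#\{i : (x_i - x_{i-1})(x_i - x_{i+1}) > \epsilon\}},
#' waveform length \eqn{WL = \sum |x_{i+1} - x_i|}, and the population
#' variance \eqn{\sigma^2 = \frac{1}{N}\sum (x_i - \bar x)^2}.
#'
#' @param x Numeric vector (one channel's window; length >= 3 for SSC).
#' @param ssc_epsilon SSC slope-product threshold (default 0; envelopes are
#'   already low-noise after the hardware filtering).
#' @return Named numeric vector \code{(mav, rms, ssc, wl, var)}.
#' @examples
#' td_feature_vector(c(1, -1, 1, -1))  # MAV 1, RMS 1, SSC 2, WL 6, VAR 1
#' @export
td_feature_vector <- function(x, ssc_epsilon = 0) {
  n <- length(x)
  if (n == 0L) stop("empty window")
  mav <- mean(abs(x))
  rms <- sqrt(mean(x^2))
  d <- diff(x)
  wl <- sum(abs(d))
  v <- mean((x - mean(x))^2)
  ssc <- if (n >= 3L) sum(-d[-length(d)] * d[-1] > ssc_epsilon) else 0
  c(mav = mav, rms = rms, ssc = ssc, wl = wl, var = v)
}

#' Extract the windowed feature matrix of a session
#'
#' Slides the analysis window over the multi-channel signal and computes the
#' five time-domain features per channel, concatenated channel-by-channel in
#' the fixed order (MAV, RMS, SSC, WL, VAR), giving 5 x channels columns.
#' Each window receives the majority per-sample label; windows whose majority
#' label covers less than \code{purity} of the samples (transition windows)
#' are discarded.
#'
#' Implementation note: features are computed from channel-wise cumulative
#' sums, so the cost is linear in the signal length rather than in
#' windows x window length.
#'
#' @param samples Numeric matrix (samples x channels).
#' @param spec A \code{\link{window_spec}}.
#' @param labels Per-sample label vector (e.g. the joint gesture/force
#'   label), or NULL to skip labelling.
#' @param ssc_epsilon SSC threshold.
#' @param purity Minimum majority share for a window to be kept.
#' @return An object of class \code{feature_matrix}: \code{features}
#'   (windows x (5 x channels)), \code{w_start} (1-based window starts),
#'   \code{label} (majority labels), \code{ssc_epsilon}.
#' @export
extract_features <- function(samples, spec, labels = NULL,
                             ssc_epsilon = 0, purity = 0.75) {
  samples <- as.matrix(samples)
  win <- sliding_windows(nrow(samples), spec)
  L <- spec$length_n
  nch <- ncol(samples)
  nwin <- nrow(win)
  s <- win[, "start"]; e <- win[, "end"] - 1L

  feat <- matrix(0, nrow = nwin, ncol = 5L * nch)
  fnames <- c("mav", "rms", "ssc", "wl", "var")
  colnames(feat) <- as.vector(t(outer(paste0("ch", seq_len(nch)),
                                      fnames, paste, sep = "_")))
  for (c_ in seq_len(nch)) {
    x <- samples[, c_]
    cs_abs <- c(0, cumsum(abs(x)))
    cs_sq <- c(0, cumsum(x^2))
    cs_x <- c(0, cumsum(x))
    d <- diff(x)
    cs_wl <- c(0, 0, cumsum(abs(d)))             # WL of window [s, e]
    ssc_ind <- c(0, -d[-length(d)] * d[-1] > ssc_epsilon, 0)
    cs_ssc <- c(0, cumsum(ssc_ind))              # SSC at interior points

    mav <- (cs_abs[e + 1L] - cs_abs[s]) / L
    msq <- (cs_sq[e + 1L] - cs_sq[s]) / L
    mu <- (cs_x[e + 1L] - cs_x[s]) / L
    wl <- cs_wl[e + 1L] - cs_wl[s + 1L]
    ssc <- cs_ssc[e] - cs_ssc[s + 1L]            # interior samples s+1 .. e-1
    base <- (c_ - 1L) * 5L
    feat[, base + 1L] <- mav
    feat[, base + 2L] <- sqrt(msq)
    feat[, base + 3L] <- ssc
    feat[, base + 4L] <- wl
    feat[, base + 5L] <- pmax(0, msq - mu^2)
  }

  lab <- NULL
  keep <- rep(TRUE, nwin)
  if (!is.null(labels)) {
    lab <- character(nwin)
    for (w in seq_len(nwin)) {
      tab <- table(labels[s[w]:e[w]])
      lab[w] <- names(tab)[which.max(tab)]
      keep[w] <- max(tab) / L >= purity
    }
    lab <- lab[keep]
  }
  if (!any(keep)) stop("all windows discarded by the label-purity rule")
  structure(list(features = feat[keep, , drop = FALSE],
                 w_start = win[keep, "start"],
                 label = lab,
                 ssc_epsilon = ssc_epsilon),
            class = "feature_matrix")
}

#' Write a feature matrix as CSV
#'
#' Header: \code{w_start, ch<c>_<mav|rms|ssc|wl|var>..., label}.
#'
#' @param fm A \code{feature_matrix}.
#' @param path Output path.
#' @export
write_features_csv <- function(fm, path) {
  df <- data.frame(w_start = fm$w_start - 1L, fm$features,
                   check.names = FALSE)
  if (!is.null(fm$label)) df$label <- fm$label
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
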