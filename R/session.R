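#' Generate a labeled synthetic acquisition session
#'
#' Simulates one subject's recording under the acquisition protocol: every
#' gesture is produced \code{repetitions_per_gesture} times and held for
#' \code{hold_duration_s} seconds, with rest intervals between repetitions.
#' Rest intervals are generated and then trimmed, so the stored session is the
#' concatenation of the hold segments only (84000 rows x 6 channels under the
#' default protocol). Spherical and Tip repetitions cycle through the force
#' levels Low, Medium, High (twice each over 6 repetitions); during those
#' holds the FSR voltage block is non-zero and encodes a grasp-force sum
#' tracking the centre of the corresponding force band.
#'
#' Envelope model: per-channel amplitude = activation pattern x force gain
#' (grasps only) x trapezoidal ramp, plus Gaussian AR(1) noise with marginal
#' sd \code{noise_sd} and time constant \code{noise_tau_s} (band-limited, as
#' the output of the sensors' low-pass smoothing stage), clipped at zero
#' (envelopes are rectified signals).
#'
#' @param protocol A \code{\link{session_protocol}}.
#' @param model A \code{\link{make_subject_model}} subject model.
#' @param seed Integer seed; a fixed (protocol, model, seed) triple reproduces
#'   a byte-identical session. Sub-streams are split by (gesture, repetition).
#' @param subject_id Identifier stored with the session.
#' @param calibration FSR calibration used (inverted) to synthesise voltages;
#'   defaults to the identity polynomial.
#'
#' @return An object of class \code{emg_session}: \code{samples}
#'   (n x channels), \code{fsr_volts} (n x fsr_count), \code{rate_hz},
#'   \code{gesture_label} and \code{force_label} (per-sample; force level is
#'   \code{"none"} outside Spherical/Tip holds), \code{subject_id}.
#' @examples
#' p <- session_protocol(rate_hz = 100)  # reduced rate for a quick example
#' m <- make_subject_model(1, 0.1, seed = 1)
#' s <- generate_session(p, m, seed = 2)
#' nrow(s$samples)  # 7 gestures x 6 reps x 2 s x 100 Hz = 8400
#' @export
generate_session <- function(protocol, model, seed, subject_id = "S01",
                             calibration = fsr_calibration()) {
  stopifnot(inherits(protocol, "session_protocol"),
            inherits(model, "subject_model"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  rate <- protocol$rate_hz
  hold_n <- round(protocol$hold_duration_s * rate)
  rest_n <- round(protocol$inter_rest_s * rate)
  reps <- protocol$repetitions_per_gesture
  nch <- protocol$channels
  nfsr <- protocol$fsr_count
  band <- force_band_spec(max_force_sum = model$max_force_N)

  n_seg <- length(protocol$gestures) * reps
  # sub-stream seeds split by (gesture, repetition): envelope, fsr, rest
  seg_seeds <- matrix(sample.int(.Machine$integer.max, 3L * n_seg),
                      nrow = n_seg, ncol = 3L)

  blocks <- vector("list", n_seg)
  seg <- 0L
  for (g in protocol$gestures) {
    grasp <- g %in% GRASP_GESTURES
    for (r in seq_len(reps)) {
      seg <- seg + 1L
      level <- if (grasp) {
        protocol$force_levels[((r - 1L) %% length(protocol$force_levels)) + 1L]
      } else "none"
      gain <- if (grasp) model$force_gain[[level]] else 1
      amp <- model$activation_pattern[g, seq_len(nch)] * gain

      set.seed(seg_seeds[seg, 1L])
      ramp <- .trapezoid(hold_n, model$ramp_ms, rate)
      env <- outer(ramp, amp)
      if (model$noise_sd > 0) {
        env <- env + .envelope_noise(hold_n, nch, model, rate)
      }
      env[env < 0] <- 0

      fsr <- if (grasp) {
        generate_force_trace(level, band, protocol$hold_duration_s, rate,
                             model, seed = seg_seeds[seg, 2L],
                             calibration = calibration)
      } else {
        matrix(0, nrow = hold_n, ncol = nfsr)
      }

      # rest interval: generated, then trimmed from the stored session
      set.seed(seg_seeds[seg, 3L])
      if (rest_n > 0 && model$noise_sd > 0) {
        rest <- .envelope_noise(rest_n, nch, model, rate)
        rest[rest < 0] <- 0   # generated for protocol fidelity; not stored
      }

      blocks[[seg]] <- list(env = env, fsr = fsr, gesture = g, level = level)
    }
  }

  samples <- do.call(rbind, lapply(blocks, `[[`, "env"))
  fsr_volts <- do.call(rbind, lapply(blocks, `[[`, "fsr"))
  gesture_label <- rep(vapply(blocks, `[[`, "", "gesture"), each = hold_n)
  force_label <- rep(vapply(blocks, `[[`, "", "level"), each = hold_n)
  colnames(samples) <- paste0("ch", seq_len(nch))
  colnames(fsr_volts) <- paste0("fsr", seq_len(nfsr))

  structure(list(samples = samples,
                 fsr_volts = fsr_volts,
                 rate_hz = rate,
                 gesture_label = gesture_label,
                 force_label = force_label,
                 subject_id = subject_id),
            class = "emg_session")
}

# band-limited Gaussian envelope noise: AR(1) per channel, marginal sd
# model$noise_sd, time constant model$noise_tau_s (0 -> white)
.envelope_noise <- function(n, nch, model, rate_hz) {
  sd <- model$noise_sd
  tau <- if (is.null(model$noise_tau_s)) 0 else model$noise_tau_s
  if (n == 0L || sd == 0) return(matrix(0, n, nch))
  phi <- if (tau > 0) exp(-1 / (tau * rate_hz)) else 0
  if (phi == 0) {
    return(matrix(stats::rnorm(n * nch, sd = sd), nrow = n))
  }
  x0 <- stats::rnorm(nch, sd = sd)                 # stationary start
  eps <- matrix(stats::rnorm(n * nch, sd = sd * sqrt(1 - phi^2)), nrow = n)
  out <- matrix(0, n, nch)
  for (c_ in seq_len(nch)) {
    out[, c_] <- as.numeric(stats::filter(eps[, c_], phi,
                                          method = "recursive",
                                          init = x0[c_]))
  }
  out
}

# trapezoidal 0->1->0 activation profile over n samples
.trapezoid <- function(n, ramp_ms, rate_hz) {
  if (n == 0L) return(numeric(0))
  ramp_n <- max(1L, round(ramp_ms / 1000 * rate_hz))
  i <- seq_len(n)
  pmin(1, i / ramp_n, (n - i + 1) / ramp_n)
}

#' Synthesise an FSR voltage block for one grasp hold
#'
#' Produces a per-sensor FSR voltage trace whose calibrated force sum tracks
#' the centre of the requested force band (30/60/90% of the subject's maximum
#' force sum for Low/Medium/High) with a trapezoidal onset/offset and a slow
#' wander emulating the subject's tracking error under visual feedback
#' (stationary sd 2% of the maximum force sum). Each sensor carries the
#' proportion of the force sum given by \code{model$fsr_share}; voltages are
#' obtained by inverting \code{calibration} on [0, 5] V.
#'
#' @param level One of \code{"Low"}, \code{"Medium"}, \code{"High"}.
#' @param band_spec A \code{\link{force_band_spec}}.
#' @param duration_s Trace duration, seconds (0 gives an empty block).
#' @param rate_hz Sampling rate.
#' @param model A subject model (uses \code{fsr_share}, \code{ramp_ms}).
#' @param seed Integer seed.
#' @param calibration FSR calibration to invert (default identity).
#' @return Matrix (samples x sensors) of voltages, with attribute
#'   \code{"plateau"} marking the full-amplitude samples.
#' @export
generate_force_trace <- function(level, band_spec, duration_s, rate_hz,
                                 model, seed,
                                 calibration = fsr_calibration()) {
  if (!level %in% FORCE_LEVELS) stop("unknown force level: ", level)
  n <- round(duration_s * rate_hz)
  nfsr <- length(model$fsr_share)
  if (n == 0L) {
    out <- matrix(0, nrow = 0L, ncol = nfsr)
    attr(out, "plateau") <- logical(0)
    return(out)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  target <- c(Low = 0.30, Medium = 0.60, High = 0.90)[[level]]
  ramp <- .trapezoid(n, model$ramp_ms, rate_hz)

  # slow AR(1) wander, stationary sd = 2% of max force sum
  phi <- 0.99
  z <- numeric(n)
  eps <- stats::rnorm(n, sd = 0.02 * sqrt(1 - phi^2))
  z[1] <- stats::rnorm(1, sd = 0.02)
  for (i in seq_len(n - 1L)) z[i + 1L] <- phi * z[i] + eps[i + 1L]

  frac <- pmin(1, pmax(0, (target + z) * ramp))
  force_sum <- frac * band_spec$max_force_sum
  force <- outer(force_sum, model$fsr_share)
  volts <- matrix(fsr_invert(as.vector(force), calibration), nrow = n)
  attr(volts, "plateau") <- ramp >= 1
  volts
}

#' @export
print.emg_session <- function(x, ...) {
  cat("emg_session:", x$subject_id, "\n")
  cat(sprintf("  %d samples x %d channels at %g Hz (%g s)\n",
              nrow(x$samples), ncol(x$samples), x$rate_hz,
              nrow(x$samples) / x$rate_hz))
  cat("  gestures:", paste(unique(x$gesture_label), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write sessions as CSV
#'
#' Column layout: \code{t_s, ch1..chC, fsr1..fsrF, gesture, force_level,
#' subject_id}, one row per sample; \code{force_level} is empty outside
#' grasps. The round trip is lossless for labels and accurate to well below
#' 1e-9 for floating-point values.
#'
#' @param session An \code{emg_session}.
#' @param path Output CSV path.
#' @export
write_session_csv <- function(session, path) {
  n <- nrow(session$samples)
  df <- data.frame(t_s = (seq_len(n) - 1) / session$rate_hz,
                   session$samples,
                   session$fsr_volts,
                   gesture = session$gesture_label,
                   force_level = ifelse(session$force_label == "none", "",
                                        session$force_label),
                   subject_id = session$subject_id,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  fsr_cols <- grep("^fsr[0-9]+$", names(df), value = TRUE)
  rate <- if (nrow(df) > 1) round(1 / (df$t_s[2] - df$t_s[1])) else 1000
  force <- as.character(df$force_level)
  force[is.na(force) | force == ""] <- "none"
  structure(list(samples = as.matrix(df[ch_cols]),
                 fsr_volts = as.matrix(df[fsr_cols]),
                 rate_hz = rate,
                 gesture_label = as.character(df$gesture),
                 force_label = force,
                 subject_id = as.character(df$subject_id[1])),
            class = "emg_session")
}
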