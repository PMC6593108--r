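#' Gesture and force-level vocabularies
#'
#' The seven hand/wrist motion classes decoded by the system, in canonical
#' order, and the three grasp-force levels. \code{GRASP_GESTURES} are the two
#' classes for which a force classifier is activated.
#'
#' @format Character vectors.
#' @export
GESTURES <- c("Rest", "Spherical", "Tip", "Platform", "Point",
              "Wrist supination", "Wrist pronation")

#' @rdname GESTURES
#' @export
FORCE_LEVELS <- c("Low", "Medium", "High")

#' @rdname GESTURES
#' @export
GRASP_GESTURES <- c("Spherical", "Tip")

#' Acquisition-session protocol
#'
#' Describes the recording schedule: each of the seven gestures is produced
#' \code{repetitions_per_gesture} times, held for \code{hold_duration_s}
#' seconds, with \code{inter_rest_s} seconds of relaxed rest between
#' repetitions. The defaults reproduce the study protocol: 6 repetitions of
#' 2 s holds at 1 kHz over 6 envelope channels and 5 FSR sensors, giving
#' 7 x 6 x 2000 = 84000 hold samples per session. The two grasping gestures
#' (Spherical, Tip) cycle through the three force levels across their
#' repetitions.
#'
#' @param gestures Character vector of the 7 gesture names (each exactly once).
#' @param repetitions_per_gesture Repetitions of each gesture (>= 1).
#' @param hold_duration_s Hold duration per repetition, seconds.
#' @param inter_rest_s Rest interval between repetitions, seconds (generated,
#'   then trimmed from the stored session).
#' @param rate_hz Sampling rate, samples per second.
#' @param channels Number of sEMG envelope channels.
#' @param fsr_count Number of force-sensitive resistors on the glove.
#' @param force_levels Force levels applied to the grasping gestures.
#'
#' @return An object of class \code{session_protocol}.
#' @examples
#' p <- session_protocol()
#' p$rate_hz * p$hold_duration_s * p$repetitions_per_gesture * 7  # 84000
#' @export
session_protocol <- function(gestures = GESTURES,
                             repetitions_per_gesture = 6,
                             hold_duration_s = 2,
                             inter_rest_s = 2,
                             rate_hz = 1000,
                             channels = 6,
                             fsr_count = 5,
                             force_levels = FORCE_LEVELS) {
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (repetitions_per_gesture < 1) stop("repetitions_per_gesture must be >= 1")
  if (length(gestures) != 7L || anyDuplicated(gestures) ||
      !setequal(gestures, GESTURES)) {
    stop("gestures must contain exactly the 7 canonical gesture names, each once")
  }
  structure(list(gestures = gestures,
                 repetitions_per_gesture = as.integer(repetitions_per_gesture),
                 hold_duration_s = hold_duration_s,
                 inter_rest_s = inter_rest_s,
                 rate_hz = rate_hz,
                 channels = as.integer(channels),
                 fsr_count = as.integer(fsr_count),
                 force_levels = force_levels),
            class = "session_protocol")
}

#' Synthetic subject model
#'
#' Generates the per-subject parameters of the envelope model: a 7 x channels
#' matrix of mean envelope amplitudes (one row per gesture; the Rest row is
#' zero — a relaxed muscle produces only noise), force-level gain multipliers
#' applied to the grasping gestures, envelope noise, trapezoidal onset/offset
#' ramps, the subject's maximum grasp-force sum and the division of that force
#' across the FSR sensors.
#'
#' Each non-rest gesture is given a dominant channel plus small random
#' co-activation on the remaining channels, so pairwise distances between
#' gesture activation rows scale linearly with \code{separation}.
#'
#' @param separation Pattern-distance scale (> 0); amplitudes are proportional
#'   to it, in envelope units.
#' @param noise_sd Envelope noise standard deviation (>= 0), envelope units.
#'   Envelope noise is temporally correlated (Gaussian AR(1) with marginal sd
#'   \code{noise_sd}): an envelope is the output of the sensor's low-pass
#'   smoothing stage, so its noise is band-limited, not white at the sampling
#'   rate.
#' @param noise_tau_s Envelope-noise correlation time constant, seconds
#'   (default 0.05, the smoothing time scale of commercial envelope sensors;
#'   0 gives white noise).
#' @param seed Integer seed; the model is deterministic given the seed.
#' @param channels Number of envelope channels.
#' @param ramp_ms Trapezoidal onset/offset ramp duration, ms.
#' @param max_force_N Subject maximum grasp-force sum, newtons.
#' @param fsr_count Number of FSR sensors.
#'
#' @return An object of class \code{subject_model} with fields
#'   \code{activation_pattern}, \code{force_gain}, \code{noise_sd},
#'   \code{ramp_ms}, \code{max_force_N}, \code{fsr_share}.
#' @examples
#' m <- make_subject_model(separation = 1, noise_sd = 0.1, seed = 1)
#' rowSums(m$activation_pattern)
#' @export
make_subject_model <- function(separation, noise_sd, seed,
                               channels = 6,
                               ramp_ms = 100,
                               max_force_N = 10,
                               fsr_count = 5,
                               noise_tau_s = 0.05) {
  if (!is.numeric(separation) || separation <= 0) {
    stop("separation must be positive")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  pattern <- matrix(0, nrow = 7, ncol = channels,
                    dimnames = list(GESTURES, paste0("ch", seq_len(channels))))
  # non-rest gestures: dominant channel (cycled) + weak co-activation
  nonrest <- setdiff(GESTURES, "Rest")
  for (i in seq_along(nonrest)) {
    row <- stats::runif(channels, min = 0.05, max = 0.30)
    dom <- ((i - 1L) %% channels) + 1L
    row[dom] <- stats::runif(1, min = 0.9, max = 1.1)
    pattern[nonrest[i], ] <- separation * row
  }

  share <- stats::runif(fsr_count, min = 0.5, max = 1.5)
  share <- share / sum(share)

  structure(list(activation_pattern = pattern,
                 force_gain = c(Low = 0.5, Medium = 1.0, High = 1.5),
                 noise_sd = noise_sd,
                 noise_tau_s = noise_tau_s,
                 ramp_ms = ramp_ms,
                 max_force_N = max_force_N,
                 fsr_share = share,
                 seed = as.integer(seed)),
            class = "subject_model")
}

# save/restore the global RNG state so seeded generators do not clobber
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
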