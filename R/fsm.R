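#' Classifier roles active in a given FSM state
#'
#' The gesture classifier is always active; the Spherical force classifier is
#' active exactly when the machine is in the Spherical state, and the Tip
#' force classifier exactly in the Tip state. In every other state no force
#' classifier runs, so at most one force classifier is ever active.
#'
#' @param state Current gesture state (one of the 7 gesture names).
#' @return Character vector of roles among \code{"gesture"},
#'   \code{"spherical_force"}, \code{"tip_force"}.
#' @examples
#' active_classifiers("Rest")       # "gesture"
#' active_classifiers("Spherical")  # "gesture", "spherical_force"
#' @export
active_classifiers <- function(state) {
  if (!state %in% GESTURES) stop("unknown state: ", state)
  c("gesture",
    if (state == "Spherical") "spherical_force",
    if (state == "Tip") "tip_force")
}

#' One FSM transition
#'
#' The machine holds exactly one gesture state; the gesture decision at each
#' tick moves it there directly (all transitions are allowed). The output
#' carries a force level only in the Spherical/Tip states, and the force
#' decision is consumed on the same tick only when the machine was already
#' in that state before the tick (the force classifier is activated by the
#' state, so its first usable output comes one tick after entry). Supplying
#' a force decision when the previous state did not activate a force
#' classifier is an error.
#'
#' @param state Gesture state before the tick.
#' @param gesture_decision Output of the gesture classifier at this tick.
#' @param force_decision Output of the active force classifier at this tick,
#'   or NULL when no force classifier was active.
#' @return List with \code{state} (new state) and \code{output}
#'   (list \code{gesture}, \code{force}; force is \code{"none"} outside
#'   grasp states and on entry ticks).
#' @export
fsm_step <- function(state, gesture_decision, force_decision = NULL) {
  if (!state %in% GESTURES) stop("unknown state: ", state)
  if (!gesture_decision %in% GESTURES) {
    stop("unknown gesture decision: ", gesture_decision)
  }
  expects_force <- state %in% GRASP_GESTURES
  if (!expects_force && !is.null(force_decision)) {
    stop("force decision supplied while no force classifier was active")
  }
  new_state <- gesture_decision
  force <- "none"
  if (new_state %in% GRASP_GESTURES && new_state == state &&
      !is.null(force_decision)) {
    force <- force_decision
  }
  list(state = new_state,
       output = list(gesture = new_state, force = force))
}

#' Decode a stream through the hierarchical FSM
#'
#' Replays an input stream (per-sample rows for the NLR cadence, per-window
#' feature rows for the LDA cadence — the FSM is cadence-agnostic) through
#' the gesture classifier and, whenever the machine sits in the Spherical or
#' Tip state, through the corresponding force classifier. The initial state
#' is Rest. Optional majority-vote smoothing over the last \code{smooth_k}
#' gesture decisions (ties to the most recent decision) can suppress
#' isolated misclassifications; it is off by default (\code{smooth_k = 1}).
#'
#' @param gesture_model,spherical_model,tip_model Fitted models sharing the
#'   stream's input representation; each must work with
#'   \code{\link{predict_nlr}} or \code{\link{predict_lda}}. The force
#'   models may be NULL, in which case grasp states emit force
#'   \code{"none"}.
#' @param X Input stream, one observation per row (already in the models'
#'   input space: scaled channels for NLR, feature rows for LDA).
#' @param smooth_k Majority-vote window over gesture decisions (1 = off).
#' @return A data frame with columns \code{tick}, \code{gesture},
#'   \code{force_level}.
#' @export
decode_stream <- function(gesture_model, spherical_model = NULL,
                          tip_model = NULL, X, smooth_k = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  g_raw <- .model_predict(gesture_model, X)
  g <- if (smooth_k > 1L) .majority_smooth(g_raw, smooth_k) else g_raw

  sph <- if (!is.null(spherical_model)) .model_predict(spherical_model, X)
  tip <- if (!is.null(tip_model)) .model_predict(tip_model, X)

  # vectorised FSM replay: state after tick t is the (smoothed) decision at
  # t; the force output at t is consumed only when the previous state
  # already was the same grasp state
  prev <- c("Rest", g[-n])
  force <- rep("none", n)
  use_sph <- g == "Spherical" & prev == "Spherical"
  use_tip <- g == "Tip" & prev == "Tip"
  if (!is.null(sph)) force[use_sph] <- sph[use_sph]
  if (!is.null(tip)) force[use_tip] <- tip[use_tip]

  data.frame(tick = seq_len(n), gesture = g, force_level = force,
             stringsAsFactors = FALSE)
}

.model_predict <- function(model, X) {
  if (inherits(model, "nlr_model")) predict_nlr(model, X)$label
  else if (inherits(model, "lda_model")) predict_lda(model, X)$label
  else stop("unsupported model class: ", paste(class(model), collapse = "/"))
}

# majority vote over the trailing k decisions; ties go to the most recent
.majority_smooth <- function(labels, k) {
  n <- length(labels)
  out <- character(n)
  for (i in seq_len(n)) {
    w <- labels[max(1L, i - k + 1L):i]
    tab <- table(w)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (length(top) == 1L) top else {
      # most recent decision among the tied labels
      w[max(which(w %in% top))]
    }
  }
  out
}

#' Write a decoded stream as CSV
#'
#' Columns: \code{tick, t_s, gesture, force_level}.
#'
#' @param decoded Data frame from \code{\link{decode_stream}}.
#' @param rate_hz Decision cadence used to derive \code{t_s}.
#' @param path Output path.
#' @export
write_decoded_csv <- function(decoded, rate_hz, path) {
  df <- data.frame(tick = decoded$tick,
                   t_s = (decoded$tick - 1) / rate_hz,
                   gesture = decoded$gesture,
                   force_level = decoded$force_level)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
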