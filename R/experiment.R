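#' Experiment configuration
#'
#' Bundles every tunable of the end-to-end multi-subject experiment: the
#' acquisition protocol, the synthetic subject population, preprocessing
#' (downsampling step and split fractions), the NLR hyperparameter grid,
#' the LDA windowing, and the evaluation settings. Defaults reproduce the
#' study conditions: 31 subjects, 84000-sample sessions, step-10
#' downsampling with a 60/20/20 three-way split of the kept data, a
#' 70/30 two-way split of the feature windows, and Wilcoxon comparison at
#' alpha = 0.05.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param seed Master seed; every stage's randomness derives from it.
#' @param protocol A \code{\link{session_protocol}}.
#' @param separation,noise_sd Subject-model population parameters.
#' @param step Downsampling step (kept data feed the three-way split; the
#'   discarded 90% form the Generalization Set).
#' @param fractions TR/CVS/TS fractions of the kept data.
#' @param train_frac LDA-pathway training fraction of the feature windows.
#' @param nlr_grid Data frame of NLR configurations (\code{degree},
#'   \code{TH}).
#' @param nlr_max_iter RProp iteration budget.
#' @param window \code{\link{window_spec}} arguments (list with
#'   \code{length_ms}, \code{overlap_ms}).
#' @param ssc_epsilon,purity Feature-extraction settings.
#' @param smooth_k FSM majority-smoothing window (1 = off).
#' @param alpha Wilcoxon significance threshold.
#' @return A list of class \code{experiment_config}.
#' @export
experiment_config <- function(n_subjects = 31L,
                              seed = 1L,
                              protocol = session_protocol(),
                              separation = 1.0,
                              noise_sd = 0.1,
                              step = 10L,
                              fractions = c(0.6, 0.2, 0.2),
                              train_frac = 0.7,
                              nlr_grid = data.frame(degree = 1:3, TH = 0.5),
                              nlr_max_iter = 300L,
                              window = list(length_ms = 150, overlap_ms = 100),
                              ssc_epsilon = 0,
                              purity = 0.75,
                              smooth_k = 1L,
                              alpha = 0.05) {
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 protocol = protocol, separation = separation,
                 noise_sd = noise_sd, step = as.integer(step),
                 fractions = fractions, train_frac = train_frac,
                 nlr_grid = nlr_grid, nlr_max_iter = as.integer(nlr_max_iter),
                 window = window, ssc_epsilon = ssc_epsilon, purity = purity,
                 smooth_k = as.integer(smooth_k), alpha = alpha),
            class = "experiment_config")
}

.CLASSIFIERS <- c("gesture", "spherical_force", "tip_force")

# joint stratification label: gesture for non-grasps, gesture|level for grasps
.joint_label <- function(gesture, force) {
  ifelse(force == "none", gesture, paste(gesture, force, sep = "|"))
}

#' Run the full protocol on one synthetic subject
#'
#' Generates a session, then runs both classification pathways: the NLR path
#' (per-channel scaling fitted on TR, step-10 downsampling, stratified
#' three-way split of the kept samples, one-vs-all NLR with grid selection
#' on CVS, tested on TS and on the Generalization Set) and the LDA path
#' (time-domain features on 150/100 ms windows of the full-rate scaled
#' signal, stratified 70/30 split, one-vs-all LDA tested on TS). The three
#' classifiers — gesture, Spherical force, Tip force — are trained per the
#' hierarchy: the gesture training data include the grasps at all three
#' force levels; each force classifier sees only its gesture's samples.
#' Finally the GS stream is replayed through the FSM.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param subject_index Subject number (used for the id and seed stream).
#' @param seeds Integer vector of at least 4 stage seeds (model, session,
#'   splits, training).
#' @return List with per-classifier/per-algorithm confusion matrices and
#'   metrics, the selected NLR configurations, and FSM replay summaries.
#' @export
run_subject <- function(config, subject_index, seeds) {
  protocol <- config$protocol
  model <- make_subject_model(config$separation, config$noise_sd,
                              seed = seeds[1],
                              channels = protocol$channels,
                              fsr_count = protocol$fsr_count)
  session <- generate_session(protocol, model, seed = seeds[2],
                              subject_id = sprintf("S%02d", subject_index))
  gesture <- session$gesture_label
  n <- nrow(session$samples)

  # force supervision comes from the measured FSR bands (that is what the
  # visual-feedback bands are for): calibrated force sum -> Low/Medium/High,
  # with sub-band samples labeled none and excluded from the force
  # classifiers' train/test sets
  band_spec <- force_band_spec(max_force_sum = model$max_force_N)
  force_sum <- rowSums(matrix(fsr_to_force(as.vector(session$fsr_volts),
                                           fsr_calibration()),
                              nrow = n))
  band <- band_label(force_sum, band_spec)
  band[!gesture %in% GRASP_GESTURES] <- "none"
  joint <- .joint_label(gesture, band)

  ## ---- NLR pathway: scaled raw samples at the downsampled rate ----
  ds <- downsample(n, config$step)
  split <- three_way_split(ds$kept, joint[ds$kept],
                           fractions = config$fractions, seed = seeds[3])
  split$gs <- ds$discarded
  scaling <- fit_scaling(session$samples[split$tr, , drop = FALSE])
  scaled <- apply_scaling(session$samples, scaling)

  nlr <- list(); nlr_sel <- list()
  idx_sets <- list(gesture = seq_len(n),
                   spherical_force = which(gesture == "Spherical" & band != "none"),
                   tip_force = which(gesture == "Tip" & band != "none"))
  label_sets <- list(gesture = gesture,
                     spherical_force = band, tip_force = band)
  class_sets <- list(gesture = protocol$gestures,
                     spherical_force = protocol$force_levels,
                     tip_force = protocol$force_levels)
  fallbacks <- list(gesture = "Rest",
                    spherical_force = NULL, tip_force = NULL)
  nlr_models <- list()
  for (cl in .CLASSIFIERS) {
    sub <- idx_sets[[cl]]
    lab <- label_sets[[cl]]
    tr <- intersect(split$tr, sub); cv <- intersect(split$cvs, sub)
    ts <- intersect(split$ts, sub); gs <- intersect(split$gs, sub)
    m <- train_ova_nlr(scaled[tr, , drop = FALSE], lab[tr],
                       scaled[cv, , drop = FALSE], lab[cv],
                       classes = class_sets[[cl]], grid = config$nlr_grid,
                       max_iter = config$nlr_max_iter,
                       seed = seeds[4] + match(cl, .CLASSIFIERS),
                       fallback = fallbacks[[cl]])
    m$scaling <- scaling
    nlr_models[[cl]] <- m
    pred_ts <- predict_nlr(m, scaled[ts, , drop = FALSE])$label
    pred_gs <- predict_nlr(m, scaled[gs, , drop = FALSE])$label
    nlr[[cl]] <- list(
      ts = .eval_block(lab[ts], pred_ts, class_sets[[cl]]),
      gs = .eval_block(lab[gs], pred_gs, class_sets[[cl]]))
    nlr_sel[[cl]] <- list(degree = m$degree, TH = m$TH, cv_f1 = m$cv_f1)
  }

  ## ---- LDA pathway: TD features on the full-rate scaled signal ----
  wspec <- window_spec(config$window$length_ms, config$window$overlap_ms,
                       rate_hz = protocol$rate_hz)
  fm <- extract_features(scaled, wspec, labels = joint,
                         ssc_epsilon = config$ssc_epsilon,
                         purity = config$purity)
  w_joint <- fm$label
  w_gesture <- sub("\\|.*$", "", w_joint)
  w_force <- ifelse(grepl("\\|", w_joint), sub("^.*\\|", "", w_joint), "none")
  wsplit <- two_way_split(seq_along(w_joint), w_joint,
                          train_frac = config$train_frac, seed = seeds[3] + 1L)
  w_idx_sets <- list(gesture = seq_along(w_joint),
                     spherical_force = which(w_gesture == "Spherical" &
                                               w_force != "none"),
                     tip_force = which(w_gesture == "Tip" & w_force != "none"))
  w_label_sets <- list(gesture = w_gesture,
                       spherical_force = w_force, tip_force = w_force)
  lda <- list()
  for (cl in .CLASSIFIERS) {
    sub <- w_idx_sets[[cl]]
    lab <- w_label_sets[[cl]]
    tr <- intersect(wsplit$tr, sub); ts <- intersect(wsplit$ts, sub)
    m <- fit_lda_ova(fm$features[tr, , drop = FALSE], lab[tr],
                     classes = class_sets[[cl]])
    pred <- predict_lda(m, fm$features[ts, , drop = FALSE])$label
    lda[[cl]] <- list(ts = .eval_block(lab[ts], pred, class_sets[[cl]]))
  }

  ## ---- FSM replay of the time-ordered GS stream (NLR cadence) ----
  gs <- split$gs
  decoded <- decode_stream(nlr_models$gesture, nlr_models$spherical_force,
                           nlr_models$tip_force,
                           scaled[gs, , drop = FALSE],
                           smooth_k = config$smooth_k)
  truth_g <- gesture[gs]; truth_f <- band[gs]
  grasp_ticks <- truth_g %in% GRASP_GESTURES
  emitted <- decoded$force_level != "none"
  scored <- emitted & truth_f != "none"
  fsm <- list(
    gesture_accuracy = 100 * mean(decoded$gesture == truth_g),
    force_accuracy = if (any(scored))
      100 * mean(decoded$force_level[scored] == truth_f[scored]) else NA_real_,
    force_coverage = 100 * mean(emitted[grasp_ticks]))

  list(subject_id = session$subject_id, nlr = nlr, lda = lda,
       nlr_selection = nlr_sel, fsm = fsm)
}

.eval_block <- function(truth, pred, classes) {
  cm <- confusion_matrix(truth, pred, classes)
  met <- class_metrics(cm)
  list(cm = unclass(cm), metrics = met, macro_f1 = mean(met$f1))
}

#' Run the multi-subject experiment
#'
#' Executes \code{\link{run_subject}} for every synthetic subject,
#' aggregates the per-class metrics (mean and sd across subjects, matching
#' the layout of per-classifier results tables), and compares the two
#' algorithm families per classifier with a paired Wilcoxon signed-rank
#' test on the per-subject macro-F1 values — the NLR classifier evaluated
#' on the Generalization Set against the LDA classifier evaluated on its
#' test set, both at the full 1 kHz cadence. Fully deterministic for a
#' fixed config seed.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param progress Print one line per subject.
#' @return An \code{eval_report} list: \code{config}, \code{subjects},
#'   \code{aggregate}, \code{wilcoxon}, \code{fsm}.
#' @export
run_experiment <- function(config = experiment_config(), progress = FALSE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max,
                                4L * config$n_subjects),
                     ncol = 4L)
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    subjects[[i]] <- run_subject(config, i, seed_mat[i, ])
    if (progress) {
      message(sprintf("subject %d/%d: NLR gesture GS F1 %.2f, LDA gesture TS F1 %.2f",
                      i, config$n_subjects,
                      subjects[[i]]$nlr$gesture$gs$macro_f1,
                      subjects[[i]]$lda$gesture$ts$macro_f1))
    }
  }

  agg <- list(); wil <- list()
  for (cl in .CLASSIFIERS) {
    nlr_f1 <- vapply(subjects, function(s) s$nlr[[cl]]$gs$macro_f1, 0)
    lda_f1 <- vapply(subjects, function(s) s$lda[[cl]]$ts$macro_f1, 0)
    agg[[cl]] <- list(
      nlr = .aggregate_blocks(lapply(subjects, function(s) s$nlr[[cl]]$gs)),
      nlr_ts = .aggregate_blocks(lapply(subjects, function(s) s$nlr[[cl]]$ts)),
      lda = .aggregate_blocks(lapply(subjects, function(s) s$lda[[cl]]$ts)))
    wt <- wilcoxon_compare(nlr_f1, lda_f1, alpha = config$alpha)
    wil[[cl]] <- c(wt, list(alpha = config$alpha,
                            mean_f1_nlr = mean(nlr_f1),
                            mean_f1_lda = mean(lda_f1)))
  }
  fsm <- list(
    gesture_accuracy = mean(vapply(subjects, function(s) s$fsm$gesture_accuracy, 0)),
    force_accuracy = mean(vapply(subjects, function(s) s$fsm$force_accuracy, 0),
                          na.rm = TRUE),
    force_coverage = mean(vapply(subjects, function(s) s$fsm$force_coverage, 0)))

  structure(list(
    config = list(n_subjects = config$n_subjects, seed = config$seed,
                  separation = config$separation, noise_sd = config$noise_sd,
                  step = config$step, fractions = config$fractions,
                  train_frac = config$train_frac, alpha = config$alpha),
    subjects = subjects, aggregate = agg, wilcoxon = wil, fsm = fsm),
    class = "eval_report")
}

# mean +/- sd of per-class metrics and mean row-normalised confusion matrix
.aggregate_blocks <- function(blocks) {
  met <- lapply(blocks, `[[`, "metrics")
  classes <- met[[1]]$class
  cols <- c("f1", "accuracy", "misclassification")
  per_class <- lapply(cols, function(col) {
    vals <- vapply(met, function(m) m[[col]], numeric(length(classes)))
    vals <- matrix(vals, nrow = length(classes))
    data.frame(class = classes, mean = rowMeans(vals),
               sd = apply(vals, 1L, stats::sd), stringsAsFactors = FALSE)
  })
  names(per_class) <- cols
  cms <- lapply(blocks, function(b) {
    cm <- b$cm
    rs <- rowSums(cm)
    cm / ifelse(rs == 0, 1, rs)
  })
  macro <- vapply(blocks, `[[`, 0, "macro_f1")
  list(per_class = per_class,
       mean_confusion = Reduce(`+`, cms) / length(cms),
       mean_macro_f1 = mean(macro),
       sd_macro_f1 = stats::sd(macro))
}

#' Write / validate an evaluation report
#'
#' \code{write_report_json} serialises a report deterministically (no
#' timestamps or machine state, so identical runs give byte-identical
#' files). \code{validate_report} checks the structure against the schema
#' document shipped at \code{inst/schema/eval-report-schema.json}
#' (required keys and types).
#'
#' @param report An \code{eval_report}.
#' @param path Output JSON path.
#' @export
write_report_json <- function(report, path) {
  obj <- .report_to_plain(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

.report_to_plain <- function(report) {
  subj <- lapply(report$subjects, function(s) {
    per_cl <- function(block) list(macro_f1 = block$macro_f1,
                                   cm = unname(block$cm))
    list(subject_id = s$subject_id,
         nlr = lapply(s$nlr, function(x) list(ts = per_cl(x$ts),
                                              gs = per_cl(x$gs))),
         lda = lapply(s$lda, function(x) list(ts = per_cl(x$ts))),
         nlr_selection = s$nlr_selection,
         fsm = s$fsm)
  })
  agg <- lapply(report$aggregate, function(cl) {
    lapply(cl, function(a) {
      list(per_class = a$per_class,
           mean_confusion = unname(a$mean_confusion),
           mean_macro_f1 = a$mean_macro_f1,
           sd_macro_f1 = a$sd_macro_f1)
    })
  })
  list(schema = "semghier-eval-report/1",
       config = report$config, subjects = subj, aggregate = agg,
       wilcoxon = report$wilcoxon, fsm = report$fsm)
}

#' @rdname write_report_json
#' @param strict Raise an error (TRUE) or return the problem list (FALSE).
#' @export
validate_report <- function(report, strict = TRUE) {
  obj <- if (inherits(report, "eval_report")) .report_to_plain(report) else report
  schema_path <- system.file("schema", "eval-report-schema.json",
                             package = "semghier")
  schema <- jsonlite::read_json(schema_path)
  problems <- character(0)
  need <- names(schema$properties)
  miss <- setdiff(need, names(obj))
  if (length(miss)) problems <- c(problems, paste("missing key(s):",
                                                  paste(miss, collapse = ", ")))
  if (!identical(obj$schema, "semghier-eval-report/1")) {
    problems <- c(problems, "schema tag mismatch")
  }
  for (cl in .CLASSIFIERS) {
    w <- obj$wilcoxon[[cl]]
    if (is.null(w$p_value) || is.null(w$significant)) {
      problems <- c(problems, paste("wilcoxon block incomplete for", cl))
    }
    if (is.null(obj$aggregate[[cl]]$nlr$mean_macro_f1) ||
        is.null(obj$aggregate[[cl]]$lda$mean_macro_f1)) {
      problems <- c(problems, paste("aggregate block incomplete for", cl))
    }
  }
  if (strict && length(problems)) {
    stop("report fails schema validation: ", paste(problems, collapse = "; "))
  }
  if (length(problems)) problems else TRUE
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Hierarchical sEMG decoding benchmark:",
      x$config$n_subjects, "subjects, seed", x$config$seed, "\n\n")
  for (cl in .CLASSIFIERS) {
    w <- x$wilcoxon[[cl]]
    cat(sprintf("%-16s mean macro-F1: NLR(GS) %6.2f%%  LDA(TS) %6.2f%%  Wilcoxon p = %s%s\n",
                cl, w$mean_f1_nlr, w$mean_f1_lda,
                format.pval(w$p_value, digits = 3),
                if (isTRUE(w$significant)) " *" else " (ns)"))
  }
  cat(sprintf("\nFSM replay (GS): gesture accuracy %.2f%%, force accuracy %.2f%%, coverage %.2f%%\n",
              x$fsm$gesture_accuracy, x$fsm$force_accuracy,
              x$fsm$force_coverage))
  invisible(x)
}
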