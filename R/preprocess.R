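#' Per-channel scaling
#'
#' The only transformation applied to the envelope samples before
#' classification: each channel is centred on its mean and divided by its
#' range (max - min), so the fitting data map into [-1, 1]. A zero-range
#' (constant) channel is emitted as all zeros and reported in the
#' \code{"warnings"} attribute rather than raising an error, which keeps
#' degenerate synthetic fixtures usable.
#'
#' @param samples Numeric matrix (samples x channels).
#' @return \code{fit_scaling}: an object of class \code{scaling_params} with
#'   per-channel \code{mean} and \code{range}. \code{apply_scaling}: the
#'   scaled matrix.
#' @examples
#' p <- fit_scaling(cbind(c(0, 5, 10)))
#' apply_scaling(cbind(c(0, 5, 10)), p)  # -0.5, 0, 0.5
#' @export
fit_scaling <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("need at least 2 samples per channel")
  mu <- colMeans(samples)
  rng <- apply(samples, 2L, function(x) max(x) - min(x))
  warn <- character(0)
  if (any(rng == 0)) {
    warn <- paste0("zero-range channel(s): ",
                   paste(which(rng == 0), collapse = ", "),
                   " will be emitted as all zeros")
    warning(warn)
  }
  structure(list(mean = mu, range = rng, warnings = warn),
            class = "scaling_params")
}

#' @rdname fit_scaling
#' @param params A fitted \code{scaling_params}.
#' @export
apply_scaling <- function(samples, params) {
  samples <- as.matrix(samples)
  if (ncol(samples) != length(params$mean)) {
    stop("channel count does not match scaling parameters")
  }
  rng <- params$range
  rng[rng == 0] <- 1   # zero-range channels map to all zeros
  out <- sweep(samples, 2L, params$mean, `-`)
  out <- sweep(out, 2L, rng, `/`)
  out[, params$range == 0] <- 0
  out
}

#' Downsample and form the generalization set
#'
#' Keeps every \code{step}-th sample starting at the first one; the kept
#' samples (10% of the data at the default step of 10, i.e. 100 Hz from
#' 1 kHz) feed the three-way split, while the discarded complement (90% of
#' the data) forms the Generalization Set (GS), used as a second held-out
#' test of each classifier.
#'
#' @param n_samples Number of samples (rows) in the recording.
#' @param step Downsampling step (>= 1).
#' @return List with integer index vectors \code{kept} and \code{discarded}
#'   (1-based, order-preserving).
#' @examples
#' d <- downsample(84000, 10)
#' length(d$kept)        # 8400
#' length(d$discarded)   # 75600 (90% of the data -> GS)
#' @export
downsample <- function(n_samples, step) {
  if (step < 1L) stop("step must be >= 1")
  kept <- seq.int(1L, n_samples, by = as.integer(step))
  list(kept = kept, discarded = setdiff(seq_len(n_samples), kept))
}

# stratified index allocation: for each class, floor(frac * n_c) rows go to
# each non-first subset; the remainder goes to the first (training) subset
.stratified_alloc <- function(indices, labels, fractions, seed, min_per_class) {
  stopifnot(length(indices) == length(labels))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  classes <- unique(labels)
  small <- classes[tabulate(factor(labels, classes)) < min_per_class]
  if (length(small)) {
    stop("class(es) with fewer than ", min_per_class, " samples: ",
         paste(small, collapse = ", "))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  parts <- rep(list(integer(0)), length(fractions))
  for (cl in classes) {
    idx <- indices[labels == cl]
    idx <- idx[sample.int(length(idx))]
    n_c <- length(idx)
    sizes <- floor(fractions * n_c)
    sizes[1] <- n_c - sum(sizes[-1])   # remainder to the training subset
    start <- 1L
    for (k in seq_along(sizes)) {
      parts[[k]] <- c(parts[[k]], idx[seq.int(start, length.out = sizes[k])])
      start <- start + sizes[k]
    }
  }
  lapply(parts, sort)
}

#' Stratified three-way split (TR / CVS / TS)
#'
#' Splits the downsample-kept samples into a Training Set, Cross Validation
#' Set and Test Set holding 60/20/20% of the kept data (hence 6/2/2% of the
#' original recording at step 10), stratified by label so every class keeps
#' its proportion. Per class, each of CVS and TS receives
#' \code{floor(fraction x n_c)} samples and the remainder goes to TR;
#' deterministic for a fixed seed.
#'
#' @param kept_indices Integer indices of the kept samples (1-based).
#' @param labels Per-kept-sample labels (stratification key; use the joint
#'   gesture/force label to keep force sub-classes balanced).
#' @param fractions Numeric (TR, CVS, TS) fractions summing to 1.
#' @param seed Integer seed.
#' @return An object of class \code{dataset_split} with index vectors
#'   \code{tr}, \code{cvs}, \code{ts} (and \code{gs} when attached via
#'   \code{split_with_gs}).
#' @export
three_way_split <- function(kept_indices, labels,
                            fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  parts <- .stratified_alloc(kept_indices, labels, fractions, seed,
                             min_per_class = 3L)
  structure(list(tr = parts[[1]], cvs = parts[[2]], ts = parts[[3]],
                 seed = as.integer(seed), fractions = fractions),
            class = "dataset_split")
}

#' Stratified two-way split (TR / TS)
#'
#' Splits feature windows (the LDA pathway) into a training set holding
#' \code{train_frac} of the data (default 70%) and a test set holding the
#' rest, stratified by label; deterministic for a fixed seed.
#'
#' @param indices Integer indices to split.
#' @param labels Per-index labels.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with index vectors \code{tr} and \code{ts}.
#' @export
two_way_split <- function(indices, labels, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  parts <- .stratified_alloc(indices, labels,
                             fractions = c(train_frac, 1 - train_frac), seed,
                             min_per_class = 2L)
  list(tr = parts[[1]], ts = parts[[2]])
}

#' Serialize / read a split manifest
#'
#' JSON layout: \code{\{seed, fractions, tr:[...], cvs:[...], ts:[...],
#' gs:[...]\}} with 0-based integer sample indices.
#'
#' @param split A \code{dataset_split} (optionally carrying \code{gs}).
#' @param path JSON path.
#' @export
write_split_json <- function(split, path) {
  obj <- list(seed = split$seed, fractions = split$fractions,
              tr = split$tr - 1L, cvs = split$cvs - 1L, ts = split$ts - 1L,
              gs = if (is.null(split$gs)) integer(0) else split$gs - 1L)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(tr = as.integer(obj$tr) + 1L,
                 cvs = as.integer(obj$cvs) + 1L,
                 ts = as.integer(obj$ts) + 1L,
                 gs = as.integer(obj$gs) + 1L,
                 seed = obj$seed, fractions = obj$fractions),
            class = "dataset_split")
}
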