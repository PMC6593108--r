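#' Polynomial feature expansion
#'
#' Maps a channel vector to all monomials of total degree 1..degree over its
#' coordinates (e.g. for two channels at degree 2: x1, x2, x1^2, x1*x2,
#' x2^2), which turns the logistic regression non-linear. The constant term
#' is excluded (the bias theta0 is a separate parameter). Monomials are
#' ordered graded-lexicographically: by total degree, then lexicographically
#' on the exponent vectors.
#'
#' @param x Numeric vector, or matrix with one observation per row.
#' @param degree Maximum total degree (>= 1); degree 1 is the identity map.
#' @return Expanded vector, or matrix with one expanded row per observation.
#' @examples
#' poly_expand(c(2, 3), 2)  # x1, x2, x1^2, x1*x2, x2^2
#' ncol(poly_expand(matrix(rnorm(12), 2), 2))  # 6 -> 27 features
#' @export
poly_expand <- function(x, degree) {
  if (degree < 1L) stop("degree must be >= 1")
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (degree == 1L && is.matrix(x)) return(X)
  ex <- .monomial_exponents(ncol(X), degree)
  out <- matrix(1, nrow = nrow(X), ncol = nrow(ex))
  for (j in seq_len(nrow(ex))) {
    for (v in which(ex[j, ] > 0L)) {
      out[, j] <- out[, j] * X[, v]^ex[j, v]
    }
  }
  colnames(out) <- apply(ex, 1L, function(e) {
    paste(sprintf("x%d^%d", which(e > 0), e[e > 0]), collapse = "*")
  })
  if (is.matrix(x)) out else out[1L, ]
}

# exponent vectors of all monomials of total degree 1..degree over d
# variables, graded lexicographic order; cached per (d, degree)
.monomial_cache <- new.env(parent = emptyenv())

.monomial_exponents <- function(d, degree) {
  key <- paste(d, degree, sep = ":")
  if (!is.null(.monomial_cache[[key]])) return(.monomial_cache[[key]])
  compositions <- function(k, dd) {
    # exponent vectors of total degree k over dd variables, lexicographic
    if (dd == 1L) return(matrix(k, 1L, 1L))
    do.call(rbind, lapply(k:0, function(first) {
      cbind(first, compositions(k - first, dd - 1L))
    }))
  }
  ex <- do.call(rbind, lapply(seq_len(degree), function(k) compositions(k, d)))
  # lexicographic on exponents descending-first gives x1, x2, ..., then
  # x1^2, x1*x2, ... within each total degree
  dimnames(ex) <- NULL
  ex <- matrix(as.integer(ex), nrow = nrow(ex))
  .monomial_cache[[key]] <- ex
  ex
}

#' Numerically stable logistic function
#'
#' \eqn{g(z) = 1 / (1 + e^{-z})}, evaluated without overflow for large
#' negative arguments.
#'
#' @param z Numeric vector.
#' @return Probabilities in [0, 1].
#' @export
logistic <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

#' Cross-entropy cost of a binary logistic unit
#'
#' \deqn{J(\theta, \theta_0) = -\frac{1}{m}\sum_i \left[y^{(i)} \ln g(\theta^T
#' x^{(i)} + \theta_0) + (1 - y^{(i)}) \ln(1 - g(\theta^T x^{(i)} +
#' \theta_0))\right]}
#' with probabilities clipped to [1e-12, 1 - 1e-12] before the logarithms.
#'
#' @param theta Parameter vector over the (expanded) features.
#' @param theta0 Bias scalar.
#' @param X Design matrix m x d of expanded inputs.
#' @param y Binary membership vector in \{0, 1\}.
#' @return The scalar cost J.
#' @export
cross_entropy_cost <- function(theta, theta0, X, y) {
  if (nrow(X) == 0L) stop("empty training batch")
  g <- logistic(drop(X %*% theta) + theta0)
  g <- pmin(1 - 1e-12, pmax(1e-12, g))
  -mean(y * log(g) + (1 - y) * log(1 - g))
}

#' Analytic gradient of the cross-entropy cost
#'
#' @inheritParams cross_entropy_cost
#' @return List with \code{theta} (d-vector \eqn{\frac{1}{m} X^T (g - y)})
#'   and \code{theta0} (\eqn{mean(g - y)}).
#' @export
cost_gradient <- function(theta, theta0, X, y) {
  r <- logistic(drop(X %*% theta) + theta0) - y
  list(theta = drop(crossprod(X, r)) / nrow(X), theta0 = mean(r))
}

#' Train a binary logistic unit by resilient backpropagation
#'
#' iRprop- optimisation of the cross-entropy cost: each parameter carries its
#' own step size, grown by eta_plus after a gradient-sign agreement and
#' shrunk by eta_minus (with the remembered gradient zeroed) after a sign
#' change; parameters move by the signed step. A global acceptance rule
#' rejects any step that increases the cost (reverting the parameters and
#' shrinking all steps), so the recorded cost trace is non-increasing.
#' Training stops at \code{max_iter} iterations or when the cost has changed
#' by less than \code{tol} over 10 consecutive iterations.
#'
#' @param X Design matrix of (already expanded) inputs.
#' @param y Binary labels in \{0, 1\}.
#' @param init Optional list \code{(theta, theta0)}; defaults to
#'   Uniform(-0.01, 0.01) draws under \code{seed}.
#' @param max_iter Maximum iterations (default 300).
#' @param seed Seed for the initialisation.
#' @param eta_plus,eta_minus,delta0,delta_min,delta_max Step-size constants
#'   (Riedmiller defaults 1.2, 0.5, 0.1, 1e-6, 50).
#' @param tol Cost-plateau tolerance.
#' @return An object of class \code{nlr_binary}: \code{theta},
#'   \code{theta0}, \code{cost_trace} (accepted costs, element 1 = initial).
#' @export
rprop_fit <- function(X, y, init = NULL, max_iter = 300L, seed = 1L,
                      eta_plus = 1.2, eta_minus = 0.5, delta0 = 0.1,
                      delta_min = 1e-6, delta_max = 50, tol = 1e-6) {
  if (nrow(X) == 0L) stop("empty training batch")
  d <- ncol(X)
  if (is.null(init)) {
    old <- .Random.seed_save()
    set.seed(as.integer(seed))
    init <- list(theta = stats::runif(d, -0.01, 0.01),
                 theta0 = stats::runif(1, -0.01, 0.01))
    .Random.seed_restore(old)
  }
  w <- c(init$theta, init$theta0)     # parameters, bias last
  delta <- rep(delta0, d + 1L)
  g_prev <- rep(0, d + 1L)
  J <- cross_entropy_cost(w[seq_len(d)], w[d + 1L], X, y)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- J
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    gr <- cost_gradient(w[seq_len(d)], w[d + 1L], X, y)
    g <- c(gr$theta, gr$theta0)
    if (any(!is.finite(g))) stop("non-finite gradient encountered")
    sgn <- g * g_prev
    delta <- ifelse(sgn > 0, pmin(delta * eta_plus, delta_max),
                    ifelse(sgn < 0, pmax(delta * eta_minus, delta_min), delta))
    g[sgn < 0] <- 0                   # iRprop-: forget flipped gradients
    w_new <- w - sign(g) * delta
    J_new <- cross_entropy_cost(w_new[seq_len(d)], w_new[d + 1L], X, y)
    if (!is.finite(J_new)) stop("non-finite cost encountered")
    if (J_new <= J) {
      w <- w_new
      g_prev <- g
      J <- J_new
    } else {                          # reject: shrink all steps, stay put
      delta <- pmax(delta * eta_minus, delta_min)
      g_prev <- rep(0, d + 1L)
    }
    trace[it + 1L] <- J
    if (it >= 10L && abs(trace[it + 1L] - trace[it - 9L]) < tol) break
  }
  structure(list(theta = unname(w[seq_len(d)]), theta0 = unname(w[d + 1L]),
                 cost_trace = trace[seq_len(it + 1L)]),
            class = "nlr_binary")
}

#' Train a one-vs-all non-linear logistic regression model
#'
#' For every configuration in the hyperparameter grid (polynomial degree and
#' decision threshold TH), trains one binary logistic unit per class
#' (one-vs-all) on the training set by resilient backpropagation, scores
#' macro-F1 on the cross-validation set, and keeps the best configuration
#' (ties to the earlier grid entry). The selection record (grid and CV
#' macro-F1 per configuration) is retained in the model.
#'
#' @param X_tr,y_tr Training samples (raw scaled channels; expansion happens
#'   internally) and labels.
#' @param X_cv,y_cv Cross-validation samples and labels.
#' @param classes Class vocabulary (order fixes the one-vs-all units and the
#'   tie-break preference).
#' @param grid Data frame with columns \code{degree} and \code{TH}; default
#'   degrees 1..3 at TH 0.5.
#' @param max_iter RProp iteration budget per unit.
#' @param seed Integer seed (initialisation sub-streams per unit).
#' @param fallback Label returned when no unit reaches TH (the gesture
#'   classifier falls back to \code{"Rest"}); NULL means argmax regardless
#'   (the force classifiers).
#' @return An object of class \code{nlr_model}.
#' @export
train_ova_nlr <- function(X_tr, y_tr, X_cv, y_cv, classes,
                          grid = data.frame(degree = 1:3, TH = 0.5),
                          max_iter = 300L, seed = 1L, fallback = NULL) {
  miss <- setdiff(classes, unique(y_tr))
  if (length(miss)) stop("class(es) missing from training set: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(classes, unique(y_cv))
  if (length(miss)) stop("class(es) missing from CV set: ",
                         paste(miss, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  unit_seeds <- matrix(sample.int(.Machine$integer.max,
                                  nrow(grid) * length(classes)),
                       nrow = nrow(grid))

  best <- NULL
  cv_f1 <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    deg <- grid$degree[k]
    Xe_tr <- poly_expand(as.matrix(X_tr), deg)
    Xe_cv <- poly_expand(as.matrix(X_cv), deg)
    units <- lapply(seq_along(classes), function(i) {
      fit <- rprop_fit(Xe_tr, as.numeric(y_tr == classes[i]),
                       max_iter = max_iter, seed = unit_seeds[k, i])
      fit$positive_class <- classes[i]
      fit
    })
    cand <- structure(list(classes = classes, degree = deg, TH = grid$TH[k],
                           units = units, fallback = fallback),
                      class = "nlr_model")
    pred <- predict_nlr(cand, Xe_cv, expanded = TRUE)
    cv_f1[k] <- macro_f1(y_cv, pred$label, classes)
    if (is.null(best) || cv_f1[k] > best$cv_f1) {
      best <- cand
      best$cv_f1 <- cv_f1[k]
    }
  }
  best$selection <- list(grid = grid, cv_f1 = cv_f1)
  best
}

#' Predict with a one-vs-all NLR model
#'
#' Each unit's membership probability is computed by the logistic function;
#' the predicted class is the argmax over the classes whose probability
#' reaches the decision threshold TH (the >= rule). When no class reaches
#' TH, the model's fallback label is returned if it has one (gesture model:
#' Rest), otherwise the plain argmax (force models). Ties break to the
#' lowest class index. Per-class probabilities are independent one-vs-all
#' outputs and are not normalised to sum to 1.
#'
#' @param model An \code{nlr_model}.
#' @param X Matrix of observations (raw channels, one per row), or already
#'   expanded features when \code{expanded = TRUE}.
#' @param expanded Set TRUE when \code{X} is already polynomially expanded.
#' @return List with \code{label} (character vector) and \code{prob}
#'   (observations x classes matrix).
#' @export
predict_nlr <- function(model, X, expanded = FALSE) {
  X <- as.matrix(X)
  if (!expanded) X <- poly_expand(X, model$degree)
  if (ncol(X) != length(model$units[[1]]$theta)) {
    stop("input dimension does not match the model")
  }
  prob <- vapply(model$units, function(u) {
    logistic(drop(X %*% u$theta) + u$theta0)
  }, numeric(nrow(X)))
  prob <- matrix(prob, nrow = nrow(X),
                 dimnames = list(NULL, model$classes))
  over <- prob >= model$TH
  masked <- ifelse(over, prob, -Inf)
  idx <- max.col(masked, ties.method = "first")
  label <- model$classes[idx]
  none <- !matrixStats_any_row(over)
  if (any(none)) {
    label[none] <- if (!is.null(model$fallback)) model$fallback else
      model$classes[max.col(prob, ties.method = "first")[none]]
  }
  list(label = label, prob = prob)
}

# rowAnys without a matrixStats dependency
matrixStats_any_row <- function(m) rowSums(m) > 0

#' Serialize / read an NLR model as JSON
#'
#' Layout: \code{\{algorithm:"nlr", classes, degree, TH, units:[\{class,
#' theta, theta0\}], scaling:\{mean, range\}, selection:\{grid, cv_f1\}\}}.
#'
#' @param model An \code{nlr_model} (optionally carrying \code{$scaling}).
#' @param path JSON path.
#' @export
write_nlr_json <- function(model, path) {
  obj <- list(algorithm = "nlr",
              classes = model$classes,
              degree = model$degree,
              TH = model$TH,
              fallback = model$fallback,
              units = lapply(model$units, function(u) {
                list(class = u$positive_class,
                     theta = u$theta, theta0 = u$theta0)
              }),
              scaling = if (!is.null(model$scaling)) {
                list(mean = unname(model$scaling$mean),
                     range = unname(model$scaling$range))
              },
              selection = if (!is.null(model$selection)) {
                list(grid = model$selection$grid,
                     cv_f1 = model$selection$cv_f1)
              })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_nlr_json
#' @export
read_nlr_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  units <- lapply(seq_len(nrow(obj$units)), function(i) {
    structure(list(theta = obj$units$theta[[i]],
                   theta0 = obj$units$theta0[i],
                   positive_class = obj$units$class[i]),
              class = "nlr_binary")
  })
  structure(list(classes = obj$classes, degree = obj$degree, TH = obj$TH,
                 fallback = obj$fallback, units = units,
                 scaling = obj$scaling, selection = obj$selection),
            class = "nlr_model")
}
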