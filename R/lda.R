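#' Binary linear discriminant
#'
#' Closed-form two-class LDA: with pooled within-class covariance
#' \eqn{\Sigma} (divisor N - 2), class means \eqn{\mu_1, \mu_2} and priors
#' \eqn{\Pi_1, \Pi_2},
#' \deqn{\beta = \Sigma^{-1}(\mu_1 - \mu_2), \quad
#'       \beta_0 = -\beta^T \frac{\mu_1 + \mu_2}{2} + \ln\frac{\Pi_1}{\Pi_2},}
#' and an observation is assigned to class 1 when
#' \eqn{\beta^T x + \beta_0 \ge 0}. A near-singular \eqn{\Sigma} (condition
#' number above 1e10) is ridge-regularised by
#' \eqn{\lambda I, \lambda = 10^{-6}\,\mathrm{tr}(\Sigma)/d}.
#'
#' @param X1,X2 Matrices of observations of class 1 and class 2 (>= 2 rows
#'   each, equal column count).
#' @param priors Optional numeric (\eqn{\Pi_1, \Pi_2}); defaults to the
#'   sample frequencies.
#' @return List with \code{beta}, \code{beta0}, \code{sigma}, \code{lambda}.
#' @export
fit_lda_binary <- function(X1, X2, priors = NULL) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) < 2L || nrow(X2) < 2L) stop("each class needs >= 2 samples")
  if (ncol(X1) != ncol(X2)) stop("dimension mismatch between classes")
  n1 <- nrow(X1); n2 <- nrow(X2)
  if (is.null(priors)) priors <- c(n1, n2) / (n1 + n2)
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  S <- (crossprod(sweep(X1, 2L, mu1)) + crossprod(sweep(X2, 2L, mu2))) /
    (n1 + n2 - 2L)
  reg <- .ridge_guard(S)
  beta <- drop(solve(reg$sigma, mu1 - mu2))
  beta0 <- -sum(beta * (mu1 + mu2) / 2) + log(priors[1] / priors[2])
  list(beta = beta, beta0 = beta0, sigma = reg$sigma, lambda = reg$lambda)
}

# ridge regularisation of a near-singular pooled covariance
.ridge_guard <- function(S, cond_limit = 1e10) {
  d <- ncol(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lambda <- 0
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_limit) {
    lambda <- 1e-6 * sum(diag(S)) / d
    if (lambda <= 0) lambda <- 1e-12
    S <- S + diag(lambda, d)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / min(ev) > 1e14) {
      stop("pooled covariance singular even after regularisation")
    }
  }
  list(sigma = S, lambda = lambda)
}

#' One-vs-all linear discriminant model
#'
#' Multi-class LDA with a shared pooled within-class covariance
#' \eqn{\Sigma} (divisor N - K) and, for each class c, the linear score
#' \deqn{{}_c\beta = \Sigma^{-1}\mu_c, \quad
#'       {}_c\beta_0 = -{}_c\beta^T \frac{\mu_c}{2} + \ln \Pi_c,}
#' predicting the class with the largest \eqn{{}_c\beta^T x + {}_c\beta_0}.
#' Priors are the training-set class frequencies. With equal priors and an
#' identity covariance this reduces exactly to nearest-centroid
#' classification.
#'
#' @param X Feature matrix (observations x features).
#' @param labels Class labels (every class needs >= 2 samples).
#' @param classes Class vocabulary fixing unit order and tie-breaking;
#'   defaults to the sorted unique labels.
#' @return An object of class \code{lda_model}: \code{classes},
#'   \code{sigma}, \code{lambda}, \code{units} (per class: \code{beta},
#'   \code{beta0}, \code{mu}, \code{prior}).
#' @export
fit_lda_ova <- function(X, labels, classes = NULL) {
  X <- as.matrix(X)
  if (is.null(classes)) classes <- sort(unique(labels))
  counts <- table(factor(labels, classes))
  if (any(counts < 2L)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  K <- length(classes); n <- nrow(X); d <- ncol(X)
  S <- matrix(0, d, d)
  mus <- matrix(0, K, d, dimnames = list(classes, colnames(X)))
  for (k in seq_len(K)) {
    Xc <- X[labels == classes[k], , drop = FALSE]
    mus[k, ] <- colMeans(Xc)
    S <- S + crossprod(sweep(Xc, 2L, mus[k, ]))
  }
  S <- S / (n - K)
  reg <- .ridge_guard(S)
  priors <- as.numeric(counts) / n
  units <- lapply(seq_len(K), function(k) {
    beta <- drop(solve(reg$sigma, mus[k, ]))
    list(class = classes[k], beta = beta,
         beta0 = -sum(beta * mus[k, ]) / 2 + log(priors[k]),
         mu = mus[k, ], prior = priors[k])
  })
  structure(list(classes = classes, sigma = reg$sigma, lambda = reg$lambda,
                 units = units),
            class = "lda_model")
}

#' Predict with a one-vs-all LDA model
#'
#' Evaluates each class's linear score and returns the argmax; ties break to
#' the lowest class index.
#'
#' @param model An \code{lda_model}.
#' @param X Observations (matrix or single vector).
#' @return List with \code{label} and \code{score}
#'   (observations x classes).
#' @export
predict_lda <- function(model, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  d <- length(model$units[[1]]$beta)
  if (ncol(X) != d) stop("input dimension does not match the model")
  B <- vapply(model$units, `[[`, numeric(d), "beta")
  b0 <- vapply(model$units, `[[`, numeric(1), "beta0")
  score <- sweep(X %*% B, 2L, b0, `+`)
  colnames(score) <- model$classes
  list(label = model$classes[max.col(score, ties.method = "first")],
       score = score)
}

#' Serialize / read an LDA model as JSON
#'
#' Layout: \code{\{algorithm:"lda", classes, sigma, lambda, units:[\{class,
#' beta, beta0, mu, prior\}]\}}.
#'
#' @param model An \code{lda_model}.
#' @param path JSON path.
#' @export
write_lda_json <- function(model, path) {
  obj <- list(algorithm = "lda", classes = model$classes,
              sigma = unname(as.matrix(model$sigma)),
              lambda = model$lambda,
              units = lapply(model$units, function(u) {
                list(class = u$class, beta = unname(u$beta),
                     beta0 = u$beta0, mu = unname(u$mu), prior = u$prior)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda_json
#' @export
read_lda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  units <- lapply(seq_len(nrow(obj$units)), function(i) {
    list(class = obj$units$class[i], beta = obj$units$beta[[i]],
         beta0 = obj$units$beta0[i], mu = obj$units$mu[[i]],
         prior = obj$units$prior[i])
  })
  structure(list(classes = obj$classes, sigma = obj$sigma,
                 lambda = obj$lambda, units = units),
            class = "lda_model")
}
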