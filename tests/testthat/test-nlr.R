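test_that("polynomial expansion enumerates the documented monomials", {
  expect_equal(poly_expand(c(2, 3), 1), c(2, 3), ignore_attr = TRUE)
  e2 <- poly_expand(c(2, 3), 2)
  expect_setequal(unname(e2), c(2, 3, 4, 6, 9))  # x1, x2, x1^2, x1*x2, x2^2
  expect_length(e2, 5)
  expect_equal(ncol(poly_expand(matrix(0, 1, 6), 2)), 27)  # 6 + 21
  expect_error(poly_expand(c(1, 2), 0), "degree")

  # matrix form agrees with the vector form row by row
  set.seed(3)
  X <- matrix(rnorm(12), ncol = 3)
  E <- poly_expand(X, 3)
  for (i in 1:4) expect_equal(E[i, ], poly_expand(X[i, ], 3),
                              ignore_attr = TRUE)
})

test_that("logistic function is exact and overflow-safe", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(log(3)), 0.75)
  expect_equal(logistic(-1000), 0)
  expect_equal(logistic(1000), 1)
  expect_false(any(!is.finite(logistic(c(-750, 750)))))
})

test_that("cross-entropy cost matches its literal transcription", {
  set.seed(41)
  X <- matrix(rnorm(50 * 4), ncol = 4)
  y <- rbinom(50, 1, 0.5)
  expect_equal(cross_entropy_cost(rep(0, 4), 0, X, y), log(2),
               tolerance = 1e-12)
  for (trial in 1:20) {
    theta <- rnorm(4); theta0 <- rnorm(1)
    expect_equal(cross_entropy_cost(theta, theta0, X, y),
                 cost_oracle(theta, theta0, X, y), tolerance = 1e-12)
  }
  # perfectly confident correct predictions cost (almost) nothing
  Xp <- matrix(c(-1e4, 1e4), ncol = 1)
  expect_lt(cross_entropy_cost(1, 0, Xp, c(0, 1)), 1e-10)
  expect_error(cross_entropy_cost(1, 0, matrix(0, 0, 1), numeric(0)), "empty")
})

test_that("analytic gradient passes central finite differences", {
  set.seed(17)
  h <- 1e-6
  for (trial in 1:10) {
    X <- matrix(rnorm(40 * 3), ncol = 3)
    y <- rbinom(40, 1, 0.5)
    theta <- rnorm(3); theta0 <- rnorm(1)
    g <- cost_gradient(theta, theta0, X, y)
    for (j in 1:3) {
      e <- rep(0, 3); e[j] <- h
      num <- (cross_entropy_cost(theta + e, theta0, X, y) -
                cross_entropy_cost(theta - e, theta0, X, y)) / (2 * h)
      expect_equal(g$theta[j], num, tolerance = 1e-6)
    }
    num0 <- (cross_entropy_cost(theta, theta0 + h, X, y) -
               cross_entropy_cost(theta, theta0 - h, X, y)) / (2 * h)
    expect_equal(g$theta0, num0, tolerance = 1e-6)
  }
  # balanced symmetric data at theta = 0: bias gradient vanishes
  Xs <- matrix(c(-1, 1), ncol = 1)
  gs <- cost_gradient(0, 0, Xs, c(0, 1))
  expect_equal(gs$theta0, 0)
})

test_that("RProp training reduces the cost and honours its budget", {
  set.seed(23)
  X <- matrix(c(rnorm(50, -1, 0.3), rnorm(50, 1, 0.3)), ncol = 1)
  y <- rep(c(0, 1), each = 50)

  fit0 <- rprop_fit(X, y, max_iter = 0, seed = 1)
  init <- rprop_fit(X, y, max_iter = 0, seed = 1)
  expect_identical(fit0$theta, init$theta)

  fit <- rprop_fit(X, y, max_iter = 200, seed = 1)
  expect_lt(fit$cost_trace[length(fit$cost_trace)], log(2))
  # accepted-cost trace is non-increasing
  expect_true(all(diff(fit$cost_trace) <= 1e-12))
})

test_that("degree-2 expansion lets RProp solve concentric rings", {
  rings <- ring_fixture(n_per_class = 100, seed = 5)
  Xe <- poly_expand(rings$X, 2)
  fit <- rprop_fit(Xe, rings$y, max_iter = 300, seed = 2)
  p <- logistic(drop(Xe %*% fit$theta) + fit$theta0)
  acc <- mean((p >= 0.5) == (rings$y == 1))
  expect_gte(acc, 0.99)
})

test_that("one-vs-all training selects by CV macro-F1 and is deterministic", {
  fx <- gaussian_fixture(60, list(c(0, 0), c(4, 0), c(0, 4)), sd = 0.5,
                         seed = 9)
  cv <- gaussian_fixture(30, list(c(0, 0), c(4, 0), c(0, 4)), sd = 0.5,
                         seed = 10)
  grid1 <- data.frame(degree = 1, TH = 0.5)
  m1 <- train_ova_nlr(fx$X, fx$y, cv$X, cv$y, classes = c("C1", "C2", "C3"),
                      grid = grid1, seed = 3)
  expect_equal(m1$degree, 1)
  expect_equal(nrow(m1$selection$grid), 1)

  m <- train_ova_nlr(fx$X, fx$y, cv$X, cv$y, classes = c("C1", "C2", "C3"),
                     seed = 3)
  expect_gte(m$cv_f1, 95)
  m_again <- train_ova_nlr(fx$X, fx$y, cv$X, cv$y,
                           classes = c("C1", "C2", "C3"), seed = 3)
  expect_identical(m$units, m_again$units)

  expect_error(train_ova_nlr(fx$X, fx$y, cv$X, cv$y,
                             classes = c("C1", "C2", "C3", "C9"), seed = 1),
               "missing")
})

test_that("NLR prediction applies the threshold rule with fallback", {
  # hand-built two-unit model on one feature
  unit <- function(theta, theta0, cls) {
    structure(list(theta = theta, theta0 = theta0, positive_class = cls),
              class = "nlr_binary")
  }
  m <- structure(list(classes = c("Rest", "Spherical"), degree = 1, TH = 0.5,
                      units = list(unit(-5, 0, "Rest"), unit(5, 0, "Spherical")),
                      fallback = "Rest"),
                 class = "nlr_model")
  pr <- predict_nlr(m, matrix(c(-1, 1, 0), ncol = 1))
  expect_equal(pr$label[1:2], c("Rest", "Spherical"))
  # at x = 0 both probabilities are exactly TH = 0.5: the >= rule accepts,
  # ties break to the lowest class index
  expect_equal(pr$label[3], "Rest")
  expect_true(all(pr$prob > 0 & pr$prob < 1))

  # no unit reaches TH -> fallback label (gesture model)
  m$TH <- 0.999
  expect_equal(predict_nlr(m, matrix(1, 1, 1))$label, "Rest")
  # without a fallback (force model) the argmax wins regardless of TH
  m$fallback <- NULL
  expect_equal(predict_nlr(m, matrix(1, 1, 1))$label, "Spherical")

  expect_error(predict_nlr(m, matrix(1, 1, 3), expanded = TRUE), "dimension")
})

test_that("degree-1 NLR and LDA agree on a well-separated linear problem", {
  tr <- gaussian_fixture(80, list(c(-3, 0), c(3, 0)), sd = 0.4, seed = 4)
  te <- gaussian_fixture(40, list(c(-3, 0), c(3, 0)), sd = 0.4, seed = 5)
  nlr <- train_ova_nlr(tr$X, tr$y, te$X, te$y, classes = c("C1", "C2"),
                       grid = data.frame(degree = 1, TH = 0.5), seed = 6)
  lda <- fit_lda_ova(tr$X, tr$y)
  expect_identical(predict_nlr(nlr, te$X)$label, predict_lda(lda, te$X)$label)
})

test_that("NLR models survive a JSON round trip", {
  fx <- gaussian_fixture(30, list(c(0, 0), c(3, 3)), sd = 0.5, seed = 1)
  m <- train_ova_nlr(fx$X, fx$y, fx$X, fx$y, classes = c("C1", "C2"),
                     grid = data.frame(degree = 2, TH = 0.5), seed = 2)
  m$scaling <- list(mean = c(0, 0), range = c(1, 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_nlr_json(m, path)
  r <- read_nlr_json(path)
  expect_equal(r$degree, m$degree)
  expect_equal(r$TH, m$TH)
  for (k in seq_along(m$units)) {
    expect_equal(r$units[[k]]$theta, m$units[[k]]$theta)
    expect_equal(r$units[[k]]$theta0, m$units[[k]]$theta0)
  }
  expect_identical(predict_nlr(r, fx$X)$label, predict_nlr(m, fx$X)$label)
})

test_that("CV macro-F1 does not decrease with pattern separation", {
  f1_at <- function(sep) {
    m <- make_subject_model(sep, noise_sd = 0.2, seed = 14)
    s <- generate_session(small_protocol(), m, seed = 15)
    d <- downsample(nrow(s$samples), 10)
    sp <- three_way_split(d$kept, s$gesture_label[d$kept], seed = 16)
    sc <- fit_scaling(s$samples[sp$tr, ])
    X <- apply_scaling(s$samples, sc)
    mod <- train_ova_nlr(X[sp$tr, ], s$gesture_label[sp$tr],
                         X[sp$cvs, ], s$gesture_label[sp$cvs],
                         classes = GESTURES,
                         grid = data.frame(degree = 1, TH = 0.5),
                         max_iter = 150, seed = 17)
    mod$cv_f1
  }
  f1 <- vapply(c(0.3, 0.6, 1.2), f1_at, numeric(1))
  expect_true(all(diff(f1) >= 0))
})
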