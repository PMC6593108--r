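# minimal hand-built NLR models over one input feature, used to drive the
# FSM with predictable decisions
fake_unit <- function(theta, theta0, cls) {
  structure(list(theta = theta, theta0 = theta0, positive_class = cls),
            class = "nlr_binary")
}
# gesture model: x < -0.5 -> Rest, -0.5..0.5 -> Spherical, x > 0.5 -> Tip
fake_gesture_model <- function() {
  structure(list(classes = c("Rest", "Spherical", "Tip"), degree = 1,
                 TH = 0.5, fallback = "Rest",
                 units = list(fake_unit(-20, -10, "Rest"),
                              fake_unit(0, 1, "Spherical"),
                              fake_unit(20, -10, "Tip"))),
            class = "nlr_model")
}
# force model: Low below 0, High above (no Medium mass)
fake_force_model <- function() {
  structure(list(classes = c("Low", "Medium", "High"), degree = 1, TH = 0.5,
                 fallback = NULL,
                 units = list(fake_unit(-20, 0, "Low"),
                              fake_unit(0, -5, "Medium"),
                              fake_unit(20, 0, "High"))),
            class = "nlr_model")
}

test_that("classifier activation follows the hierarchy", {
  expect_equal(active_classifiers("Rest"), "gesture")
  expect_equal(active_classifiers("Spherical"), c("gesture", "spherical_force"))
  expect_equal(active_classifiers("Tip"), c("gesture", "tip_force"))
  expect_equal(active_classifiers("Platform"), "gesture")
  expect_error(active_classifiers("Fist"), "unknown")
})

test_that("single FSM transitions route force decisions with entry latency", {
  # entering Spherical from Platform: state moves, no force output yet
  st <- fsm_step("Platform", "Spherical")
  expect_equal(st$state, "Spherical")
  expect_equal(st$output$force, "none")

  # steady Spherical state consumes the force decision on the same tick
  st2 <- fsm_step("Spherical", "Spherical", force_decision = "High")
  expect_equal(st2$output$gesture, "Spherical")
  expect_equal(st2$output$force, "High")

  # leaving a grasp state clears the force output
  st3 <- fsm_step("Tip", "Rest", force_decision = "Low")
  expect_equal(st3$state, "Rest")
  expect_equal(st3$output$force, "none")

  # force decisions are only legal when the previous state activated one
  expect_error(fsm_step("Platform", "Spherical", force_decision = "Low"),
               "no force classifier")
})

test_that("FSM invariants hold on random decision streams", {
  set.seed(101)
  for (stream in 1:100) {
    n <- 100
    decisions <- sample(GESTURES, n, replace = TRUE)
    forces <- sample(FORCE_LEVELS, n, replace = TRUE)
    state <- "Rest"
    for (t in seq_len(n)) {
      roles <- active_classifiers(state)
      expect_lte(sum(roles %in% c("spherical_force", "tip_force")), 1)
      fd <- if (state %in% GRASP_GESTURES) forces[t] else NULL
      st <- fsm_step(state, decisions[t], force_decision = fd)
      # exactly one state; force only in grasp states
      expect_true(st$state %in% GESTURES && length(st$state) == 1)
      if (!st$output$gesture %in% GRASP_GESTURES) {
        expect_equal(st$output$force, "none")
      }
      expect_equal(st$output$gesture, st$state)
      state <- st$state
    }
  }
})

test_that("decoded streams mirror the gesture decisions and emit force in steady grasps", {
  gm <- fake_gesture_model(); fm <- fake_force_model()
  # pure rest input
  X <- matrix(rep(-1, 50), ncol = 1)
  out <- decode_stream(gm, fm, fm, X)
  expect_true(all(out$gesture == "Rest"))
  expect_true(all(out$force_level == "none"))

  # rest -> spherical hold: force appears one tick after entry
  X2 <- matrix(c(rep(-1, 5), rep(-0.2, 10)), ncol = 1)
  out2 <- decode_stream(gm, fm, fm, X2)
  expect_equal(out2$gesture, c(rep("Rest", 5), rep("Spherical", 10)))
  expect_equal(out2$force_level[6], "none")            # entry tick
  expect_true(all(out2$force_level[7:15] == "Low"))    # steady state

  # the FSM never invents gestures: output equals the decision sequence
  expect_identical(out2$gesture, predict_nlr(gm, X2)$label)

  # removing force models changes nothing for non-grasp outputs
  out3 <- decode_stream(gm, NULL, NULL, X2)
  expect_identical(out3$gesture, out2$gesture)
  expect_true(all(out3$force_level == "none"))
})

test_that("majority smoothing suppresses isolated misclassifications", {
  gm <- fake_gesture_model(); fm <- fake_force_model()
  # steady spherical input with two isolated tip blips
  x <- rep(-0.2, 40)
  x[c(15, 30)] <- 1        # decodes as Tip unsmoothed
  X <- matrix(x, ncol = 1)
  raw <- decode_stream(gm, fm, fm, X)
  expect_equal(sum(raw$gesture == "Tip"), 2)
  sm <- decode_stream(gm, fm, fm, X, smooth_k = 5)
  expect_true(all(sm$gesture[5:40] == "Spherical"))
})

test_that("a noiseless session replay emits force on nearly every grasp tick", {
  cfg <- experiment_config(n_subjects = 1, seed = 9, noise_sd = 0,
                           protocol = session_protocol(rate_hz = 100),
                           nlr_grid = data.frame(degree = 2, TH = 0.5))
  sub <- run_subject(cfg, 1, c(101, 102, 103, 104))
  expect_equal(sub$fsm$gesture_accuracy, 100)
  expect_gte(sub$fsm$force_coverage, 99)
  expect_gte(sub$fsm$force_accuracy, 99)
})
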