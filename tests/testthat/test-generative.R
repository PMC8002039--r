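test_that("neural derivative evaluates the bilinear state equation exactly", {
  m <- connectivity_model(
    A = matrix(c(-1, 0.5, 0, -1), 2, 2),
    B = matrix(0, 2, 2),
    C = matrix(c(1, 0), 2, 1),
    regions = c("R1", "R2"), inputs = "u1"
  )
  expect_equal(neural_derivative(c(0, 0), 0, m), c(0, 0))
  expect_equal(neural_derivative(c(0, 0), 1, m), c(1, 0))
  expect_equal(neural_derivative(c(0.2, 0.1), 1, m), c(0.8, 0.0))
  expect_error(neural_derivative(c(0.2, 0.1, 0), 1, m), "length")
})

test_that("hemodynamic rest state is a fixed point and drive raises the signal", {
  h <- hemodynamic_params(2)
  st <- fesdcm:::rest_state(2)
  d <- hemodynamic_derivative(st, h)
  expect_equal(unlist(d), rep(0, 8), ignore_attr = TRUE)
  expect_equal(bold_observe(st, h), c(0, 0))
  st$x <- c(1, 0)
  d <- hemodynamic_derivative(st, h)
  expect_gt(d$s[1], 0)
  expect_equal(d$s[2], 0)
  # observation depends only on volume and deoxyhemoglobin
  st2 <- fesdcm:::rest_state(2)
  st2$lf <- c(0.3, -0.2)
  expect_equal(bold_observe(st2, h), c(0, 0))
})

test_that("impulse response peaks 4-6 s after a brief neural impulse", {
  # integrate the hemodynamic cascade alone under a 1 s unit neural impulse
  h <- hemodynamic_params(1)
  st <- fesdcm:::rest_state(1)
  dt <- 0.05
  ts <- seq(dt, 25, by = dt)
  bold <- numeric(length(ts))
  for (i in seq_along(ts)) {
    st$x <- if (ts[i] <= 1) 1 else 0
    d <- hemodynamic_derivative(st, h)
    st$s <- st$s + dt * d$s
    st$lf <- st$lf + dt * d$lf
    st$lv <- st$lv + dt * d$lv
    st$lq <- st$lq + dt * d$lq
    bold[i] <- bold_observe(st, h)
  }
  tpeak <- ts[which.max(bold)]
  expect_gt(tpeak, 4)
  expect_lt(tpeak, 6.5)
  # post-peak undershoot
  expect_lt(min(bold[ts > tpeak]), 0)
})

test_that("stability check flags eigenvalues correctly", {
  expect_true(check_stability(-diag(4))$stable)
  expect_false(check_stability(matrix(0.1))$stable)
  expect_error(check_stability(matrix(1, 2, 3)), "square")
  withr::with_seed(8, {
    for (i in 1:10) {
      A <- matrix(stats::runif(16, -0.4, 0.4), 4)
      diag(A) <- -1
      # Gershgorin: |offdiag row sum| <= 3 * 0.4 > 1 is possible, so verify
      # against the direct eigensolve
      expect_equal(check_stability(A)$stable,
                   all(Re(eigen(A, only.values = TRUE)$values) < 0))
    }
  })
})

test_that("simulation honours trivial limits and sampling counts", {
  m0 <- connectivity_model(truth_model$A, truth_model$B,
                          matrix(0, 4, 3), masks = truth_model$masks)
  y <- simulate_bold(m0, NULL, study_paradigm, study_inputs_ev)
  expect_equal(dim(y), c(4, 200))
  expect_equal(max(abs(y)), 0)
  y2 <- simulate_bold(truth_model, NULL, study_paradigm, study_inputs_ev)
  expect_equal(dim(y2), c(4L, 200L))
  bad <- truth_model
  bad$A[1, 1] <- 0.2
  expect_error(simulate_bold(bad, NULL, study_paradigm, study_inputs_ev),
               "unstable|eigenvalue")
})

test_that("additive noise has the requested standard deviation", {
  y0 <- simulate_bold(truth_model, NULL, study_paradigm, study_inputs_ev)
  y1 <- simulate_bold(truth_model, NULL, study_paradigm, study_inputs_ev,
                      noise_sd = 1, seed = 99)
  resid <- y1 - y0
  expect_lt(abs(stats::sd(resid) - 1), 0.1)
  # deterministic given seed
  y1b <- simulate_bold(truth_model, NULL, study_paradigm, study_inputs_ev,
                       noise_sd = 1, seed = 99)
  expect_identical(y1, y1b)
})

test_that("compiled integrator matches the pure-R reference", {
  y <- simulate_bold(truth_model, NULL, short_paradigm, short_inputs)
  yr <- fesdcm:::simulate_bold_r(truth_model, NULL, short_paradigm,
                                 short_inputs)
  expect_lt(max(abs(y - yr)), 1e-10)
  yn <- simulate_bold(truth_model, NULL, short_paradigm, short_inputs,
                      observation = "neural")
  ynr <- fesdcm:::simulate_bold_r(truth_model, NULL, short_paradigm,
                                  short_inputs, observation = "neural")
  expect_lt(max(abs(yn - ynr)), 1e-10)
})

test_that("modulation semantics: constant u_j=1 equals folding B into A", {
  # P is on during every ON block; build a model where P modulates and
  # compare against A + B_P with inputs held identical
  m <- truth_model
  p <- study_paradigm
  # constant-on input: run with boxcar inputs forced to 1 everywhere
  inp <- study_inputs_box
  inp$V <- inp$V * 0
  inp$E <- inp$E * 0 + 1
  inp$P <- inp$P * 0
  y1 <- simulate_bold(m, NULL, p, inp)
  m2 <- connectivity_model(m$A + m$B$E,
                           B = lapply(m$B, function(b) b * 0),
                           C = m$C, masks = list(
                             A = (abs(m$A + m$B$E) > 0) * 1,
                             B = lapply(m$masks$B, function(b) b * 0),
                             C = m$masks$C))
  y2 <- simulate_bold(m2, NULL, p, inp)
  expect_equal(y1, y2, tolerance = 1e-12)
})

test_that("response is first-order linear in C and integration converges in dt", {
  m <- truth_model
  eps <- 0.2
  mA <- connectivity_model(m$A, m$B, m$C * eps, masks = m$masks)
  mB <- connectivity_model(m$A, m$B, m$C * 2 * eps, masks = m$masks)
  yA <- simulate_bold(mA, NULL, short_paradigm, short_inputs)
  yB <- simulate_bold(mB, NULL, short_paradigm, short_inputs)
  expect_lt(norm(yB - 2 * yA, "F") / norm(yB, "F"), 0.2)
  # halving microtime_dt changes trajectories by < 1e-3 relative norm;
  # boxcar blocks align with both microtime grids, so the comparison
  # isolates the integrator (event onsets would be re-quantized)
  p2 <- build_paradigm(3, 240, 9, 21, n_conditions = 4, seed = 2L,
                       microtime_dt = 3 / 32)
  ib1 <- build_inputs(short_paradigm, "boxcar")
  ib2 <- build_inputs(p2, "boxcar")
  y <- simulate_bold(m, NULL, short_paradigm, ib1)
  y2 <- simulate_bold(m, NULL, p2, ib2)
  expect_lt(norm(y - y2, "F") / norm(y, "F"), 1e-3)
})
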