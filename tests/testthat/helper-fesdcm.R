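# Shared fixtures, built once per test run.

study_paradigm <- build_paradigm(3, 600, 9, 21, seed = 1L)
study_inputs_box <- build_inputs(study_paradigm, "boxcar")
study_inputs_ev <- build_inputs(study_paradigm, "event")
truth_model <- default_truth_model()

# short paradigm for cheap unit tests (same block grammar, 2 cycles per
# condition)
short_paradigm <- build_paradigm(3, 240, 9, 21, n_conditions = 4, seed = 2L)
short_inputs <- build_inputs(short_paradigm, "event")

# Simulate one noisy session from a model at a given SNR, deterministic.
simulate_snr <- function(model, paradigm, inputs, snr = 2, seed = 1L) {
  y <- simulate_bold(model, NULL, paradigm, inputs, noise_sd = 0)
  sds <- apply(y, 1, stats::sd) / snr
  y + withr::with_seed(as.integer(seed),
                       matrix(stats::rnorm(length(y)), nrow(y))) * sds
}

# Align a cohort's first-level posteriors with a design's row order.
align_posteriors <- function(posts, cohort, design) {
  keys <- paste0(cohort$records$id,
                 ifelse(cohort$records$timepoint > 0, ":PRE", ":POST"))
  posts[match(rownames(design$X), keys)]
}

# Conjugate linear-Gaussian toy problem used by the free-energy and BMR
# oracle tests: y = X theta + noise, Gaussian prior; everything closed-form.
conjugate_toy <- function(seed = 3, n = 40, sigma = 0.7) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * 3), n)
    th0 <- c(0.3, -0.2, 0.1)
    S0 <- diag(c(0.5, 0.25, 1))
    y <- as.numeric(X %*% c(0.5, -0.4, 0.2)) + stats::rnorm(n, 0, sigma)
    list(X = X, y = y, th0 = th0, S0 = S0, sigma = sigma, n = n)
  })
}

# Closed-form posterior and log evidence of the toy under a given prior cov.
conjugate_solve <- function(toy, S0 = toy$S0) {
  tau <- 1 / toy$sigma^2
  P <- solve(S0) + tau * crossprod(toy$X)
  S <- solve(P)
  m <- as.numeric(S %*% (solve(S0, toy$th0) + tau * crossprod(toy$X, toy$y)))
  Sy <- toy$X %*% S0 %*% t(toy$X) + diag(toy$sigma^2, toy$n)
  r <- toy$y - as.numeric(toy$X %*% toy$th0)
  le <- -0.5 * (toy$n * log(2 * pi) +
                  as.numeric(determinant(Sy)$modulus) +
                  sum(r * solve(Sy, r)))
  list(mean = m, cov = S, log_evidence = le)
}

# Standard ROI fixture: four well-separated spheres on a small grid.
roi_fixture_layout <- function() {
  centers <- list(M1 = c(21, 21, 24), S1 = c(45, 21, 24),
                  SMA = c(21, 48, 24), AG = c(48, 48, 24))
  list(
    centers = centers,
    grid = list(dim = c(24, 24, 16), voxdim = c(3, 3, 3),
                origin = c(0, 0, 0)),
    rois = stats::setNames(lapply(names(centers), function(l) {
      roi_spec(l, centers[[l]], 4)
    }), names(centers))
  )
}

sphere_mask <- function(center, grid, radius = 12) {
  g <- list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$voxdim[1],
            y = grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$voxdim[2],
            z = grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$voxdim[3])
  d2 <- outer(outer((g$x - center[1])^2, (g$y - center[2])^2, `+`),
              (g$z - center[3])^2, `+`)
  (d2 <= radius^2) * 1
}
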