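test_that("free energy has zero KL at the prior and matches the conjugate evidence", {
  toy <- conjugate_toy()
  sol <- conjugate_solve(toy)
  lam <- log(1 / toy$sigma^2)
  model <- list(predict = function(th) matrix(toy$X %*% th, nrow = 1),
                prior = list(mean = toy$th0, cov = toy$S0))
  # at the exact posterior, Laplace F equals the exact log evidence
  Fq <- free_energy(matrix(toy$y, 1), model,
                    list(mean = sol$mean, cov = sol$cov), lambda = lam)
  expect_equal(Fq, sol$log_evidence, tolerance = 1e-6)
  # q = prior: KL = 0, so F is the expected log-likelihood under the prior
  Fp <- free_energy(matrix(toy$y, 1), model,
                    list(mean = toy$th0, cov = toy$S0), lambda = lam)
  r <- toy$y - as.numeric(toy$X %*% toy$th0)
  ell <- sum(stats::dnorm(toy$y, as.numeric(toy$X %*% toy$th0), toy$sigma,
                          log = TRUE)) -
    0.5 * sum(diag(toy$S0 %*% crossprod(toy$X))) / toy$sigma^2
  expect_equal(Fp, ell, tolerance = 1e-6)
  # adding a parameter with near-zero prior variance leaves F unchanged
  X2 <- cbind(toy$X, stats::rnorm(toy$n))
  model2 <- list(predict = function(th) matrix(X2 %*% th, nrow = 1),
                 prior = list(mean = c(toy$th0, 0),
                              cov = diag(c(diag(toy$S0), 1e-10))))
  Fq2 <- free_energy(matrix(toy$y, 1), model2,
                     list(mean = c(sol$mean, 0),
                          cov = diag(c(diag(sol$cov), 1e-10))),
                     lambda = lam)
  # compare against F computed with the diagonalized 3-parameter posterior
  Fq3 <- free_energy(matrix(toy$y, 1), model,
                     list(mean = sol$mean, cov = diag(diag(sol$cov))),
                     lambda = lam)
  expect_equal(Fq2, Fq3, tolerance = 1e-6)
  # singular candidate covariance errors
  expect_error(free_energy(matrix(toy$y, 1), model,
                           list(mean = sol$mean, cov = matrix(0, 3, 3))),
               "singular|positive")
})

test_that("linear-Gaussian reduction: posterior equals the analytic regression", {
  p <- build_paradigm(3, 120, 9, 21, n_conditions = 4, seed = 2)
  inp <- build_inputs(p)
  regions <- c("M1", "S1", "SMA", "AG")
  A <- diag(-0.5, 4); A[2, 1] <- 0.2
  dimnames(A) <- list(regions, regions)
  Cm <- matrix(0, 4, 3, dimnames = list(regions, c("V", "E", "P")))
  Cm[1, 1] <- 0.1; Cm[2, 3] <- 0.1
  masks <- list(A = (A != 0) * 1,
                B = list(V = matrix(0, 4, 4), E = matrix(0, 4, 4),
                         P = matrix(0, 4, 4)),
                C = (Cm != 0) * 1)
  pri <- dcm_priors(masks, estimate_hemo = FALSE)
  iA <- grep("^A:", names(pri$mean))
  pri$mean[iA] <- A[masks$A != 0]      # A fixed at truth
  pri$variance[iA] <- 1e-10
  spec <- dcm_model_spec(masks, p, inp, priors = pri,
                         observation = "neural", estimate_hemo = FALSE)
  iC <- grep("^C:", names(pri$mean))
  truth <- pri$mean
  truth[iC] <- c(0.12, 0.08)
  y0 <- spec$predict(truth)
  yn <- y0 + withr::with_seed(5L, matrix(stats::rnorm(length(y0), 0, 0.05),
                                         nrow(y0)))
  post <- invert(yn, spec, settings = list(fix_lambda = log(1 / 0.05^2)))
  # analytic Bayesian linear regression on the response columns
  base <- spec$predict(`[<-`(truth, iC, 0))
  M <- sapply(iC, function(k) {
    t2 <- truth; t2[iC] <- 0; t2[k] <- 1
    as.numeric(spec$predict(t2) - base)
  })
  tau <- 1 / 0.05^2
  P <- diag(1 / pri$variance[iC]) + tau * crossprod(M)
  Sp <- solve(P)
  mp <- as.numeric(Sp %*% (tau * crossprod(M, as.numeric(yn - base))))
  expect_equal(as.numeric(post$mean[iC]), mp, tolerance = 1e-6)
  expect_equal(unname(post$cov[iC, iC]), Sp, tolerance = 1e-6)
})

test_that("noiseless simulate-then-invert recovers the generating parameters", {
  spec <- dcm_model_spec(truth_model$masks, study_paradigm, study_inputs_ev)
  y <- simulate_bold(truth_model, NULL, study_paradigm, study_inputs_ev)
  post <- invert(y, spec)
  th <- fesdcm:::model_to_theta(truth_model)
  expect_lt(max(abs(post$mean[names(th)] - th)), 0.1)
  expect_true(!is.unsorted(post$diagnostics$F_trace))
  expect_gt(post$diagnostics$explained_variance, 0.99)
})

test_that("null driving input is recovered as null and inversion is deterministic", {
  m0 <- connectivity_model(truth_model$A, truth_model$B,
                           truth_model$C * 0, masks = truth_model$masks)
  y <- simulate_bold(m0, NULL, short_paradigm, short_inputs, noise_sd = 0.2,
                     seed = 3)
  spec <- dcm_model_spec(truth_model$masks, short_paradigm, short_inputs)
  post <- invert(y, spec)
  iC <- grep("^C:", names(post$mean))
  z <- abs(post$mean[iC]) / sqrt(diag(post$cov)[iC])
  expect_true(all(z < 2))
  post2 <- invert(y, spec)
  expect_identical(post$mean, post2$mean)
  expect_identical(post$cov, post2$cov)
  expect_identical(post$free_energy, post2$free_energy)
})

test_that("prediction at the posterior mean explains the data", {
  spec <- dcm_model_spec(truth_model$masks, short_paradigm, short_inputs)
  y0 <- simulate_bold(truth_model, NULL, short_paradigm, short_inputs)
  yn <- simulate_snr(truth_model, short_paradigm, short_inputs, snr = 2,
                     seed = 6)
  post <- invert(yn, spec)
  yhat <- predict(post)
  expect_equal(dim(yhat), dim(yn))
  # explained variance against the noisy data exceeds 50% at SNR 2
  expect_gt(post$diagnostics$explained_variance, 0.5)
  # the prediction tracks the noiseless signal
  expect_gt(stats::cor(as.numeric(yhat), as.numeric(y0)), 0.9)
})

test_that("data orientation and length are validated", {
  spec <- dcm_model_spec(truth_model$masks, short_paradigm, short_inputs)
  y <- simulate_bold(truth_model, NULL, short_paradigm, short_inputs)
  expect_error(invert(y[, 1:10], spec), "volumes")
  # transposed input is accepted
  post1 <- invert(t(y), spec)
  expect_s3_class(post1, "fes_posterior")
})
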