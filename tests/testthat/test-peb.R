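# Patients' clinical capacity scores (PRE and POST sessions, raw units) and
# carryover classification used as worked inputs for the design-matrix rules.
clinical_scores <- function() {
  data.frame(
    id = sprintf("P%02d", rep(1:8, each = 2)),
    cohort = "patient",
    carryover = rep(c(1, -1, 1, -1, 1, -1, -1, 1), each = 2),
    timepoint = rep(c(1, -1), 8),
    capacity_score = c(20.30, 21.32, 8.15, 8.17, 14.33, 18.15, 23.42, 23.82,
                       21.26, 23.00, 24.50, 22.70, 17.31, 16.99, 18.50, 19.76)
  )
}

test_that("controls get a single all-ones mean regressor", {
  rec <- data.frame(id = sprintf("C%02d", 1:16), cohort = "control")
  d <- build_design(rec, "mean")
  expect_equal(dim(d$X), c(16L, 1L))
  expect_true(all(d$X == 1))
  expect_error(build_design(rec, c("mean", "carryover")), "single mean")
})

test_that("capacity scores are mean-corrected and scaled into [-1, 1]", {
  rec <- clinical_scores()
  d <- build_design(rec)
  cs <- d$X[, "capacity"]
  expect_true(all(cs >= -1 & cs <= 1))
  expect_equal(mean(cs), 0, tolerance = 1e-12)
  expect_equal(max(abs(cs)), 1)
  # direct check of the normalization rule on the printed scores
  raw <- rec$capacity_score
  expect_equal(sort(unname(cs)),
               sort((raw - mean(raw)) / max(abs(raw - mean(raw)))))
  # degenerate: equal scores give a zero column
  expect_equal(normalize_capacity(rep(17, 5)), rep(0, 5))
  # label coding
  expect_true(all(d$X[, "carryover"] %in% c(-1, 1)))
  expect_true(all(d$X[, "time"] %in% c(-1, 1)))
  # rows ordered by (subject, PRE before POST)
  expect_equal(rownames(d$X)[1:2], c("P01:PRE", "P01:POST"))
  # missing scores error
  rec2 <- rec; rec2$capacity_score[3] <- NA
  expect_error(build_design(rec2), "capacity")
})

# Construct Gaussian first-level posteriors with a known group structure so
# the hierarchy can be tested without any model inversion.
make_fake_posteriors <- function(X, beta_true, noise = 0.02,
                                 between = 0.05, seed = 1,
                                 prior_var = 1 / 16) {
  nm <- rownames(beta_true)
  p <- length(nm)
  prior <- list(mean = stats::setNames(rep(0, p), nm),
                cov = `dimnames<-`(diag(prior_var, p), list(nm, nm)))
  withr::with_seed(seed, {
    lapply(seq_len(nrow(X)), function(i) {
      th <- as.numeric(beta_true %*% X[i, ]) +
        stats::rnorm(p, 0, between)
      m <- th + stats::rnorm(p, 0, noise)
      structure(list(mean = stats::setNames(m, nm),
                     cov = `dimnames<-`(diag(noise^2, p), list(nm, nm)),
                     prior = prior),
                class = "fes_posterior")
    })
  })
}

test_that("degenerate hierarchy: identical noise-free subjects return their mean", {
  nm <- c("B:E:SMA->M1", "B:E:M1->S1")
  beta_true <- matrix(c(0.3, -0.2), 2, 1, dimnames = list(nm, "mean"))
  X <- matrix(1, 8, 1, dimnames = list(NULL, "mean"))
  posts <- make_fake_posteriors(X, beta_true, noise = 1e-4, between = 0,
                                seed = 2)
  fit <- fit_peb(posts, X, field = "B")
  # the hyperprior on the between-subject log-precision keeps the estimated
  # random-effects variance finite, so a small residual shrinkage (~1e-3)
  # toward the coefficient prior remains even in the degenerate case
  expect_equal(as.numeric(fit$beta), c(0.3, -0.2), tolerance = 1e-2)
})

test_that("planted group effects are recovered and rows are exchangeable", {
  rec <- clinical_scores()
  d <- build_design(rec)
  nm <- c("B:E:SMA->M1", "B:E:M1->S1", "B:E:S1->M1")
  beta_true <- matrix(0, 3, 4, dimnames = list(nm, colnames(d$X)))
  beta_true["B:E:SMA->M1", ] <- c(0, -0.39, 0.51, 0)
  beta_true["B:E:M1->S1", "mean"] <- 0.4
  posts <- make_fake_posteriors(d$X, beta_true, seed = 3)
  fit <- fit_peb(posts, d, field = "B")
  expect_equal(fit$beta["B:E:SMA->M1", "carryover"], -0.39, tolerance = 0.06)
  expect_equal(fit$beta["B:E:SMA->M1", "time"], 0.51, tolerance = 0.06)
  expect_equal(fit$beta["B:E:M1->S1", "mean"], 0.4, tolerance = 0.06)
  # permuting subjects together with design rows leaves estimates unchanged
  perm <- c(9:16, 1:8)
  fit2 <- fit_peb(posts[perm], d$X[perm, ], field = "B")
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-8)
  # free energy invariant to design column order
  fit3 <- fit_peb(posts, d$X[, c(3, 1, 4, 2)], field = "B")
  expect_equal(fit3$free_energy, fit$free_energy, tolerance = 1e-4)
  # rank-deficient designs are rejected
  expect_error(fit_peb(posts, cbind(d$X, dup = d$X[, "time"]), field = "B"),
               "rank")
})

test_that("empirical-Bayes shrinkage pulls subjects toward the group prediction", {
  nm <- c("B:E:SMA->M1", "B:E:M1->S1")
  beta_true <- matrix(c(0.3, -0.2), 2, 1, dimnames = list(nm, "mean"))
  X <- matrix(1, 12, 1, dimnames = list(NULL, "mean"))
  posts <- make_fake_posteriors(X, beta_true, noise = 0.1, between = 0.05,
                                seed = 4)
  fit <- fit_peb(posts, X, field = "B")
  for (i in seq_along(posts)) {
    # the empirical-Bayes update combines the subject's likelihood summary
    # (its de-shrunk estimate) with the design-predicted group value; with
    # diagonal covariances the updated mean lies between the two,
    # coordinate-wise
    po <- posts[[i]]
    eta <- diag(1 / (1 / diag(po$cov) - 1 / diag(po$prior$cov))) %*%
      (po$mean / diag(po$cov) - po$prior$mean / diag(po$prior$cov))
    eta <- as.numeric(eta)
    grp <- as.numeric(fit$beta %*% X[i, ])
    upd <- fit$subject_means[i, ]
    expect_true(all((upd - eta) * (grp - eta) >= -1e-8))
    expect_true(all(abs(upd - grp) <= abs(eta - grp) + 1e-8))
  }
})

test_that("regressor contributions combine by the signed sum rule", {
  ge <- group_estimates(c(carryover = -0.39, time = 0.51), "B:E:SMA->M1")
  expect_equal(combine_contributions(ge, "B:E:SMA->M1", carryover = 1,
                                     timepoint = 1), 0.12)
  expect_equal(combine_contributions(ge, "B:E:SMA->M1", carryover = 1,
                                     timepoint = -1), -0.90)
  expect_equal(combine_contributions(ge, "B:E:SMA->M1"), 0)
  ge0 <- group_estimates(c(mean = 0, carryover = 0, time = 0, capacity = 0),
                         "B:E:SMA->M1")
  expect_equal(combine_contributions(ge0, "B:E:SMA->M1", 1, 1, 0.5), 0)
  expect_error(combine_contributions(ge, "A:AG->M1", 1, 1), "unknown")
  # linear in each regressor value
  ge2 <- group_estimates(c(mean = 0.1, carryover = -0.3, time = 0.2,
                           capacity = 0.4), "conn")
  f <- function(cs) combine_contributions(ge2, "conn", 1, -1, cs)
  expect_equal(f(0.8) - f(0.3), 0.5 * 0.4, tolerance = 1e-12)
})

test_that("second-level search recovers a planted sparse structure", {
  rec <- clinical_scores()
  d <- build_design(rec, c("mean", "carryover"))
  nm <- c("B:E:SMA->M1", "B:E:M1->S1", "B:E:S1->M1", "B:E:AG->S1")
  beta_true <- matrix(0, 4, 2, dimnames = list(nm, colnames(d$X)))
  beta_true["B:E:SMA->M1", ] <- c(0.35, -0.2)
  beta_true["B:E:M1->S1", "mean"] <- 0.3
  posts <- make_fake_posteriors(d$X, beta_true, noise = 0.03,
                                between = 0.03, seed = 5)
  fit <- fit_peb(posts, d, field = "B")
  s <- peb_search(fit)
  expect_equal(s$method, "exhaustive")
  expect_gt(s$inclusion_prob["B:E:SMA->M1"], 0.9)
  expect_gt(s$inclusion_prob["B:E:M1->S1"], 0.9)
  expect_lt(s$inclusion_prob["B:E:S1->M1"], 0.5)
  expect_lt(s$inclusion_prob["B:E:AG->S1"], 0.5)
  # all-on pattern equals the plain fit
  s_on <- peb_search(fit, switchable = character(0))
  expect_equal(s_on$bma$beta, fit$beta, tolerance = 1e-6)
  # one switchable connection -> exactly two models
  s1 <- peb_search(fit, switchable = "B:E:AG->S1")
  expect_equal(nrow(s1$models), 2L)
  # greedy mode agrees with the exhaustive winner on the kept set
  sg <- peb_search(fit, cap = 2)
  expect_equal(sg$method, "greedy")
  expect_gt(sg$inclusion_prob["B:E:SMA->M1"], 0.9)
  expect_lt(sg$inclusion_prob["B:E:S1->M1"], 0.5)
})
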