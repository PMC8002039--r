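test_that("default cohort matches the study layout", {
  coh <- generate_cohort(cohort_spec(seed = 5))
  expect_equal(length(coh$series), 32L)           # 16 + 8 x 2
  expect_equal(sum(coh$records$cohort == "control"), 16L)
  expect_equal(sum(coh$records$cohort == "patient"), 16L)
  expect_true(all(vapply(coh$series, ncol, 0L) == 200L))
  expect_true(all(vapply(coh$series, nrow, 0L) == 4L))
  # controls carry no patient labels
  ctrl <- coh$records[coh$records$cohort == "control", ]
  expect_true(all(is.na(ctrl$carryover)))
  expect_true(all(is.na(ctrl$timepoint)))
  expect_true(all(is.na(ctrl$capacity_score)))
  # balanced CE labels, both sessions per patient
  pat <- coh$records[coh$records$cohort == "patient", ]
  expect_equal(sum(pat$carryover == 1), 8L)
  expect_equal(as.vector(table(pat$id)), rep(2L, 8))
  # every session has a recorded ground truth
  expect_equal(length(coh$truth), 32L)
})

test_that("effects enter with the +1/-1 coding and vanish when zeroed", {
  spec0 <- cohort_spec(n_controls = 0, n_patients = 4,
                       effects = list(), between_sd = 0, seed = 6)
  coh0 <- generate_cohort(spec0)
  th <- do.call(rbind, coh0$truth)
  expect_equal(max(apply(th, 2, stats::sd)), 0)   # identical ground truths
  spec1 <- cohort_spec(n_controls = 0, n_patients = 4,
                       effects = list(carryover = c("B:E:SMA->M1" = 0.5)),
                       between_sd = 0, seed = 6)
  coh1 <- generate_cohort(spec1)
  v <- vapply(coh1$truth, function(t) t[["B:E:SMA->M1"]], 0)
  ce <- coh1$records$carryover
  expect_equal(mean(v[ce == 1]) - mean(v[ce == -1]), 1.0)  # +1/-1 doubles
  expect_error(generate_cohort(cohort_spec(
    n_controls = 0, n_patients = 1, between_sd = 0,
    effects = list(carryover = c("B:E:AG->M1" = 0.5)), seed = 1)),
    "unknown connection")
})

test_that("cohort generation is reproducible and the manifest reflects it", {
  cohA <- generate_cohort(cohort_spec(n_controls = 2, n_patients = 2,
                                      seed = 9))
  cohB <- generate_cohort(cohort_spec(n_controls = 2, n_patients = 2,
                                      seed = 9))
  expect_identical(cohA$series, cohB$series)
  mA <- cohort_manifest(cohA)
  mB <- cohort_manifest(cohB)
  expect_identical(mA$truth_checksum, mB$truth_checksum)
  expect_equal(nrow(mA), 6L)
  expect_true(all(is.na(mA$carryover[mA$cohort == "control"])))
  m32 <- cohort_manifest(generate_cohort(cohort_spec(seed = 5)))
  expect_equal(nrow(m32), 32L)
})

test_that("generated series hit the requested signal-to-noise ratio", {
  coh <- generate_cohort(cohort_spec(n_controls = 3, n_patients = 0,
                                     snr = 2, seed = 12))
  for (i in seq_along(coh$series)) {
    mod <- fesdcm:::theta_to_model(coh$truth[[i]], truth_model$masks,
                                   truth_model$regions, truth_model$inputs)
    y0 <- simulate_bold(mod, NULL, coh$paradigm, coh$inputs)
    resid <- coh$series[[i]] - y0
    snr_emp <- apply(y0, 1, stats::sd) / apply(resid, 1, stats::sd)
    expect_true(all(abs(snr_emp - 2) / 2 < 0.25))
  }
  # pooled over regions and subjects the empirical SNR is within 10%
  snr_all <- unlist(lapply(seq_along(coh$series), function(i) {
    mod <- fesdcm:::theta_to_model(coh$truth[[i]], truth_model$masks,
                                   truth_model$regions, truth_model$inputs)
    y0 <- simulate_bold(mod, NULL, coh$paradigm, coh$inputs)
    apply(y0, 1, stats::sd) / apply(coh$series[[i]] - y0, 1, stats::sd)
  }))
  expect_lt(abs(mean(snr_all) - 2) / 2, 0.1)
})

test_that("synthetic volumes embed and recover the planted series", {
  lay <- roi_fixture_layout()
  y <- simulate_bold(truth_model, NULL, short_paradigm, short_inputs)
  vol <- generate_volumes(y, lay$rois, lay$grid, noise_sd = 0, tr = 3,
                          seed = 2)
  for (l in names(lay$rois)) {
    ev <- first_eigenvariate(vol, lay$rois[[l]])
    expect_gt(stats::cor(ev, y[l, ]), 0.99)
  }
  # zero series -> pure noise
  v0 <- generate_volumes(y * 0, lay$rois, lay$grid, noise_sd = 0.5, tr = 3,
                         seed = 2)
  expect_lt(abs(stats::sd(v0$data) - 0.5), 0.02)
  # overlapping ROIs rejected
  bad <- lay$rois
  bad$S1$center <- bad$M1$center + c(5, 0, 0)
  expect_error(generate_volumes(y, bad, lay$grid), "overlapping")
})

test_that("sampled truth models are stable, integrable and reproducible", {
  m1 <- sample_truth_model(4, paradigm = short_paradigm,
                           inputs = short_inputs)
  m2 <- sample_truth_model(4, paradigm = short_paradigm,
                           inputs = short_inputs)
  expect_identical(m1$A, m2$A)
  expect_true(check_stability(m1$A)$stable)
  expect_identical(m1$masks, truth_model$masks)
})
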