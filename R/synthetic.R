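#' Default ground-truth connectivity for the control group
#'
#' A stable bilinear model on (M1, S1, SMA, AG) whose structure follows the
#' motor-network hypotheses the pipeline searches over: endogenous
#' connections everywhere except the AG-M1 pair and AG to SMA; FES (input E)
#' modulates all endogenous connections except S1 to AG, S1 to SMA and the
#' M1/S1 self-connections; V drives M1 and SMA, P drives S1. Signs follow the
#' expected physiology (suppressive M1 to S1 and SMA to M1, excitatory
#' sensory feedback); magnitudes are set to plausible sub-Hz coupling values.
#'
#' @return a [connectivity_model()].
#' @export
default_truth_model <- function() {
  regions <- c("M1", "S1", "SMA", "AG")
  # rows = target, columns = source; loop gains kept low enough that the
  # planted modulatory effects (up to ~1 Hz on SMA->M1) leave A + B stable
  A <- matrix(c(
    # src:  M1     S1     SMA    AG
    -0.50,  0.20, -0.20,  0.00,   # -> M1
    -0.25, -0.50,  0.25,  0.10,   # -> S1
    -0.15,  0.20, -0.50,  0.00,   # -> SMA
     0.00,  0.10,  0.15, -0.50    # -> AG
  ), 4, 4, byrow = TRUE, dimnames = list(regions, regions))
  BE <- matrix(c(
     0.00,  0.15,  0.00,  0.00,
     0.30,  0.00, -0.25,  0.10,
     0.05,  0.00, -0.10,  0.00,
     0.00,  0.00,  0.15, -0.10
  ), 4, 4, byrow = TRUE, dimnames = list(regions, regions))
  # SMA->M1 modulation is part of the structure with mean 0: the planted
  # carryover/time effects act on it (matching the group-mean-free worked
  # combination for that connection)
  mask_BE <- (BE != 0) * 1
  mask_BE["M1", "SMA"] <- 1
  C <- matrix(0, 4, 3, dimnames = list(regions, c("V", "E", "P")))
  C["M1", "V"] <- 0.125
  C["SMA", "V"] <- 0.15
  C["S1", "P"] <- 0.19
  masks <- list(A = (A != 0) * 1,
                B = list(V = matrix(0, 4, 4), E = mask_BE,
                         P = matrix(0, 4, 4)),
                C = (C != 0) * 1)
  connectivity_model(A, B = list(V = matrix(0, 4, 4), E = BE,
                                 P = matrix(0, 4, 4)), C = C, masks = masks)
}

# Named free-parameter vector of a model (connection_names ordering).
model_to_theta <- function(model) {
  masks <- model$masks
  th <- c(model$A[masks$A != 0],
          unlist(lapply(seq_along(model$B),
                        function(j) model$B[[j]][masks$B[[j]] != 0])),
          model$C[masks$C != 0])
  stats::setNames(th, connection_names(masks, model$regions, model$inputs))
}

# Rebuild matrices from a named free-parameter vector.
theta_to_model <- function(theta, masks, regions, inputs,
                           check_stable = TRUE) {
  n <- length(regions); m <- length(inputs)
  A <- matrix(0, n, n); A[masks$A != 0] <- theta[seq_len(sum(masks$A != 0))]
  off <- sum(masks$A != 0)
  B <- replicate(m, matrix(0, n, n), simplify = FALSE)
  for (j in seq_len(m)) {
    nb <- sum(masks$B[[j]] != 0)
    if (nb) B[[j]][masks$B[[j]] != 0] <- theta[off + seq_len(nb)]
    off <- off + nb
  }
  C <- matrix(0, n, m); C[masks$C != 0] <- theta[off + seq_len(sum(masks$C != 0))]
  connectivity_model(A, B, C, regions, inputs, masks,
                     check_stable = check_stable)
}

#' Cohort specification for synthetic data generation
#'
#' Defaults mirror the study conditions: 16 controls with one session and 8
#' patients with two sessions (PRE/POST), balanced CE/nCE labels, capacity
#' scores drawn uniformly over the observed clinical range (8-25 raw units)
#' and normalized by the group rule, and planted group effects on named
#' connections. Default effect sizes (carryover -0.25 Hz and time +0.30 Hz on
#' the FES modulation of SMA to M1, capacity -0.05 Hz on the V drive to SMA)
#' follow the reported sign pattern at magnitudes that keep the sessionwise
#' modulations inside the support of the first-level shrinkage priors.
#'
#' @param n_controls,n_patients cohort sizes (patients contribute two
#'   sessions each).
#' @param effects list with named numeric vectors `carryover`, `time`,
#'   `capacity`, keyed by connection name, in Hz per unit regressor.
#' @param control_model,patient_model ground-truth [connectivity_model()]s
#'   (patient defaults to the control model; group differences enter through
#'   the regressor effects).
#' @param snr target signal-to-noise ratio (per-region signal sd over noise
#'   sd); used unless `noise_sd` is given explicitly.
#' @param noise_sd explicit additive noise sd, percent signal (overrides
#'   `snr`).
#' @param between_sd between-subject sd on free A/B/C entries, Hz.
#' @param capacity_range raw capacity-score range for patients.
#' @param seed master seed.
#' @return list of class `fes_cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 16, n_patients = 8,
                        effects = list(
                          carryover = c("B:E:SMA->M1" = -0.25),
                          time = c("B:E:SMA->M1" = 0.30),
                          capacity = c("C:V->SMA" = -0.05)),
                        control_model = default_truth_model(),
                        patient_model = NULL,
                        snr = 2, noise_sd = NULL, between_sd = 0.05,
                        capacity_range = c(8, 25), seed = 1L) {
  if (is.null(patient_model)) patient_model <- control_model
  structure(list(n_controls = n_controls, n_patients = n_patients,
                 effects = effects, control_model = control_model,
                 patient_model = patient_model, snr = snr,
                 noise_sd = noise_sd, between_sd = between_sd,
                 capacity_range = capacity_range, seed = as.integer(seed)),
            class = "fes_cohort_spec")
}

apply_effects <- function(theta, effects, ce, tp, cs) {
  bump <- function(th, eff, w) {
    if (is.null(eff) || w == 0) return(th)
    miss <- setdiff(names(eff), names(th))
    if (length(miss)) stop("effect on unknown connection: ",
                           paste(miss, collapse = ", "))
    th[names(eff)] <- th[names(eff)] + w * eff
    th
  }
  theta <- bump(theta, effects$carryover, ce)
  theta <- bump(theta, effects$time, tp)
  theta <- bump(theta, effects$capacity, cs)
  theta
}

#' Generate a synthetic cohort
#'
#' Subject-session parameters are the group-mean parameters plus the planted
#' regressor effects (CE x carryover + timepoint x time + normalized capacity
#' x capacity) plus subject-level Gaussian variability shared between a
#' patient's PRE and POST sessions; each realized A matrix is checked for
#' stability (resampled up to 20 times). BOLD is then simulated through the
#' generative model with additive white noise calibrated per region to the
#' requested SNR. Fully deterministic given the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param paradigm a [build_paradigm()] object; default is the study
#'   paradigm (TR 3 s, 600 s run, 9 s OFF / 21 s ON, 4 conditions).
#' @param encoding input encoding, passed to [build_inputs()].
#' @return object of class `fes_cohort`: `records` (one row per
#'   subject-session), `series` (list of regions x volumes matrices),
#'   `truth` (list of named ground-truth parameter vectors), `noise_sd`
#'   (per-session, per-region), `paradigm`, `inputs`, `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            paradigm = build_paradigm(3, 600, 9, 21,
                                                      seed = spec$seed),
                            encoding = "event") {
  inputs <- build_inputs(paradigm, encoding)
  masks_c <- spec$control_model$masks
  masks_p <- spec$patient_model$masks
  regions <- spec$control_model$regions
  input_labels <- spec$control_model$inputs
  theta_c <- model_to_theta(spec$control_model)
  theta_p <- model_to_theta(spec$patient_model)

  withr::with_seed(spec$seed, {
    # patient labels and capacity scores first (normalization is group-wide)
    ce <- rep(c(1, -1), length.out = spec$n_patients)
    cs_raw <- matrix(stats::runif(2 * spec$n_patients,
                                  spec$capacity_range[1],
                                  spec$capacity_range[2]),
                     ncol = 2, dimnames = list(NULL, c("PRE", "POST")))
    cs_norm <- matrix(normalize_capacity(as.numeric(cs_raw)),
                      ncol = 2, dimnames = dimnames(cs_raw))

    # a draw is admissible when every session of the subject yields a stable
    # model AND a finite noiseless trajectory (the hemodynamic cascade can
    # diverge for extreme couplings even when A itself is stable)
    simulate_clean <- function(theta, masks) {
      mod <- tryCatch(theta_to_model(theta, masks, regions, input_labels),
                      error = function(e) NULL)
      if (is.null(mod)) return(NULL)
      tryCatch(simulate_bold(mod, NULL, paradigm, inputs, noise_sd = 0),
               error = function(e) NULL)
    }
    add_noise <- function(y) {
      sds <- if (is.null(spec$noise_sd)) {
        apply(y, 1, stats::sd) / spec$snr
      } else {
        rep(spec$noise_sd, length(regions))
      }
      sds <- pmax(sds, 1e-6)
      list(y = y + matrix(stats::rnorm(length(y)), nrow(y)) * sds, sd = sds)
    }

    records <- list(); series <- list(); truth <- list(); noise <- list()
    row <- 0L
    for (i in seq_len(spec$n_controls)) {
      y <- NULL
      for (try in 1:20) {
        b <- stats::rnorm(length(theta_c), 0, spec$between_sd)
        th <- theta_c + b
        y <- simulate_clean(th, masks_c)
        if (!is.null(y)) break
      }
      if (is.null(y)) stop("stability resampling exhausted for control ", i)
      sim <- add_noise(y)
      row <- row + 1L
      records[[row]] <- data.frame(id = sprintf("C%02d", i),
                                   cohort = "control", carryover = NA_real_,
                                   timepoint = NA_real_,
                                   capacity_score = NA_real_)
      series[[row]] <- sim$y; truth[[row]] <- th; noise[[row]] <- sim$sd
    }
    for (i in seq_len(spec$n_patients)) {
      sess <- NULL
      for (try in 1:20) {
        b <- stats::rnorm(length(theta_p), 0, spec$between_sd)
        cand <- lapply(1:2, function(s) {
          tp <- c(1, -1)[s]
          th <- apply_effects(theta_p + b, spec$effects, ce[i], tp,
                              cs_norm[i, s])
          list(theta = th, y = simulate_clean(th, masks_p))
        })
        if (!any(vapply(cand, function(z) is.null(z$y), logical(1)))) {
          sess <- cand
          break
        }
      }
      if (is.null(sess)) stop("stability resampling exhausted for patient ", i)
      for (s in 1:2) {
        sim <- add_noise(sess[[s]]$y)
        row <- row + 1L
        records[[row]] <- data.frame(id = sprintf("P%02d", i),
                                     cohort = "patient", carryover = ce[i],
                                     timepoint = c(1, -1)[s],
                                     capacity_score = cs_raw[i, s])
        series[[row]] <- sim$y; truth[[row]] <- sess[[s]]$theta
        noise[[row]] <- sim$sd
      }
    }
    structure(list(records = do.call(rbind, records), series = series,
                   truth = truth, noise_sd = noise, paradigm = paradigm,
                   inputs = inputs, spec = spec),
              class = "fes_cohort")
  })
}

#' @export
print.fes_cohort <- function(x, ...) {
  cat("Synthetic cohort:", sum(x$records$cohort == "control"),
      "control sessions +", sum(x$records$cohort == "patient"),
      "patient sessions,", x$paradigm$n_volumes, "volumes each\n")
  invisible(x)
}

#' Cohort manifest
#'
#' One row per subject-session with labels, the generation seed and a
#' checksum of the ground-truth parameters (regeneration with the same seed
#' reproduces identical checksums).
#'
#' @param cohort a [generate_cohort()] object.
#' @return data.frame.
#' @export
cohort_manifest <- function(cohort) {
  ck <- vapply(cohort$truth, function(th) {
    sprintf("%.10f:%.10f", sum(th), sum(th^2))
  }, "")
  cbind(cohort$records,
        data.frame(seed = cohort$spec$seed,
                   n_volumes = cohort$paradigm$n_volumes,
                   truth_checksum = ck))
}

#' Embed ROI series into synthetic 4-D volumes
#'
#' Each region's time series is written into the voxels around its ROI
#' center with Gaussian spatial weighting (sd = radius/2, support 2 x
#' radius); everywhere else is pure noise. Used as the fixture for the
#' ROI-summarization stage.
#'
#' @param series regions x volumes matrix (rows named by region).
#' @param roi_layout named list of [roi_spec()] (centers >= 2 x radius
#'   apart).
#' @param grid list with `dim` (3 integers), `voxdim` (mm), `origin` (mm).
#' @param noise_sd voxel noise sd.
#' @param tr repetition time, s.
#' @param seed noise seed.
#' @return a [volume_series()].
#' @export
generate_volumes <- function(series, roi_layout, grid, noise_sd = 0.1,
                             tr = 3, seed = 1L) {
  centers <- t(vapply(roi_layout, function(r) r$center, numeric(3)))
  radii <- vapply(roi_layout, function(r) r$radius, 0)
  if (length(roi_layout) > 1) {
    dd <- as.matrix(stats::dist(centers))
    diag(dd) <- Inf
    lim <- outer(radii, radii, function(a, b) 2 * pmax(a, b))
    if (any(dd < lim)) stop("overlapping ROIs: centers closer than twice ",
                            "the sphere radius")
  }
  d <- grid$dim
  Tn <- ncol(series)
  g <- voxel_grid_mm(d, grid$voxdim, grid$origin)
  arr <- withr::with_seed(as.integer(seed),
                          array(stats::rnorm(prod(d) * Tn, 0, noise_sd),
                                dim = c(d, Tn)))
  flat <- matrix(arr, prod(d), Tn)
  for (r in seq_along(roi_layout)) {
    roi <- roi_layout[[r]]
    sigma <- roi$radius / 2
    d2 <- outer(outer((g$x - roi$center[1])^2, (g$y - roi$center[2])^2, `+`),
                (g$z - roi$center[3])^2, `+`)
    sel <- which(d2 <= (2 * roi$radius)^2)
    w <- exp(-d2[sel] / (2 * sigma^2))
    flat[sel, ] <- flat[sel, ] + outer(w, series[r, ])
  }
  volume_series(array(flat, c(d, Tn)), voxdim = grid$voxdim,
                origin = grid$origin, tr = tr)
}
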