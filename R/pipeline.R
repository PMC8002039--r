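a_conn <- function(src, tgt) paste0("A:", src, "->", tgt)
b_conn <- function(src, tgt, input = "E") paste0("B:", input, ":", src, "->", tgt)

#' STEP 1 candidate driving-input structures
#'
#' Three candidate C structures for the controls group: the volitional input
#' V drives M1 only, SMA only, or both; the proprioceptive input P drives S1
#' in every candidate.
#'
#' @return named list of character vectors of C connection names.
#' @export
step1_input_space <- function() {
  list(
    "V->M1"   = c("C:V->M1", "C:P->S1"),
    "V->SMA"  = c("C:V->SMA", "C:P->S1"),
    "V->both" = c("C:V->M1", "C:V->SMA", "C:P->S1")
  )
}

#' STEP 2 candidate endogenous structures
#'
#' Fixed connections (always present): the M1-S1 bidirectional pair, SMA to
#' M1 and M1 to SMA. The four remaining bidirectional inter-region pairs
#' (SMA-S1, AG-M1, AG-S1, AG-SMA) are switched; by default direction-pairs
#' are switched jointly (2^4 = 16 candidates), with `pairwise = FALSE`
#' switching the eight directions independently (2^8 candidates).
#' Self-connections are always present and are not part of the switch set.
#'
#' @param pairwise switch bidirectional pairs jointly (default TRUE).
#' @return list with `candidates` (named list of ON off-diagonal A
#'   connections, fixed included), `fixed`, `switch_units` (named list of the
#'   switched connection groups).
#' @export
step2_structural_space <- function(pairwise = TRUE) {
  fixed <- c(a_conn("M1", "S1"), a_conn("S1", "M1"),
             a_conn("SMA", "M1"), a_conn("M1", "SMA"))
  pairs <- list(
    "SMA<->S1" = c(a_conn("SMA", "S1"), a_conn("S1", "SMA")),
    "AG<->M1"  = c(a_conn("AG", "M1"), a_conn("M1", "AG")),
    "AG<->S1"  = c(a_conn("AG", "S1"), a_conn("S1", "AG")),
    "AG<->SMA" = c(a_conn("AG", "SMA"), a_conn("SMA", "AG"))
  )
  units <- if (pairwise) pairs else
    stats::setNames(as.list(unlist(pairs, use.names = FALSE)),
                    unlist(pairs, use.names = FALSE))
  grid <- enumerate_reduced_models(names(units), cap = 2^length(units))
  candidates <- lapply(seq_len(nrow(grid)), function(i) {
    on <- names(units)[grid[i, , drop = TRUE] == 1]
    c(fixed, unlist(units[on], use.names = FALSE))
  })
  names(candidates) <- apply(grid, 1, function(r) {
    on <- names(units)[r == 1]
    if (length(on)) paste(on, collapse = "+") else "fixed-only"
  })
  list(candidates = candidates, fixed = fixed, switch_units = units,
       grid = grid)
}

#' STEP 3 switchable modulatory connections
#'
#' The electrical-stimulation input E is the only modulator; its switchable
#' entries are the B coefficients over every connection present in the
#' winning A structure, self-connections included.
#'
#' @param winning_a character vector of A connection names present in the
#'   winning structure (self-connections `A:R->R` included).
#' @return character vector of switchable B connection names.
#' @export
step3_b_space <- function(winning_a) {
  st <- sub("^A:", "", winning_a)
  paste0("B:E:", st)
}

# Full structure masks for first-level inversion: complete A, complete
# B for input E, and the union of the STEP 1 C candidates.
full_masks <- function(regions = c("M1", "S1", "SMA", "AG"),
                       inputs = c("V", "E", "P")) {
  n <- length(regions)
  A <- matrix(1, n, n, dimnames = list(regions, regions))
  B <- stats::setNames(replicate(length(inputs), matrix(0, n, n),
                                 simplify = FALSE), inputs)
  B[["E"]] <- matrix(1, n, n, dimnames = list(regions, regions))
  C <- matrix(0, n, length(inputs), dimnames = list(regions, inputs))
  C["M1", "V"] <- 1
  C["SMA", "V"] <- 1
  C["S1", "P"] <- 1
  list(A = A, B = B, C = C)
}

# Pin a set of parameters (by name) in a first-level posterior via Bayesian
# model reduction; returns the updated posterior with the reduced prior.
reduce_posterior <- function(post, off_names, pinned_var = 1e-8) {
  if (!length(off_names)) return(post)
  vr <- diag(post$prior$cov)
  idx <- which(names(post$mean) %in% off_names)
  vr[idx] <- pinned_var
  red_prior <- list(mean = post$prior$mean, cov = diag(vr, length(vr)))
  r <- bayesian_model_reduction(post$prior, post, red_prior)
  post$mean <- r$mean
  post$cov <- r$cov
  post$free_energy <- post$free_energy + r$dF
  post$prior$cov <- red_prior$cov
  post
}

#' Run the six-step model-structure identification pipeline
#'
#' Controls first: STEP 1 selects the driving-input (C) structure by Bayesian
#' model selection over the three candidates; STEP 2 searches the endogenous
#' (A) structure over the switchable bidirectional pairs with fixed M1-S1 and
#' SMA-M1 / M1-SMA connections, averaging the best-performing models; STEP 3
#' exhaustively searches the modulatory (B) structure with E as the only
#' modulator. Patients then inherit the C structure (STEP 4, weights
#' re-estimated), search their A structure nested inside the controls' winner
#' (STEP 5), and search their B structure within the STEP 5 result (STEP 6).
#'
#' Every subject is inverted once against the full model; all structure
#' comparisons are performed at the second level by Bayesian model reduction
#' of the group (PEB) posterior, and resolved structures are propagated to
#' the first-level posteriors by per-subject BMR before the next step.
#'
#' @param cohort a [generate_cohort()] object, or a list with `records`
#'   (data.frame), `series` (list of regions x volumes matrices, aligned with
#'   records rows), `paradigm` and `inputs`.
#' @param config list; recognized fields: `cap` (4096), `occam_mass` (0.95),
#'   `pairwise` (TRUE), `include_threshold` (0.5), `settings` (passed to
#'   [invert()]), `expected_variance_fraction` (1/16), `out_dir` (optional:
#'   persist per-step JSON artifacts).
#' @return object of class `fes_pipeline_result`: per-step winners,
#'   probabilities, estimates, final control and patient group estimates, and
#'   the first-level posteriors.
#' @export
run_pipeline <- function(cohort, config = list()) {
  cfg <- utils::modifyList(list(cap = 4096, occam_mass = 0.95,
                                pairwise = TRUE, include_threshold = 0.5,
                                settings = list(),
                                expected_variance_fraction = 1 / 16,
                                out_dir = NULL), config)
  records <- cohort$records
  masks <- full_masks()
  spec <- dcm_model_spec(masks, cohort$paradigm, cohort$inputs)
  regions <- spec$regions
  self_conn <- a_conn(regions, regions)

  invert_rows <- function(rows) {
    lapply(rows, function(i) invert(cohort$series[[i]], spec, cfg$settings))
  }

  ctrl_rows <- which(records$cohort == "control")
  pat_rows <- which(records$cohort == "patient")
  if (!length(ctrl_rows)) stop("pipeline requires a controls group")

  ctrl_post <- invert_rows(ctrl_rows)
  ctrl_design <- build_design(records[ctrl_rows, , drop = FALSE], "mean")
  steps <- list()

  # STEP 1: driving-input structure, controls
  cand_c <- step1_input_space()
  peb_c <- fit_peb(ctrl_post, ctrl_design, field = "C",
                   cfg$expected_variance_fraction)
  cmp <- peb_compare(peb_c, cand_c)
  win_c <- cand_c[[cmp$winner]]
  steps$step1 <- list(candidates = cand_c, probabilities = cmp$probabilities,
                      winner = cmp$winner, structure = win_c)
  all_c <- paste0("C:", c("V->M1", "V->SMA", "P->S1"))
  ctrl_post <- lapply(ctrl_post, reduce_posterior,
                      off_names = setdiff(all_c, win_c))

  # STEP 2: endogenous structure, controls
  sp2 <- step2_structural_space(cfg$pairwise)
  peb_a <- fit_peb(ctrl_post, ctrl_design, field = "A",
                   cfg$expected_variance_fraction)
  switch_a <- unlist(sp2$switch_units, use.names = FALSE)
  cmp2 <- peb_compare(peb_a, sp2$candidates, switchable = switch_a)
  incl_units <- vapply(names(sp2$switch_units), function(un) {
    in_cand <- vapply(sp2$candidates, function(cd) {
      all(sp2$switch_units[[un]] %in% cd)
    }, logical(1))
    sum(cmp2$probabilities[in_cand])
  }, 0)
  keep_units <- names(incl_units)[incl_units >= cfg$include_threshold]
  win_a <- c(sp2$fixed, unlist(sp2$switch_units[keep_units],
                               use.names = FALSE))
  keep2 <- occam_window(cmp2$probabilities, cfg$occam_mass)
  bma2 <- bayesian_model_average(cmp2$reduced[keep2],
                                 cmp2$probabilities[keep2] /
                                   sum(cmp2$probabilities[keep2]))
  steps$step2 <- list(probabilities = cmp2$probabilities,
                      inclusion_prob = incl_units,
                      winner = cmp2$winner, structure = win_a,
                      bma_mean = bma2$mean)
  ctrl_post <- lapply(ctrl_post, reduce_posterior,
                      off_names = setdiff(switch_a, win_a))

  # STEP 3: modulatory structure, controls (E only)
  ctrl_b_space <- step3_b_space(c(win_a, self_conn))
  all_b <- grep("^B:", names(spec$prior$mean), value = TRUE)
  ctrl_post <- lapply(ctrl_post, reduce_posterior,
                      off_names = setdiff(all_b, ctrl_b_space))
  peb_b <- fit_peb(ctrl_post, ctrl_design, field = "B",
                   cfg$expected_variance_fraction)
  s3 <- peb_search(peb_b, switchable = ctrl_b_space, cap = cfg$cap,
                   occam_mass = cfg$occam_mass)
  win_b <- names(s3$inclusion_prob)[s3$inclusion_prob >=
                                      cfg$include_threshold]
  steps$step3 <- list(inclusion_prob = s3$inclusion_prob,
                      structure = win_b, bma = s3$bma, method = s3$method)
  ctrl_post <- lapply(ctrl_post, reduce_posterior,
                      off_names = setdiff(ctrl_b_space, win_b))
  ctrl_final <- list(C = peb_c, A = peb_a, B = s3$bma)

  pat_final <- NULL
  if (length(pat_rows)) {
    pat_post <- invert_rows(pat_rows)
    pat_design <- build_design(records[pat_rows, , drop = FALSE])
    # align posteriors with the design's (id, session) row order
    keys <- paste0(records$id[pat_rows],
                   ifelse(records$timepoint[pat_rows] > 0, ":PRE", ":POST"))
    pat_post <- pat_post[match(rownames(pat_design$X), keys)]

    # STEP 4: C structure inherited from STEP 1, weights re-estimated
    pat_post <- lapply(pat_post, reduce_posterior,
                       off_names = setdiff(all_c, win_c))
    peb_c_pat <- fit_peb(pat_post, pat_design, field = "C",
                         cfg$expected_variance_fraction)
    steps$step4 <- list(structure = win_c, estimates = peb_c_pat)

    # STEP 5: A structure nested inside the controls' winner
    pat_post <- lapply(pat_post, reduce_posterior,
                       off_names = setdiff(switch_a, win_a))
    peb_a_pat <- fit_peb(pat_post, pat_design, field = "A",
                         cfg$expected_variance_fraction)
    s5 <- peb_search(peb_a_pat, switchable = win_a, cap = cfg$cap,
                     occam_mass = cfg$occam_mass)
    win_a_pat <- names(s5$inclusion_prob)[s5$inclusion_prob >=
                                            cfg$include_threshold]
    if (!all(win_a_pat %in% win_a)) {
      stop("nestedness violated: patients' A structure contains connections ",
           "absent from the controls' winner")
    }
    steps$step5 <- list(inclusion_prob = s5$inclusion_prob,
                        structure = win_a_pat, bma = s5$bma,
                        method = s5$method)
    pat_post <- lapply(pat_post, reduce_posterior,
                       off_names = setdiff(win_a, win_a_pat))

    # STEP 6: B structure within the STEP 5 result
    pat_b_space <- step3_b_space(c(win_a_pat, self_conn))
    pat_post <- lapply(pat_post, reduce_posterior,
                       off_names = setdiff(all_b, pat_b_space))
    peb_b_pat <- fit_peb(pat_post, pat_design, field = "B",
                         cfg$expected_variance_fraction)
    s6 <- peb_search(peb_b_pat, switchable = pat_b_space, cap = cfg$cap,
                     occam_mass = cfg$occam_mass)
    win_b_pat <- names(s6$inclusion_prob)[s6$inclusion_prob >=
                                            cfg$include_threshold]
    steps$step6 <- list(inclusion_prob = s6$inclusion_prob,
                        structure = win_b_pat, bma = s6$bma,
                        method = s6$method)
    pat_final <- list(C = peb_c_pat, A = peb_a_pat, B = s6$bma)
  } else {
    pat_post <- list()
  }

  res <- structure(list(steps = steps, controls = ctrl_final,
                        patients = pat_final,
                        first_level = list(controls = ctrl_post,
                                           patients = pat_post)),
                   class = "fes_pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(res, cfg$out_dir)
  res
}

#' @export
print.fes_pipeline_result <- function(x, ...) {
  cat("Six-step model-structure identification\n")
  cat("  STEP 1 winner:", x$steps$step1$winner, "(p =",
      format(max(x$steps$step1$probabilities), digits = 3), ")\n")
  cat("  STEP 2 A structure:", length(x$steps$step2$structure),
      "off-diagonal connections\n")
  cat("  STEP 3 B structure:", length(x$steps$step3$structure),
      "modulated connections\n")
  if (!is.null(x$steps$step5)) {
    cat("  STEP 5 patients' A:", length(x$steps$step5$structure),
        "connections; STEP 6 patients' B:",
        length(x$steps$step6$structure), "connections\n")
  }
  invisible(x)
}

# Persist per-step artifacts (masks, probabilities, free energies) as JSON
# plus a summary CSV of final estimates per connection x regressor.
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per_step <- lapply(res$steps, function(st) {
    st[intersect(names(st),
                 c("probabilities", "inclusion_prob", "winner",
                   "structure", "method"))]
  })
  jsonlite::write_json(per_step, file.path(out_dir, "steps.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summarize <- function(fe, group) {
    do.call(rbind, lapply(names(fe), function(field) {
      b <- fe[[field]]$beta
      data.frame(group = group, field = field,
                 connection = rep(rownames(b), ncol(b)),
                 regressor = rep(colnames(b), each = nrow(b)),
                 estimate = as.numeric(b))
    }))
  }
  tab <- summarize(res$controls, "controls")
  if (!is.null(res$patients)) tab <- rbind(tab, summarize(res$patients,
                                                          "patients"))
  utils::write.csv(tab, file.path(out_dir, "final_estimates.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
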