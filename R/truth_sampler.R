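#' Sample a random ground-truth model for recovery studies
#'
#' Draws the free off-diagonal A entries and B entries uniformly on
#' `[-spread, spread]` (self-connections uniform on -0.7..-0.3 Hz) over the
#' structure masks of the default truth model, keeping the default driving
#' inputs, and resamples until the model is both stable and integrable under
#' the given paradigm. Used by simulate-then-invert parameter-recovery
#' studies.
#'
#' @param seed integer seed.
#' @param spread half-width of the uniform draw for off-diagonal couplings,
#'   Hz.
#' @param paradigm,inputs paradigm and input timelines used for the
#'   integrability check (defaults: the study paradigm).
#' @return a [connectivity_model()].
#' @export
sample_truth_model <- function(seed, spread = 0.35,
                               paradigm = build_paradigm(3, 600, 9, 21,
                                                         seed = 1L),
                               inputs = build_inputs(paradigm)) {
  base <- default_truth_model()
  th0 <- model_to_theta(base)
  nm <- names(th0)
  offA <- startsWith(nm, "A:") & !nm %in% a_conn(base$regions, base$regions)
  selfA <- nm %in% a_conn(base$regions, base$regions)
  isB <- startsWith(nm, "B:")
  withr::with_seed(as.integer(seed), {
    for (try in 1:50) {
      th <- th0
      th[offA] <- stats::runif(sum(offA), -spread, spread)
      th[selfA] <- stats::runif(sum(selfA), -0.7, -0.3)
      th[isB] <- stats::runif(sum(isB), -spread, spread)
      mod <- tryCatch(theta_to_model(th, base$masks, base$regions,
                                     base$inputs),
                      error = function(e) NULL)
      if (is.null(mod)) next
      ok <- tryCatch({
        simulate_bold(mod, NULL, paradigm, inputs)
        TRUE
      }, error = function(e) FALSE)
      if (ok) return(mod)
    }
    stop("could not draw a stable, integrable truth model in 50 attempts")
  })
}
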