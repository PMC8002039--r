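#' Neural derivative of the bilinear state equation
#'
#' Evaluates \eqn{\dot x = (A + \sum_j u_j B^{(j)}) x + C u} exactly.
#'
#' @param x neural state vector (length n).
#' @param u input vector (length m), ordered as `model$inputs`.
#' @param model a [connectivity_model()].
#' @return dx/dt, 1/s.
#' @export
neural_derivative <- function(x, u, model) {
  n <- length(model$regions)
  m <- length(model$inputs)
  if (length(x) != n) stop("x has length ", length(x), ", expected ", n)
  if (length(u) != m) stop("u has length ", length(u), ", expected ", m)
  Aeff <- model$A
  for (j in seq_len(m)) Aeff <- Aeff + u[j] * model$B[[j]]
  as.numeric(Aeff %*% x + model$C %*% u)
}

# Resting state of the hemodynamic cascade: zero vasodilatory signal, unit
# inflow/volume/deoxyhemoglobin (zero on the log scale).
rest_state <- function(n) {
  list(x = numeric(n), s = numeric(n),
       lf = numeric(n), lv = numeric(n), lq = numeric(n))
}

#' Hemodynamic state derivative (balloon-windkessel)
#'
#' Four states per region: vasodilatory signal s, and the logs of blood
#' inflow, blood volume and deoxyhemoglobin content. The log-transform keeps
#' the natural-scale states strictly positive.
#'
#' @param state list with numeric vectors `x` (neural activity), `s`, `lf`,
#'   `lv`, `lq` (log inflow / volume / deoxyhemoglobin).
#' @param params a [hemodynamic_params()] object.
#' @return list of derivatives `s`, `lf`, `lv`, `lq`.
#' @export
hemodynamic_derivative <- function(state, params) {
  f <- exp(state$lf); v <- exp(state$lv); q <- exp(state$lq)
  if (any(!is.finite(f)) || any(f <= 0) || any(v <= 0) || any(q <= 0)) {
    stop("natural-scale hemodynamic states must be strictly positive")
  }
  fout <- v^(1 / params$stiffness)
  ef <- 1 - (1 - params$extraction)^(1 / f)
  list(
    s  = state$x - params$decay * state$s - params$autoregulation * (f - 1),
    lf = state$s / f,
    lv = (f - fout) / (params$transit * v),
    lq = (f * ef / params$extraction - fout * q / v) / (params$transit * q)
  )
}

#' BOLD observation equation
#'
#' Maps blood volume and deoxyhemoglobin content to percent BOLD signal
#' change; the resting state maps to exactly 0.
#'
#' @inheritParams hemodynamic_derivative
#' @return percent signal change per region.
#' @export
bold_observe <- function(state, params) {
  v <- exp(state$lv); q <- exp(state$lq)
  if (any(v <= 0) || any(q <= 0)) stop("volume/deoxyhemoglobin must be positive")
  k1 <- 4.3 * 40.3 * params$extraction * params$te
  k2 <- params$epsilon * 25 * params$extraction * params$te
  k3 <- 1 - params$epsilon
  params$v0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

# Stack the input timelines into the microtime matrix expected by the
# integrator (one row per microtime bin, one column per model input).
input_matrix <- function(inputs, model) {
  U <- cbind(V = inputs$V, E = inputs$E, P = inputs$P)
  U[, model$inputs, drop = FALSE]
}

#' Simulate BOLD time series from a bilinear DCM
#'
#' Integrates the neural and hemodynamic dynamics over the paradigm's
#' microtime grid (classical RK4 per bin; inputs piecewise-constant at the
#' microtime resolution) and samples the BOLD observation at every TR.
#' Additive white Gaussian noise of the requested standard deviation is added
#' per region.
#'
#' @param model a [connectivity_model()]; must be stable.
#' @param hemo a [hemodynamic_params()] object (default canonical values).
#' @param paradigm a [build_paradigm()] object.
#' @param inputs timelines from [build_inputs()] (must match the paradigm).
#' @param noise_sd additive noise standard deviation, percent signal.
#' @param seed integer seed for the noise.
#' @param observation `"bold"` (default) or `"neural"` (returns the sampled
#'   neural states; used for linear-Gaussian reductions).
#' @return n x n_volumes matrix (regions x volumes), percent signal change.
#' @export
simulate_bold <- function(model, hemo = NULL, paradigm, inputs,
                          noise_sd = 0, seed = 1L,
                          observation = c("bold", "neural")) {
  observation <- match.arg(observation)
  st <- check_stability(model$A)
  if (!st$stable) {
    stop("unstable A matrix: eigenvalue with real part ",
         format(st$max_real, digits = 4), " >= 0")
  }
  n <- length(model$regions)
  if (is.null(hemo)) hemo <- hemodynamic_params(n)
  U <- input_matrix(inputs, model)
  bins_per_vol <- as.integer(round(paradigm$tr / paradigm$microtime_dt))
  Bflat <- unlist(model$B, use.names = FALSE)
  y <- .dcm_integrate_cpp(model$A, Bflat, model$C, U,
                          hemo$decay, hemo$autoregulation, hemo$transit,
                          hemo$stiffness, hemo$extraction,
                          hemo$epsilon, hemo$te, hemo$v0,
                          paradigm$microtime_dt, bins_per_vol,
                          paradigm$n_volumes,
                          observation == "neural")
  if (any(!is.finite(y))) {
    stop("trajectory produced non-finite BOLD output (model too extreme)")
  }
  rownames(y) <- model$regions
  if (noise_sd > 0) {
    y <- y + withr::with_seed(as.integer(seed),
                              matrix(stats::rnorm(length(y), 0, noise_sd),
                                     nrow = n))
  }
  y
}

# Pure-R reference integrator: same equations and RK4 stepping as the
# compiled kernel, used as an independent numerical oracle in the tests.
simulate_bold_r <- function(model, hemo = NULL, paradigm, inputs,
                            observation = "bold") {
  n <- length(model$regions)
  if (is.null(hemo)) hemo <- hemodynamic_params(n)
  U <- input_matrix(inputs, model)
  dt <- paradigm$microtime_dt
  bins_per_vol <- as.integer(round(paradigm$tr / dt))
  nbins <- bins_per_vol * paradigm$n_volumes
  st <- rest_state(n)
  out <- matrix(0, n, paradigm$n_volumes)
  vol <- 0
  clamp <- function(st) {
    list(x = st$x, s = pmin(pmax(st$s, -10), 10),
         lf = pmin(pmax(st$lf, -3), 3), lv = pmin(pmax(st$lv, -3), 3),
         lq = pmin(pmax(st$lq, -3), 3))
  }
  dfun <- function(st, u) {
    st <- clamp(st)
    dx <- neural_derivative(st$x, u, model)
    dh <- hemodynamic_derivative(st, hemo)
    list(x = dx, s = dh$s, lf = dh$lf, lv = dh$lv, lq = dh$lq)
  }
  add <- function(st, d, h) {
    list(x = st$x + h * d$x, s = st$s + h * d$s, lf = st$lf + h * d$lf,
         lv = st$lv + h * d$lv, lq = st$lq + h * d$lq)
  }
  for (b in seq_len(nbins)) {
    u <- U[b, ]
    k1 <- dfun(st, u)
    k2 <- dfun(add(st, k1, dt / 2), u)
    k3 <- dfun(add(st, k2, dt / 2), u)
    k4 <- dfun(add(st, k3, dt), u)
    st <- list(
      x  = st$x + dt / 6 * (k1$x + 2 * k2$x + 2 * k3$x + k4$x),
      s  = pmin(pmax(st$s + dt / 6 * (k1$s + 2 * k2$s + 2 * k3$s + k4$s),
                     -10), 10),
      lf = pmin(pmax(st$lf + dt / 6 * (k1$lf + 2 * k2$lf + 2 * k3$lf + k4$lf),
                     -3), 3),
      lv = pmin(pmax(st$lv + dt / 6 * (k1$lv + 2 * k2$lv + 2 * k3$lv + k4$lv),
                     -3), 3),
      lq = pmin(pmax(st$lq + dt / 6 * (k1$lq + 2 * k2$lq + 2 * k3$lq + k4$lq),
                     -3), 3)
    )
    if (b %% bins_per_vol == 0) {
      vol <- vol + 1
      out[, vol] <- if (observation == "neural") st$x else bold_observe(st, hemo)
    }
  }
  rownames(out) <- model$regions
  out
}
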