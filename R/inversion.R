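#' Shrinkage priors for a bilinear DCM
#'
#' Default priors over the free parameters selected by the structure masks:
#' off-diagonal A entries N(0, 1/16); self-connections N(-0.5, 1/256) in Hz
#' (parameterized directly, not log-scaled); B entries N(0, 1/16); C entries
#' N(0, 1); hemodynamic log-scale parameters (per-region signal decay and
#' transit time, global epsilon) N(0, 1/256). Observation noise is handled by
#' per-region log-precision hyperparameters with hyperprior N(2, 1),
#' estimated alongside the parameters.
#'
#' @param masks structure masks (list `A`, `B`, `C`) as in
#'   [connectivity_model()].
#' @param regions,inputs label vectors.
#' @param estimate_hemo include hemodynamic scale parameters (default TRUE).
#' @return list with named numeric vectors `mean` and `variance`.
#' @export
dcm_priors <- function(masks, regions = c("M1", "S1", "SMA", "AG"),
                       inputs = c("V", "E", "P"), estimate_hemo = TRUE) {
  nm <- connection_names(masks, regions, inputs)
  mu <- numeric(length(nm))
  va <- numeric(length(nm))
  names(mu) <- names(va) <- nm
  isA <- startsWith(nm, "A:")
  isB <- startsWith(nm, "B:")
  isC <- startsWith(nm, "C:")
  self <- vapply(strsplit(sub("^A:", "", nm), "->", fixed = TRUE),
                 function(z) length(z) == 2 && z[1] == z[2], logical(1)) & isA
  mu[isA] <- 0; va[isA] <- 1 / 16
  mu[self] <- -0.5; va[self] <- 1 / 256
  va[isB] <- 1 / 16
  va[isC] <- 1
  if (estimate_hemo) {
    hn <- c(paste0("H:decay:", regions), paste0("H:transit:", regions),
            "H:epsilon")
    hm <- stats::setNames(numeric(length(hn)), hn)
    hv <- stats::setNames(rep(1 / 256, length(hn)), hn)
    mu <- c(mu, hm); va <- c(va, hv)
  }
  list(mean = mu, variance = va)
}

#' Model specification for inversion
#'
#' Bundles structure masks, paradigm, input timelines, hemodynamics, priors
#' and observation mode into a self-contained forward-model specification
#' used by [invert()], [free_energy()] and [predict.fes_posterior()].
#'
#' @param masks structure masks (list `A`, `B` list, `C`).
#' @param paradigm a [build_paradigm()] object.
#' @param inputs timelines from [build_inputs()].
#' @param regions,input_labels label vectors.
#' @param hemo a [hemodynamic_params()] object; default canonical.
#' @param priors output of [dcm_priors()]; default priors if NULL.
#' @param observation `"bold"` or `"neural"`.
#' @param estimate_hemo passed to [dcm_priors()] when priors are NULL.
#' @return object of class `fes_model_spec` with elements `predict`
#'   (function of the parameter vector), `prior` and bookkeeping fields.
#' @export
dcm_model_spec <- function(masks, paradigm, inputs,
                           regions = c("M1", "S1", "SMA", "AG"),
                           input_labels = c("V", "E", "P"),
                           hemo = NULL, priors = NULL,
                           observation = c("bold", "neural"),
                           estimate_hemo = TRUE) {
  observation <- match.arg(observation)
  n <- length(regions)
  m <- length(input_labels)
  if (is.null(hemo)) hemo <- hemodynamic_params(n)
  if (is.null(priors)) {
    priors <- dcm_priors(masks, regions, input_labels, estimate_hemo)
  }
  nm <- names(priors$mean)
  U <- cbind(V = inputs$V, E = inputs$E, P = inputs$P)[, input_labels,
                                                       drop = FALSE]
  bins_per_vol <- as.integer(round(paradigm$tr / paradigm$microtime_dt))

  iA <- which(startsWith(nm, "A:"))
  iC <- which(startsWith(nm, "C:"))
  iB <- which(startsWith(nm, "B:"))
  iH <- which(startsWith(nm, "H:"))
  # index of each free entry inside its matrix, in the same order as nm
  posA <- which(masks$A != 0)
  posC <- which(masks$C != 0)
  posB <- lapply(masks$B, function(b) which(b != 0))
  nB <- vapply(posB, length, 0L)

  unpack <- function(theta) {
    A <- matrix(0, n, n); A[posA] <- theta[iA]
    B <- replicate(m, matrix(0, n, n), simplify = FALSE)
    off <- 0
    for (j in seq_len(m)) {
      if (nB[j] > 0) {
        B[[j]][posB[[j]]] <- theta[iB[off + seq_len(nB[j])]]
        off <- off + nB[j]
      }
    }
    C <- matrix(0, n, m); C[posC] <- theta[iC]
    h <- hemo
    if (length(iH)) {
      th <- theta[iH]
      h$decay <- hemo$decay * exp(th[seq_len(n)])
      h$transit <- hemo$transit * exp(th[n + seq_len(n)])
      h$epsilon <- hemo$epsilon * exp(th[2 * n + 1])
    }
    list(A = A, B = B, C = C, hemo = h)
  }

  predict_fn <- function(theta) {
    pars <- unpack(theta)
    ev <- eigen(pars$A, only.values = TRUE)$values
    if (max(Re(ev)) >= 0) {
      stop("unstable parameter proposal: max Re(eig(A)) = ",
           format(max(Re(ev)), digits = 4))
    }
    .dcm_integrate_cpp(pars$A, unlist(pars$B, use.names = FALSE), pars$C, U,
                       pars$hemo$decay, pars$hemo$autoregulation,
                       pars$hemo$transit, pars$hemo$stiffness,
                       pars$hemo$extraction, pars$hemo$epsilon,
                       pars$hemo$te, pars$hemo$v0,
                       paradigm$microtime_dt, bins_per_vol,
                       paradigm$n_volumes, observation == "neural")
  }

  structure(list(predict = predict_fn, unpack = unpack,
                 prior = priors, names = nm,
                 regions = regions, inputs = input_labels,
                 masks = masks, n_regions = n, observation = observation,
                 n_volumes = paradigm$n_volumes),
            class = "fes_model_spec")
}

# Finite-difference Jacobian of the vectorized prediction (column-major,
# region index fastest) with systematic forward step h.
fd_jacobian <- function(predict_fn, theta, g0, h = 1e-4) {
  p <- length(theta)
  J <- matrix(0, length(g0), p)
  for (k in seq_len(p)) {
    tk <- theta
    tk[k] <- tk[k] + h
    gk <- tryCatch(predict_fn(tk), error = function(e) NULL)
    if (is.null(gk)) {  # perturbation destabilized the model: step backwards
      tk[k] <- theta[k] - h
      gk <- predict_fn(tk)
      J[, k] <- (as.numeric(g0) - as.numeric(gk)) / h
    } else {
      J[, k] <- (as.numeric(gk) - as.numeric(g0)) / h
    }
  }
  J
}

# Laplace free energy given residuals, Jacobian, posterior covariance and
# per-region noise log-precisions. KL terms for the log-precision
# hyperparameters are added by the caller when they are being estimated.
fe_terms <- function(evec, w, J, S, theta, prior_mean, prior_prec,
                     prior_logdet, n_per_region, lambda) {
  p <- length(theta)
  d <- theta - prior_mean
  trSJ <- sum(S * crossprod(J * sqrt(w)))      # tr(S J' W J)
  logdetS <- determinant_psd(S)
  ell <- -0.5 * sum(w * evec^2) + 0.5 * sum(n_per_region * lambda) -
    0.5 * sum(n_per_region) * log(2 * pi) - 0.5 * trSJ
  kl <- 0.5 * (sum(S * prior_prec) + as.numeric(t(d) %*% prior_prec %*% d) -
                 p + prior_logdet - logdetS)
  ell - kl
}

determinant_psd <- function(M) {
  as.numeric(determinant(M, logarithm = TRUE)$modulus)
}

#' Laplace free energy of a candidate posterior
#'
#' Computes the variational free energy F = E_q[log likelihood] - KL(q ||
#' prior) under the Laplace approximation, for a Gaussian candidate posterior
#' `q` over the model parameters and a Gaussian observation model with fixed
#' per-region noise log-precision.
#'
#' With `q` equal to the prior the KL term is exactly zero. For
#' linear-Gaussian models evaluated at the exact posterior, F equals the log
#' model evidence.
#'
#' @param data regions x time matrix of observations.
#' @param model a `fes_model_spec`, or a list with `predict` (function of
#'   theta returning a regions x time matrix) and `prior` (list `mean`,
#'   `variance` or `cov`).
#' @param q candidate posterior: list with `mean` and `cov`.
#' @param lambda per-region noise log-precision (recycled to the number of
#'   regions).
#' @return free energy in nats.
#' @export
free_energy <- function(data, model, q, lambda = 0) {
  data <- as.matrix(data)
  n <- nrow(data); N <- ncol(data)
  lambda <- rep(lambda, length.out = n)
  S <- as.matrix(q$cov)
  if (!all(is.finite(S))) stop("candidate covariance must be finite")
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("candidate covariance is singular or not positive definite")
  pr <- model$prior
  if (!is.null(pr$variance) && is.null(pr$cov)) pr$cov <- diag(pr$variance,
                                                              length(pr$mean))
  prior_prec <- solve(pr$cov)
  g <- model$predict(q$mean)
  evec <- as.numeric(data - g)
  w <- rep(exp(lambda), N)
  J <- fd_jacobian(model$predict, q$mean, g)
  fe_terms(evec, w, J, S, q$mean, pr$mean, prior_prec,
           determinant_psd(as.matrix(pr$cov)), rep(N, n), lambda)
}

#' Invert a DCM by variational Laplace
#'
#' Gauss-Newton ascent on the Laplace free energy with step-halving; accepted
#' steps never decrease F. Noise is modeled as white Gaussian per region with
#' log-precision hyperparameters updated by damped Newton steps between
#' Gauss-Newton iterations. Convergence is declared when the free-energy
#' improvement stays below `tol` for `tol_count` consecutive iterations.
#' The procedure is fully deterministic for fixed inputs and settings.
#'
#' @param data regions x time matrix (rows ordered as `spec$regions`).
#'   A time x regions data.frame or matrix with named columns is transposed
#'   automatically.
#' @param spec a [dcm_model_spec()].
#' @param settings list; recognized fields `max_iter` (128), `tol` (0.01
#'   nats), `tol_count` (3), `fd_step` (1e-4), `max_halvings` (8),
#'   `lambda_prior_mean` (2), `lambda_prior_var` (1), `fix_lambda`
#'   (numeric: do not estimate noise precision, use this log-precision).
#' @return object of class `fes_posterior`: `mean`, `cov`, `free_energy`,
#'   `lambda`, `prior`, `diagnostics` (iterations, F trace, explained
#'   variance, convergence flag) and the model `spec`.
#' @export
invert <- function(data, spec, settings = list()) {
  s <- utils::modifyList(list(max_iter = 128L, tol = 0.01, tol_count = 3L,
                              fd_step = 1e-4, max_halvings = 8L,
                              lambda_prior_mean = 2, lambda_prior_var = 1,
                              fix_lambda = NULL, verbose = FALSE), settings)
  data <- as_region_matrix(data, spec$regions)
  n <- nrow(data); N <- ncol(data)
  if (N != spec$n_volumes) {
    stop("data has ", N, " volumes but the paradigm specifies ", spec$n_volumes)
  }
  p <- length(spec$prior$mean)
  mu0 <- spec$prior$mean
  Pi0 <- diag(1 / spec$prior$variance, p)
  prior_logdet <- sum(log(spec$prior$variance))
  theta <- mu0
  fixed_lambda <- !is.null(s$fix_lambda)
  lambda <- if (fixed_lambda) rep(s$fix_lambda, length.out = n) else
    rep(s$lambda_prior_mean, n)

  g <- spec$predict(theta)   # prior mean must be stable
  S <- diag(spec$prior$variance, p)
  F_trace <- numeric(0)
  F_curr <- -Inf
  below <- 0L
  converged <- FALSE
  iter <- 0L

  lambda_terms <- function(lambda, sq_by_region, tr_by_region) {
    if (fixed_lambda) return(0)
    vq <- 1 / (0.5 * exp(lambda) * (sq_by_region + tr_by_region) +
                 1 / s$lambda_prior_var)
    -sum(0.5 * (vq / s$lambda_prior_var +
                  (lambda - s$lambda_prior_mean)^2 / s$lambda_prior_var -
                  1 + log(s$lambda_prior_var / vq)))
  }

  evaluate_F <- function(evec, J, S, theta, lambda) {
    w <- rep(exp(lambda), N)
    sq <- region_rowsums(evec^2, n)
    trr <- vapply(seq_len(n), function(r) {
      idx <- seq(r, n * N, by = n)
      sum(S * crossprod(J[idx, , drop = FALSE]))
    }, 0)
    fe_terms(evec, w, J, S, theta, mu0, Pi0, prior_logdet, rep(N, n), lambda) +
      lambda_terms(lambda, sq, trr)
  }

  for (iter in seq_len(s$max_iter)) {
    evec <- as.numeric(data - g)
    J <- fd_jacobian(spec$predict, theta, g, s$fd_step)

    # M-step: per-region noise log-precision jointly with the posterior
    # covariance it conditions (small fixed point: lambda given tr(S J'J),
    # S given lambda), Newton-refined against the hyperprior
    sq <- region_rowsums(evec^2, n)
    JtJ_r <- lapply(seq_len(n), function(r) {
      idx <- seq(r, n * N, by = n)
      crossprod(J[idx, , drop = FALSE])
    })
    S_new <- S
    for (rounds in 1:3) {
      trr <- vapply(JtJ_r, function(M) sum(S_new * M), 0)
      if (!fixed_lambda) {
        lambda <- pmin(pmax(log(N / pmax(sq + trr, 1e-12)), -8), 12)
        for (it in 1:6) {
          tau <- exp(lambda)
          grad <- 0.5 * (N - tau * (sq + trr)) -
            (lambda - s$lambda_prior_mean) / s$lambda_prior_var
          curv <- -0.5 * tau * (sq + trr) - 1 / s$lambda_prior_var
          lambda <- pmin(pmax(lambda - grad / curv, -8), 12)
        }
      }
      H <- Reduce(`+`, Map(function(M, tau_r) tau_r * M,
                           JtJ_r, as.list(exp(lambda)))) + Pi0
      S_new <- solve((H + t(H)) / 2)
      if (fixed_lambda) break
    }
    trr <- vapply(JtJ_r, function(M) sum(S_new * M), 0)
    tau <- exp(lambda)
    w <- rep(tau, N)

    # E-step: Gauss-Newton proposal with step-halving on F
    grad_theta <- crossprod(J, w * evec) - Pi0 %*% (theta - mu0)
    dtheta <- as.numeric(S_new %*% grad_theta)

    F_curr_eval <- evaluate_F(evec, J, S_new, theta, lambda)
    if (!is.finite(F_curr)) {
      F_curr <- F_curr_eval
      best <- list(theta = theta, S = S_new, lambda = lambda, g = g)
    }

    # step-halving: find the best candidate along the Gauss-Newton direction
    accepted <- FALSE
    improved_local <- FALSE
    step <- 1
    F_cand <- -Inf
    for (half in 0:s$max_halvings) {
      theta_c <- theta + step * dtheta
      g_c <- tryCatch(spec$predict(theta_c), error = function(e) NULL)
      if (!is.null(g_c) && all(is.finite(g_c))) {
        e_c <- as.numeric(data - g_c)
        F_cand <- evaluate_F(e_c, J, S_new, theta_c, lambda)
        if (is.finite(F_cand) && F_cand >= F_curr) {
          accepted <- TRUE
        }
        # within-expansion improvement: move on even if the re-expanded F
        # level sits below the recorded best (re-expansion drift)
        if (is.finite(F_cand) && F_cand >= F_curr_eval + s$tol) {
          improved_local <- TRUE
        }
        if (accepted || improved_local) {
          theta <- theta_c
          g <- g_c
          break
        }
      }
      step <- step / 2
    }

    if (s$verbose) {
      cat(sprintf("iter %3d: F_at_theta %.3f F_cand %.3f accepted %s step %.4g lambda %s\n",
                  iter, F_curr_eval, F_cand, accepted, step,
                  paste(round(lambda, 2), collapse = "/")))
    }
    if (accepted) {
      dF <- F_cand - F_curr
      F_curr <- F_cand
      S <- S_new
      best <- list(theta = theta, S = S_new, lambda = lambda, g = g)
      F_trace <- c(F_trace, F_curr)
      below <- if (dF < s$tol) below + 1L else 0L
      if (below >= s$tol_count) { converged <- TRUE; break }
    } else if (improved_local) {
      S <- S_new
    } else {
      # the current expansion cannot be improved: at a mode
      if (is.finite(F_cand) || is.finite(F_curr_eval)) {
        converged <- TRUE
        break
      }
      stop("line search failed at iteration ", iter,
           ": free energy could not be increased (current F = ",
           format(F_curr, digits = 6), ")")
    }
  }

  # report the best recorded point
  theta <- best$theta
  S <- best$S
  lambda <- best$lambda
  g <- best$g

  evec <- matrix(as.numeric(data - g), n, N)
  ss_tot <- sum((data - rowMeans(data))^2)
  r2 <- if (ss_tot > 0) 1 - sum(evec^2) / ss_tot else NA_real_
  theta <- stats::setNames(as.numeric(theta), spec$names)
  dimnames(S) <- list(spec$names, spec$names)
  structure(list(mean = theta, cov = S, free_energy = F_curr,
                 lambda = lambda,
                 prior = list(mean = mu0,
                              cov = diag(spec$prior$variance, p,
                                         p) |> `dimnames<-`(list(spec$names,
                                                                 spec$names))),
                 diagnostics = list(iterations = iter, F_trace = F_trace,
                                    explained_variance = r2,
                                    converged = converged),
                 spec = spec),
            class = "fes_posterior")
}

# Sum of squares per region for a region-major vectorized residual.
region_rowsums <- function(v2, n) {
  rowSums(matrix(v2, n))
}

as_region_matrix <- function(data, regions) {
  data <- as.matrix(data)
  n <- length(regions)
  if (nrow(data) != n && ncol(data) == n) data <- t(data)
  if (nrow(data) != n) stop("data must have ", n, " regions on one dimension")
  data
}

#' @export
print.fes_posterior <- function(x, ...) {
  cat("DCM posterior over", length(x$mean), "parameters; F =",
      format(x$free_energy, digits = 8), "\n")
  cat("  iterations:", x$diagnostics$iterations,
      "| explained variance:",
      format(x$diagnostics$explained_variance, digits = 3),
      "| converged:", x$diagnostics$converged, "\n")
  invisible(x)
}

#' Predicted response at the posterior mean
#'
#' Forward-simulates the model at the posterior mean; used for
#' explained-variance diagnostics and posterior predictive checks.
#'
#' @param object a `fes_posterior` from [invert()].
#' @param ... unused.
#' @return regions x time matrix.
#' @export
predict.fes_posterior <- function(object, ...) {
  y <- object$spec$predict(object$mean)
  rownames(y) <- object$spec$regions
  y
}
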