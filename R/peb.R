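#' Second-level (between-subject) design matrix
#'
#' Builds the group design over subject-sessions. Controls are modeled with a
#' single mean regressor. Patients get, in addition, a carryover regressor
#' (CE = +1, nCE = -1), a time regressor (PRE = +1, POST = -1) and a
#' capacity-score regressor; capacity scores are mean-corrected and scaled by
#' their maximum absolute deviation so the column lies in [-1, 1] (a column
#' of zeros when all scores are equal).
#'
#' @param records data.frame with columns `id`, `cohort` ("control" or
#'   "patient"), and for patients `carryover` (+1/-1), `timepoint` (+1/-1),
#'   `capacity_score` (raw units).
#' @param regressors character subset of
#'   `c("mean", "carryover", "time", "capacity")`.
#' @return object of class `fes_peb_design`: list with `X` (matrix, one row
#'   per subject-session ordered by (id, session)), `records` (reordered).
#' @export
build_design <- function(records,
                         regressors = c("mean", "carryover", "time",
                                        "capacity")) {
  regressors <- match.arg(regressors, several.ok = TRUE)
  stopifnot(all(c("id", "cohort") %in% names(records)))
  is_control <- all(records$cohort == "control")
  if (is_control && !identical(regressors, "mean")) {
    if (!all(regressors %in% "mean")) {
      stop("controls are modeled with a single mean regressor; requested: ",
           paste(regressors, collapse = ", "))
    }
  }
  ord <- if ("timepoint" %in% names(records)) {
    order(records$id, -replace(records$timepoint,
                               is.na(records$timepoint), 0))
  } else {
    order(records$id)
  }
  records <- records[ord, , drop = FALSE]
  cols <- list()
  if ("mean" %in% regressors) cols$mean <- rep(1, nrow(records))
  if ("carryover" %in% regressors) {
    if (!"carryover" %in% names(records) || anyNA(records$carryover)) {
      stop("carryover labels missing for some rows")
    }
    stopifnot(all(records$carryover %in% c(-1, 1)))
    cols$carryover <- records$carryover
  }
  if ("time" %in% regressors) {
    if (!"timepoint" %in% names(records) || anyNA(records$timepoint)) {
      stop("timepoint labels missing for some rows")
    }
    stopifnot(all(records$timepoint %in% c(-1, 1)))
    cols$time <- records$timepoint
  }
  if ("capacity" %in% regressors) {
    if (!"capacity_score" %in% names(records) ||
        anyNA(records$capacity_score)) {
      stop("capacity scores missing for some rows")
    }
    cols$capacity <- normalize_capacity(records$capacity_score)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- paste0(records$id,
                        ifelse(rep("timepoint" %in% names(records),
                                   nrow(records)) & !is.na(records$timepoint),
                               ifelse(records$timepoint > 0, ":PRE", ":POST"),
                               ""))
  structure(list(X = X, records = records), class = "fes_peb_design")
}

#' Mean-correct and scale capacity scores into [-1, 1]
#'
#' Subtracts the cohort mean and divides by the maximum absolute deviation;
#' returns all zeros when the scores are constant.
#'
#' @param scores numeric raw capacity scores.
#' @return normalized scores in [-1, 1].
#' @export
normalize_capacity <- function(scores) {
  if (length(scores) == 0) return(numeric(0))
  d <- scores - mean(scores)
  m <- max(abs(d))
  if (m == 0) return(d)
  d / m
}

#' Fit a parametric-empirical-Bayes model over first-level posteriors
#'
#' Hierarchical general linear model: first-level parameters (one field of
#' the DCM: A, B or C) are modeled as random effects around design-predicted
#' group values with additive Gaussian between-subject variability. Each
#' first-level posterior is converted to its Gaussian likelihood summary
#' (posterior precision minus prior precision), so the hierarchy is
#' linear-Gaussian and the second-level coefficient posterior is available in
#' closed form; the between-subject log-precision is estimated by 1-D
#' free-energy ascent with hyperprior N(0, 1/16).
#'
#' @param first_level list of `fes_posterior` objects sharing one
#'   parameterization, aligned with the design rows.
#' @param design a [build_design()] object (or a bare design matrix).
#' @param field `"A"`, `"B"` or `"C"` — which first-level field the second
#'   level models.
#' @param expected_variance_fraction between-subject prior variance as a
#'   fraction of the first-level prior variance (default 1/16).
#' @return object of class `fes_peb`: `beta` (matrix, connections x
#'   regressors), `cov` (posterior covariance of vec(beta), regressor-major
#'   blocks), `free_energy`, `gamma` (between-subject log-precision),
#'   `subject_means` (empirical-Bayes updated first-level means),
#'   `connections`, `regressors`, `prior` (on vec(beta)).
#' @export
fit_peb <- function(first_level, design, field = c("B", "A", "C"),
                    expected_variance_fraction = 1 / 16) {
  field <- match.arg(field)
  X <- if (inherits(design, "fes_peb_design")) design$X else as.matrix(design)
  ns <- length(first_level)
  if (nrow(X) != ns) {
    stop("design has ", nrow(X), " rows but ", ns, " posteriors supplied")
  }
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design matrix (columns: ",
         paste(colnames(X), collapse = ", "), ")")
  }
  nm_all <- names(first_level[[1]]$mean)
  sel <- which(startsWith(nm_all, paste0(field, ":")))
  if (!length(sel)) stop("no free parameters in field ", field)
  conn <- nm_all[sel]
  p <- length(sel)
  k <- ncol(X)
  regr <- colnames(X)

  mu0 <- first_level[[1]]$prior$mean[sel]
  S0 <- as.matrix(first_level[[1]]$prior$cov)[sel, sel, drop = FALSE]
  P0 <- chol2inv(chol(S0))

  # Gaussian likelihood summary of each subject: precision and natural mean
  summ <- lapply(first_level, function(po) {
    if (!identical(names(po$mean), nm_all)) {
      stop("first-level posteriors do not share a parameterization")
    }
    S <- as.matrix(po$cov)[sel, sel, drop = FALSE]
    Pq <- chol2inv(chol((S + t(S)) / 2))
    Pi <- (Pq + t(Pq)) / 2 - P0
    es <- eigen(Pi, symmetric = TRUE)
    es$values <- pmax(es$values, 0)   # marginal precision is PSD in theory
    Pi <- es$vectors %*% (es$values * t(es$vectors))
    bi <- as.numeric(Pq %*% po$mean[sel] - P0 %*% mu0)
    list(P = Pi, b = bi)
  })

  D <- expected_variance_fraction * diag(S0)  # between-subject base variance
  beta0 <- as.numeric(outer(mu0, c(1, numeric(k - 1))))  # prior mean of beta
  Sbeta0 <- diag(rep(diag(S0), k), p * k)

  fe_of_gamma <- function(gamma, want_fit = FALSE) {
    Sb_inv <- diag(exp(gamma) / D, p)
    logdet_Sb <- sum(log(D)) - p * gamma
    H <- matrix(0, p * k, p * k)
    h <- numeric(p * k)
    csum <- 0
    sub <- vector("list", ns)
    for (i in seq_len(ns)) {
      M <- summ[[i]]$P + Sb_inv
      Minv <- chol2inv(chol((M + t(M)) / 2))
      G <- Sb_inv - Sb_inv %*% Minv %*% Sb_inv
      g <- as.numeric(Sb_inv %*% Minv %*% summ[[i]]$b)
      csum <- csum + 0.5 * sum(summ[[i]]$b * (Minv %*% summ[[i]]$b)) -
        0.5 * determinant_psd(M) - 0.5 * logdet_Sb
      xi <- X[i, ]
      H <- H + kronecker(outer(xi, xi), G)
      h <- h + as.numeric(kronecker(xi, diag(p)) %*% g)
      if (want_fit) sub[[i]] <- list(Minv = Minv)
    }
    Pb0 <- chol2inv(chol(Sbeta0))
    Pb <- Pb0 + H
    Pb <- (Pb + t(Pb)) / 2
    r <- h + as.numeric(Pb0 %*% beta0)
    Sb_post <- chol2inv(chol(Pb))
    mb <- as.numeric(Sb_post %*% r)
    F <- csum - 0.5 * determinant_psd(Sbeta0) - 0.5 * determinant_psd(Pb) -
      0.5 * sum(beta0 * (Pb0 %*% beta0)) + 0.5 * sum(r * mb) -
      0.5 * gamma^2 / (1 / 16)
    if (!want_fit) return(F)
    list(F = F, beta = mb, Sb_post = Sb_post, sub = sub, Sb_inv = Sb_inv)
  }

  opt <- stats::optimize(fe_of_gamma, interval = c(-4, 6), maximum = TRUE,
                         tol = 1e-4)
  fit <- fe_of_gamma(opt$maximum, want_fit = TRUE)

  beta <- matrix(fit$beta, p, k, dimnames = list(conn, regr))
  # empirical-Bayes updated subject-level means given the group coefficients
  subject_means <- t(vapply(seq_len(ns), function(i) {
    a <- as.numeric(beta %*% X[i, ])
    as.numeric(fit$sub[[i]]$Minv %*% (summ[[i]]$b + fit$Sb_inv %*% a))
  }, numeric(p)))
  colnames(subject_means) <- conn

  structure(list(beta = beta,
                 cov = `dimnames<-`(fit$Sb_post,
                                    list(vec_names(conn, regr),
                                         vec_names(conn, regr))),
                 free_energy = fit$F, gamma = opt$maximum,
                 subject_means = subject_means,
                 group_predicted = X %*% t(beta),
                 connections = conn, regressors = regr, field = field,
                 design = X,
                 prior = list(mean = stats::setNames(beta0,
                                                     vec_names(conn, regr)),
                              cov = Sbeta0),
                 between_var = D / exp(opt$maximum)),
            class = "fes_peb")
}

vec_names <- function(conn, regr) {
  as.character(outer(conn, regr, function(a, b) paste0(b, "|", a)))
}

#' @export
print.fes_peb <- function(x, ...) {
  cat("PEB fit over", length(x$connections), "connections x",
      length(x$regressors), "regressors (field", x$field, "); F =",
      format(x$free_energy, digits = 8), "\n")
  print(round(x$beta, 3))
  invisible(x)
}

#' Group estimates from explicit coefficients
#'
#' Constructs a minimal group-estimates object (as produced by [fit_peb()])
#' from given coefficients, e.g. to evaluate the regressor-combination rule
#' for reported values.
#'
#' @param beta matrix of coefficients (connections x regressors) with
#'   dimnames, or a named vector for a single connection.
#' @param connection connection name when `beta` is a vector.
#' @return object of class `fes_peb` (coefficients only).
#' @export
group_estimates <- function(beta, connection = "connection") {
  if (is.vector(beta)) {
    beta <- matrix(beta, nrow = 1,
                   dimnames = list(connection, names(beta)))
  }
  structure(list(beta = beta, connections = rownames(beta),
                 regressors = colnames(beta)),
            class = "fes_peb")
}

#' Combine regressor contributions into a connection magnitude
#'
#' The overall magnitude of a connection for a given subgroup and time point
#' is the signed sum of the regressor contributions:
#' theta_mean + carryover * theta_CE + timepoint * theta_t +
#' capacity * theta_CS. Regressors absent from the design contribute zero.
#'
#' @param estimates a `fes_peb` object (from [fit_peb()], a search BMA, or
#'   [group_estimates()]).
#' @param connection connection name (row of the coefficient matrix).
#' @param carryover +1 (CE) or -1 (nCE); 0 if not applicable.
#' @param timepoint +1 (PRE) or -1 (POST); 0 if not applicable.
#' @param capacity normalized capacity score in [-1, 1].
#' @return combined connection magnitude, Hz.
#' @examples
#' ge <- group_estimates(c(carryover = -0.39, time = 0.51), "B:E:SMA->M1")
#' combine_contributions(ge, "B:E:SMA->M1", carryover = 1, timepoint = 1)
#' # 0.12
#' @export
combine_contributions <- function(estimates, connection, carryover = 0,
                                  timepoint = 0, capacity = 0) {
  if (!connection %in% rownames(estimates$beta)) {
    stop("unknown connection: ", connection)
  }
  b <- estimates$beta[connection, ]
  get <- function(name) if (name %in% names(b)) b[[name]] else 0
  get("mean") + carryover * get("carryover") + timepoint * get("time") +
    capacity * get("capacity")
}

#' Exhaustive second-level search with Bayesian model averaging
#'
#' Switches named connections on/off at the second level (off = all of the
#' connection's group coefficients pinned to their prior mean with near-zero
#' variance), scores every pattern by Bayesian model reduction of the fitted
#' PEB posterior, and averages the retained models (smallest set with
#' cumulative posterior probability >= `occam_mass`).
#'
#' @param estimates a [fit_peb()] object.
#' @param switchable character vector of connection names to switch; default
#'   all fitted connections.
#' @param cap maximum number of models for exhaustive enumeration; above the
#'   cap a greedy backward search is used instead.
#' @param occam_mass cumulative probability defining the retained set.
#' @return list with `bma` (a `fes_peb` with averaged coefficients),
#'   `inclusion_prob` (per switchable connection), `models` (switch patterns
#'   with F and probability), `method` ("exhaustive" or "greedy").
#' @export
peb_search <- function(estimates, switchable = NULL, cap = 4096,
                       occam_mass = 0.95) {
  if (is.null(switchable)) switchable <- estimates$connections
  stopifnot(all(switchable %in% estimates$connections))
  post <- list(mean = stats::setNames(as.numeric(estimates$beta),
                                      names(estimates$prior$mean)),
               cov = estimates$cov)
  if (2^length(switchable) <= cap) {
    grid <- enumerate_reduced_models(switchable, cap)
    red <- lapply(seq_len(nrow(grid)), function(i) {
      off <- switchable[which(grid[i, ] == 0)]
      bmr_pin_connections(estimates, post, off)
    })
    Fv <- vapply(red, function(r) r$dF, 0)
    prob <- model_posteriors(Fv)
    keep <- occam_window(prob, occam_mass)
    bma <- bayesian_model_average(red[keep], prob[keep] / sum(prob[keep]))
    incl <- vapply(switchable, function(cn) {
      sum(prob[grid[[cn]] == 1])
    }, 0)
    models <- cbind(grid, F = Fv, probability = prob)
    method <- "exhaustive"
  } else {
    # greedy backward elimination scored by BMR
    on <- stats::setNames(rep(TRUE, length(switchable)), switchable)
    best <- bmr_pin_connections(estimates, post, character(0))
    repeat {
      cand <- names(on)[on]
      if (!length(cand)) break
      dFs <- vapply(cand, function(cn) {
        bmr_pin_connections(estimates, post,
                            c(names(on)[!on], cn))$dF
      }, 0)
      i <- which.max(dFs)
      if (dFs[i] > best$dF) {
        on[cand[i]] <- FALSE
        best <- bmr_pin_connections(estimates, post, names(on)[!on])
      } else break
    }
    # inclusion probability via the pairwise on/off comparison at the winner
    incl <- vapply(switchable, function(cn) {
      off_rest <- setdiff(names(on)[!on], cn)
      f_on <- bmr_pin_connections(estimates, post, off_rest)$dF
      f_off <- bmr_pin_connections(estimates, post, c(off_rest, cn))$dF
      model_posteriors(c(f_on, f_off))[1]
    }, 0)
    bma <- list(mean = best$mean, cov = best$cov, weights = 1, retained = 1L)
    models <- data.frame(pattern = paste(as.integer(on), collapse = ""),
                         F = best$dF, probability = 1)
    method <- "greedy"
  }
  out_beta <- matrix(bma$mean, length(estimates$connections),
                     length(estimates$regressors),
                     dimnames = list(estimates$connections,
                                     estimates$regressors))
  bma_est <- structure(list(beta = out_beta, cov = bma$cov,
                            connections = estimates$connections,
                            regressors = estimates$regressors,
                            field = estimates$field,
                            free_energy = estimates$free_energy,
                            prior = estimates$prior),
                       class = "fes_peb")
  list(bma = bma_est, inclusion_prob = incl, models = models, method = method)
}

# Reduced prior pinning all regressor coefficients of the given connections
# to their prior mean (0 off-diagonal; the shrinkage mean for the mean
# regressor of self-connections) with near-zero variance.
bmr_pin_connections <- function(estimates, post, off_connections,
                                pinned_var = 1e-8) {
  pr <- estimates$prior
  vr <- diag(pr$cov)
  if (length(off_connections)) {
    off_idx <- which(sub("^.*\\|", "", names(pr$mean)) %in% off_connections)
    vr[off_idx] <- pinned_var
  }
  bayesian_model_reduction(list(mean = pr$mean, cov = pr$cov), post,
                           list(mean = pr$mean,
                                cov = diag(vr, length(vr))))
}

#' Compare explicit second-level candidate structures
#'
#' Scores a list of named candidate structures (each a character vector of
#' connections that are ON; all other switchable connections pinned) by
#' Bayesian model reduction, returning posterior model probabilities.
#'
#' @param estimates a [fit_peb()] object.
#' @param candidates named list; each element a character vector of
#'   connections present in that candidate.
#' @param switchable the universe of connections the candidates toggle
#'   (default: union of all candidates).
#' @return list with `probabilities`, `F` (named), `reduced` (posteriors),
#'   `winner` (name of the MAP candidate).
#' @export
peb_compare <- function(estimates, candidates, switchable = NULL) {
  if (is.null(switchable)) switchable <- unique(unlist(candidates))
  post <- list(mean = stats::setNames(as.numeric(estimates$beta),
                                      names(estimates$prior$mean)),
               cov = estimates$cov)
  red <- lapply(candidates, function(onset) {
    bmr_pin_connections(estimates, post, setdiff(switchable, onset))
  })
  Fv <- vapply(red, function(r) r$dF, 0)
  prob <- model_posteriors(Fv)
  list(probabilities = prob, F = Fv, reduced = red,
       winner = names(candidates)[which.max(Fv)])
}
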