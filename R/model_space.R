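#' Posterior model probabilities from free energies
#'
#' Softmax of the free energies under uniform model priors. Invariant to
#' adding a constant to all free energies.
#'
#' @param F numeric vector of free energies (nats), optionally named.
#' @return probability vector summing to 1.
#' @export
model_posteriors <- function(F) {
  if (length(F) == 0) stop("empty free-energy vector")
  if (any(!is.finite(F))) stop("free energies must be finite")
  z <- F - max(F)
  p <- exp(z) / sum(exp(z))
  names(p) <- names(F)
  p
}

#' Bayesian model reduction
#'
#' Analytic posterior and evidence change for a model with a different
#' (reduced) prior, computed from a fitted full model without re-visiting the
#' data. Exact for Gaussian prior/posterior pairs; parameters are switched
#' off by pinning their reduced prior variance near zero.
#'
#' @param full_prior list with `mean` and `cov` (or `variance`).
#' @param full_posterior list with `mean` and `cov` (e.g. a `fes_posterior`).
#' @param reduced_prior list with `mean` and `cov` (or `variance`).
#' @return list with `mean`, `cov` (reduced posterior) and `dF` (nats;
#'   evidence of the reduced model minus evidence of the full model).
#' @export
bayesian_model_reduction <- function(full_prior, full_posterior, reduced_prior) {
  as_cov <- function(x, p) {
    if (!is.null(x$cov)) as.matrix(x$cov) else diag(x$variance, p)
  }
  mu0 <- full_prior$mean
  p <- length(mu0)
  S0 <- as_cov(full_prior, p)
  mu <- full_posterior$mean
  S <- as_cov(full_posterior, p)
  mur <- reduced_prior$mean
  Sr <- as_cov(reduced_prior, p)

  P0 <- chol2inv(chol(S0))
  Pq <- chol2inv(chol((S + t(S)) / 2))
  Pr <- chol2inv(chol(Sr))
  Pred <- Pq - P0 + Pr
  Pred <- (Pred + t(Pred)) / 2
  ev <- eigen(Pred, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("reduced posterior precision is not positive definite ",
         "(min eigenvalue ", format(min(ev), digits = 4),
         ", condition number ", format(max(ev) / abs(min(ev)), digits = 4), ")")
  }
  h <- as.numeric(Pq %*% mu - P0 %*% mu0 + Pr %*% mur)
  Sred <- chol2inv(chol(Pred))
  mured <- as.numeric(Sred %*% h)
  dF <- 0.5 * (determinant_psd(Pq) + determinant_psd(Pr) -
                 determinant_psd(P0) - determinant_psd(Pred)) +
    0.5 * (sum(h * mured) -
             as.numeric(t(mu) %*% Pq %*% mu) -
             as.numeric(t(mur) %*% Pr %*% mur) +
             as.numeric(t(mu0) %*% P0 %*% mu0))
  nm <- names(mu)
  list(mean = stats::setNames(mured, nm),
       cov = `dimnames<-`(Sred, list(nm, nm)), dF = dF)
}

#' Bayesian model average
#'
#' Moment-matched Gaussian mixture over a set of model posteriors. Models
#' with probability below `occam_min_prob` are dropped and the remaining
#' probabilities renormalized. The BMA mean is the probability-weighted mean;
#' the covariance is the within- plus between-model covariance of the
#' truncated mixture.
#'
#' @param posteriors list of posteriors (each with `mean` and `cov`).
#' @param probabilities numeric vector matching `posteriors`, summing to 1.
#' @param occam_min_prob minimum model probability retained (default 0).
#' @return list with `mean`, `cov`, `weights` (renormalized) and `retained`
#'   (indices of retained models).
#' @export
bayesian_model_average <- function(posteriors, probabilities,
                                   occam_min_prob = 0) {
  stopifnot(length(posteriors) == length(probabilities))
  if (abs(sum(probabilities) - 1) > 1e-8) {
    stop("model probabilities must sum to 1")
  }
  keep <- which(probabilities >= occam_min_prob)
  if (length(keep) == 0) {
    stop("no model reaches the Occam threshold ", occam_min_prob)
  }
  w <- probabilities[keep] / sum(probabilities[keep])
  mu <- Reduce(`+`, Map(function(po, wi) wi * po$mean, posteriors[keep],
                        as.list(w)))
  cov <- Reduce(`+`, Map(function(po, wi) {
    d <- po$mean - mu
    wi * (as.matrix(po$cov) + outer(d, d))
  }, posteriors[keep], as.list(w)))
  list(mean = mu, cov = cov, weights = w, retained = keep)
}

# Smallest set of models whose cumulative posterior probability reaches
# `mass` (standard Occam's-window behavior for "best performing models").
occam_window <- function(probabilities, mass = 0.95) {
  ord <- order(probabilities, decreasing = TRUE)
  cum <- cumsum(probabilities[ord])
  k <- which(cum >= mass)[1]
  if (is.na(k)) k <- length(ord)
  sort(ord[seq_len(k)])
}

#' Enumerate reduced models over a switchable parameter subset
#'
#' All on/off combinations of the switchable parameters; fixed parameters are
#' always on.
#'
#' @param switchable character vector (or count) of switchable parameter
#'   names.
#' @param cap maximum number of models; exceeding it raises an error
#'   suggesting greedy/pruned search.
#' @return data.frame of 0/1 switches, one row per model, one column per
#'   switchable parameter, with a model `id` attribute column.
#' @export
enumerate_reduced_models <- function(switchable, cap = 4096) {
  k <- if (is.character(switchable)) length(switchable) else as.integer(switchable)
  if (2^k > cap) {
    stop("2^", k, " = ", 2^k, " models exceeds the cap (", cap,
         "); use greedy/pruned search instead")
  }
  if (k == 0) {
    out <- data.frame(row.names = "full")
    attr(out, "n_models") <- 1L
    return(out)
  }
  grid <- expand.grid(rep(list(c(1, 0)), k))
  names(grid) <- if (is.character(switchable)) switchable else
    paste0("p", seq_len(k))
  rownames(grid) <- apply(grid, 1, paste, collapse = "")
  attr(grid, "n_models") <- nrow(grid)
  grid
}
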