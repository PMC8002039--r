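#' Bilinear connectivity model (A, B, C matrices)
#'
#' Container for the bilinear state equation
#' \deqn{\dot x = (A + \sum_j u_j B^{(j)}) x + C u}
#' where `A` holds endogenous coupling (Hz), each `B[[j]]` the modulation of
#' coupling by input j (Hz per unit input), and `C` the direct driving
#' influence of inputs on regions (Hz per unit input).
#'
#' Convention used everywhere (including serialization):
#' `A[target, source]`, i.e. row = target region, column = source region.
#'
#' @param A n x n endogenous coupling matrix, Hz. Diagonal (self-decay) must
#'   be strictly negative.
#' @param B list of n x n modulation matrices, one per input (zero matrices
#'   for non-modulatory inputs). A single matrix is accepted when there is
#'   one input.
#' @param C n x m driving-input matrix.
#' @param regions character vector of region labels (default
#'   `c("M1","S1","SMA","AG")`).
#' @param inputs character vector of input labels (default `c("V","E","P")`).
#' @param masks optional list of binary structure masks (`A`, `B` list, `C`);
#'   defaults to the nonzero pattern of the matrices with the full A
#'   diagonal. Masked-out entries are forced to zero.
#' @param check_stable if TRUE (default) error when A has an eigenvalue with
#'   nonnegative real part.
#' @return an object of class `fes_dcm_model`.
#' @export
connectivity_model <- function(A, B = NULL, C = NULL,
                               regions = c("M1", "S1", "SMA", "AG"),
                               inputs = c("V", "E", "P"),
                               masks = NULL, check_stable = TRUE) {
  n <- length(regions)
  m <- length(inputs)
  A <- as.matrix(A)
  if (!all(dim(A) == c(n, n))) stop("A must be ", n, "x", n)
  if (is.null(C)) C <- matrix(0, n, m)
  C <- as.matrix(C)
  if (!all(dim(C) == c(n, m))) stop("C must be ", n, "x", m)
  if (is.null(B)) B <- replicate(m, matrix(0, n, n), simplify = FALSE)
  if (is.matrix(B)) B <- list(B)
  if (length(B) != m) stop("B must supply one matrix per input (", m, ")")
  B <- lapply(B, function(b) {
    b <- as.matrix(b)
    if (!all(dim(b) == c(n, n))) stop("each B matrix must be ", n, "x", n)
    b
  })
  dimnames(A) <- list(regions, regions)
  dimnames(C) <- list(regions, inputs)
  for (j in seq_len(m)) dimnames(B[[j]]) <- list(regions, regions)
  names(B) <- inputs

  if (is.null(masks)) {
    masks <- list(
      A = (A != 0) * 1,
      B = lapply(B, function(b) (b != 0) * 1),
      C = (C != 0) * 1
    )
    diag(masks$A) <- 1  # self-connections always part of the model
  }
  # masked-out entries are exactly zero
  A <- A * (masks$A != 0)
  C <- C * (masks$C != 0)
  for (j in seq_len(m)) B[[j]] <- B[[j]] * (masks$B[[j]] != 0)

  if (any(diag(A) >= 0)) {
    stop("self-connections (diagonal of A) must be strictly negative; got ",
         paste(round(diag(A), 3), collapse = ", "))
  }
  if (check_stable) {
    st <- check_stability(A)
    if (!st$stable) {
      stop("A is unstable: eigenvalue with real part ",
           format(st$max_real, digits = 4), " >= 0")
    }
  }
  structure(list(regions = regions, inputs = inputs,
                 A = A, B = B, C = C, masks = masks),
            class = "fes_dcm_model")
}

#' @export
print.fes_dcm_model <- function(x, ...) {
  cat("Bilinear DCM over", length(x$regions), "regions (",
      paste(x$regions, collapse = ", "), ") and inputs",
      paste(x$inputs, collapse = ", "), "\n")
  cat("  free entries: A", sum(x$masks$A != 0),
      "| B", sum(vapply(x$masks$B, function(b) sum(b != 0), 0)),
      "| C", sum(x$masks$C != 0), "\n")
  invisible(x)
}

#' Stability check of an endogenous coupling matrix
#'
#' A bilinear model is dynamically stable at rest when all eigenvalues of A
#' have negative real part.
#'
#' @param A square coupling matrix.
#' @return list with `stable` (logical), `eigenvalues`, `max_real`.
#' @export
check_stability <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  ev <- eigen(A, only.values = TRUE)$values
  list(stable = all(Re(ev) < 0), eigenvalues = ev, max_real = max(Re(ev)))
}

#' Canonical hemodynamic (balloon-windkessel) parameters
#'
#' Per-region rate constants of the standard 4-state hemodynamic model plus
#' global BOLD observation constants. Defaults are the canonical values:
#' signal decay 0.64 1/s, autoregulation 0.32 1/s, transit time 2 s, vessel
#' stiffness 0.32, resting oxygen extraction 0.4, intra/extravascular ratio
#' epsilon 1, echo time 0.05 s, resting venous volume fraction 4%.
#'
#' @param n number of regions.
#' @param decay,autoregulation per-region rates, 1/s.
#' @param transit per-region mean transit time, s.
#' @param stiffness Grubb vessel stiffness exponent, in (0, 1].
#' @param extraction resting oxygen extraction fraction, in (0, 1).
#' @param epsilon intravascular/extravascular signal ratio (dimensionless).
#' @param te echo time, s.
#' @param v0 resting venous blood volume fraction, percent.
#' @return list of class `fes_hemo` with per-region vectors.
#' @export
hemodynamic_params <- function(n, decay = 0.64, autoregulation = 0.32,
                               transit = 2, stiffness = 0.32,
                               extraction = 0.4, epsilon = 1,
                               te = 0.05, v0 = 4) {
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else x
  p <- list(decay = rep_n(decay), autoregulation = rep_n(autoregulation),
            transit = rep_n(transit), stiffness = rep_n(stiffness),
            extraction = rep_n(extraction), epsilon = epsilon,
            te = te, v0 = v0)
  stopifnot(all(p$decay > 0), all(p$autoregulation > 0), all(p$transit > 0),
            all(p$stiffness > 0 & p$stiffness <= 1),
            all(p$extraction > 0 & p$extraction < 1))
  class(p) <- "fes_hemo"
  p
}

# Names of the free parameters of a model, in packing order:
# A entries (column-major within mask), then B per modulatory input, then C,
# in "field:source->target"-style labels.
connection_names <- function(masks, regions, inputs) {
  nm <- character(0)
  idx <- which(masks$A != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    nm <- c(nm, paste0("A:", regions[idx[, 2]], "->", regions[idx[, 1]]))
  }
  for (j in seq_along(masks$B)) {
    idx <- which(masks$B[[j]] != 0, arr.ind = TRUE)
    if (nrow(idx)) {
      nm <- c(nm, paste0("B:", inputs[j], ":", regions[idx[, 2]], "->",
                         regions[idx[, 1]]))
    }
  }
  idx <- which(masks$C != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    nm <- c(nm, paste0("C:", inputs[idx[, 2]], "->", regions[idx[, 1]]))
  }
  nm
}
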