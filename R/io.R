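#' Serialize a connectivity model to JSON
#'
#' Writes region/input labels, the dense A/B/C matrices and the structure
#' masks. The `A[target, source]` convention applies to the serialized
#' matrices as well.
#'
#' @param model a [connectivity_model()].
#' @param path output path; if NULL the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  x <- list(regions = model$regions, inputs = model$inputs,
            A = model$A, B = model$B, C = model$C,
            masks = model$masks,
            convention = "A[target, source]")
  if (is.null(path)) return(jsonlite::toJSON(x, digits = NA))
  jsonlite::write_json(x, path, digits = NA)
  invisible(path)
}

#' Read a connectivity model from JSON
#' @param path file written by [model_to_json()].
#' @return a [connectivity_model()].
#' @export
model_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(x$regions)
  as_mat <- function(b) matrix(as.numeric(b), nrow = n)
  masks <- list(A = as_mat(x$masks$A),
                B = lapply(x$masks$B, as_mat),
                C = matrix(as.numeric(x$masks$C), nrow = n))
  connectivity_model(as_mat(x$A), lapply(x$B, as_mat),
                     matrix(as.numeric(x$C), nrow = n),
                     x$regions, x$inputs, masks = masks)
}

#' Write simulated series as TSV with a sidecar JSON
#'
#' One column per region, one row per volume; the sidecar records tr, seed
#' and noise sd.
#'
#' @param series regions x volumes matrix.
#' @param path output TSV path (sidecar written next to it as `.json`).
#' @param tr repetition time, s.
#' @param seed,noise_sd provenance recorded in the sidecar.
#' @export
series_to_tsv <- function(series, path, tr = 3, seed = NA, noise_sd = NA) {
  df <- as.data.frame(t(series))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tr = tr, seed = seed, noise_sd = noise_sd),
                       sub("\\.tsv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a series TSV (volumes x regions) into a regions x volumes matrix
#' @param path TSV written by [series_to_tsv()].
#' @export
series_from_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  t(as.matrix(df))
}

#' Serialize a posterior to JSON (mean, covariance, free energy, diagnostics)
#' @param posterior a `fes_posterior`.
#' @param path output path.
#' @export
posterior_to_json <- function(posterior, path) {
  jsonlite::write_json(
    list(mean = as.list(posterior$mean),
         cov = posterior$cov,
         free_energy = posterior$free_energy,
         lambda = posterior$lambda,
         diagnostics = posterior$diagnostics[c("iterations",
                                               "explained_variance",
                                               "converged")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write subject records as CSV
#' @param records the `records` data.frame of a cohort.
#' @param path output path.
#' @export
records_to_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
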