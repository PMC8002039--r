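#' Experimental paradigm: 2x2 volitional-by-FES block design
#'
#' Builds the scan timeline of a block paradigm in which OFF (rest) and ON
#' (movement) blocks alternate for the whole run, and every ON block carries
#' one of the task conditions. The default study design is a 10-minute run at
#' TR 3 s with 20 alternating 9 s OFF / 21 s ON block pairs and four
#' conditions (volitional+FES, FES alone, volitional alone, passive
#' movement), movements paced every 3.5 s.
#'
#' Conditions are allocated to ON blocks in balanced counts (each condition
#' gets the same number of blocks) in a seed-reproducible pseudo-random
#' order.
#'
#' @param tr repetition time, seconds per volume.
#' @param run_duration total run length in seconds; must be an integer
#'   multiple of `block_off + block_on`.
#' @param block_off,block_on OFF and ON block durations in seconds.
#' @param n_conditions number of task conditions; must divide the block-pair
#'   count. Defaults to the four conditions of the 2x2 design.
#' @param seed integer seed controlling the condition permutation.
#' @param pace_interval movement pacing interval within ON blocks, seconds.
#' @param microtime_dt input sampling resolution in seconds (default
#'   `tr / 16`).
#' @return an object of class `fes_paradigm` with fields `tr`,
#'   `run_duration`, `n_volumes`, `block_off`, `block_on`, `pace_interval`,
#'   `conditions`, `block_schedule` (data.frame: onset, duration, condition),
#'   `microtime_dt`.
#' @examples
#' p <- build_paradigm(3, 600, 9, 21, seed = 1)
#' p$n_volumes  # 200
#' @export
build_paradigm <- function(tr, run_duration, block_off, block_on,
                           n_conditions = 4L, seed = 1L,
                           pace_interval = 3.5, microtime_dt = tr / 16) {
  stopifnot(tr > 0, block_off + block_on > 0, microtime_dt > 0)
  cycle <- block_off + block_on
  n_pairs <- run_duration / cycle
  if (abs(n_pairs - round(n_pairs)) > 1e-9) {
    stop("run_duration (", run_duration, " s) is not an integer multiple of ",
         "block_off + block_on (", cycle, " s)")
  }
  n_pairs <- as.integer(round(n_pairs))
  if (n_pairs %% n_conditions != 0) {
    stop("n_conditions (", n_conditions, ") does not divide the block-pair ",
         "count (", n_pairs, "); balanced allocation is impossible")
  }
  conditions <- c("vol+FES", "FES", "vol", "passive")[seq_len(n_conditions)]
  if (n_conditions > 4) {
    conditions <- c(conditions, paste0("cond", 5:n_conditions))
  }
  alloc <- rep(conditions, each = n_pairs %/% n_conditions)
  alloc <- withr::with_seed(as.integer(seed), sample(alloc))
  onsets_on <- (seq_len(n_pairs) - 1) * cycle + block_off
  schedule <- data.frame(
    onset = onsets_on,
    duration = block_on,
    condition = alloc,
    stringsAsFactors = FALSE
  )
  out <- list(
    tr = tr,
    run_duration = run_duration,
    n_volumes = as.integer(floor(run_duration / tr)),
    block_off = block_off,
    block_on = block_on,
    pace_interval = pace_interval,
    conditions = conditions,
    block_schedule = schedule,
    microtime_dt = microtime_dt,
    seed = as.integer(seed)
  )
  class(out) <- "fes_paradigm"
  out
}

#' @export
print.fes_paradigm <- function(x, ...) {
  cat("Block paradigm: ", x$run_duration, " s run, TR ", x$tr, " s (",
      x$n_volumes, " volumes)\n", sep = "")
  cat("  ", nrow(x$block_schedule), " ON-OFF block pairs (",
      x$block_off, " s OFF / ", x$block_on, " s ON), conditions: ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Condition membership of the three experimental inputs:
# V (descending volitional drive) is on when volitional effort is required;
# E (FES contribution to proprioception) when the stimulator is on;
# P (proprioceptive consequences of movement) in every condition.
input_condition_map <- function() {
  list(
    V = c("vol+FES", "vol"),
    E = c("vol+FES", "FES"),
    P = c("vol+FES", "FES", "vol", "passive")
  )
}

#' Experimental input timelines V, E and P
#'
#' Derives the three input timelines from the block schedule: the driving
#' input `V` (volitional conditions only), the modulatory input `E` (FES
#' conditions only) and the driving input `P` (all conditions). Timelines are
#' sampled at the paradigm's microtime resolution, are zero during OFF
#' blocks, and have unit amplitude (scaling is absorbed by the C and B
#' matrices).
#'
#' @param paradigm a [build_paradigm()] object.
#' @param encoding `"boxcar"` (unit value across each matching ON block) or
#'   `"event"` (unit impulses of `event_duration` seconds placed every
#'   `pace_interval` seconds from block onset).
#' @param event_duration event width in seconds for `encoding = "event"`.
#' @return list with elements `V`, `E`, `P` (numeric vectors over the
#'   microtime grid), `time` (bin start times) and `dt`.
#' @export
build_inputs <- function(paradigm, encoding = c("boxcar", "event"),
                         event_duration = 1) {
  encoding <- match.arg(encoding)
  dt <- paradigm$microtime_dt
  nbin <- as.integer(round(paradigm$run_duration / dt))
  time <- (seq_len(nbin) - 1) * dt
  cmap <- input_condition_map()
  make_one <- function(conds) {
    v <- numeric(nbin)
    sched <- paradigm$block_schedule
    for (k in seq_len(nrow(sched))) {
      if (!(sched$condition[k] %in% conds)) next
      if (encoding == "boxcar") {
        on <- time >= sched$onset[k] & time < sched$onset[k] + sched$duration[k]
        v[on] <- 1
      } else {
        ev_onsets <- seq(sched$onset[k],
                         sched$onset[k] + sched$duration[k] - 1e-9,
                         by = paradigm$pace_interval)
        ev_onsets <- ev_onsets[ev_onsets < sched$onset[k] + sched$duration[k]]
        for (o in ev_onsets) {
          on <- time >= o &
            time < min(o + event_duration, sched$onset[k] + sched$duration[k])
          v[on] <- 1
        }
      }
    }
    v
  }
  list(V = make_one(cmap$V), E = make_one(cmap$E), P = make_one(cmap$P),
       time = time, dt = dt)
}

#' Serialize a paradigm to JSON
#'
#' Onsets are in seconds with the time origin at run start.
#' @param paradigm a [build_paradigm()] object.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @export
paradigm_to_json <- function(paradigm, path = NULL) {
  x <- unclass(paradigm)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Export condition onsets as a 3-column TSV (onset, duration, condition)
#' @param paradigm a [build_paradigm()] object.
#' @param path output file path.
#' @export
paradigm_to_tsv <- function(paradigm, path) {
  utils::write.table(paradigm$block_schedule, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
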