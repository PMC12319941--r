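# Seed plumbing: every stochastic operation derives its own stream from the
# config seed so that outputs are reproducible piecewise and the caller's RNG
# state is never disturbed.
derive_seed <- function(seed, ...) {
  k <- c(...)
  s <- as.double(seed) %% 2147483647
  for (x in k) s <- (s * 48271 + as.double(x)) %% 2147483647
  as.integer(s)
}

with_seed_ <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a jittered event schedule for one subject
#'
#' Produces the per-run event table of the 10-condition event-related design:
#' `reps_per_run` repetitions of each condition per run in seeded random
#' order, 2.5 s stimuli separated by inter-stimulus intervals sampled
#' uniformly from the configured ISI range (a jittered stand-in for an
#' optimized schedule), and room textures assigned to events by a seeded
#' cyclic rotation so that each room type appears for each condition within
#' one of the balanced count over the full design.
#'
#' If the drawn ISIs would overrun the run, the jitter above the minimum ISI
#' is shrunk proportionally; if even minimum-ISI packing cannot fit the run a
#' scheduling error is raised.
#'
#' @param config A [sim_config()].
#' @param subject Subject index, used only to derive the schedule's seed
#'   stream (each subject gets an independent schedule).
#' @return A tibble with columns `run`, `onset`, `duration`, `trial_type`
#'   (condition id), `room_type`, ordered by run and onset.
#' @examples
#' sched <- generate_event_schedule(sim_config(seed = 1))
#' nrow(sched) # 8 runs x 40 events
#' @export
generate_event_schedule <- function(config, subject = 1L) {
  stopifnot(inherits(config, "navaff_config"))
  reps <- config$reps_per_run
  if (reps == 0) {
    return(tibble::tibble(run = integer(), onset = double(),
                          duration = double(), trial_type = integer(),
                          room_type = integer()))
  }
  n_cond <- 10L
  run_len <- config$n_volumes * config$tr
  dur <- config$stim_duration
  isi_min <- config$isi_range[1]
  isi_max <- config$isi_range[2]
  n_ev <- n_cond * reps
  if (n_ev * (dur + isi_min) > run_len) {
    stop(sprintf(paste0("infeasible packing: %d events of %.1f s with minimum",
                        " ISI %.1f s cannot fit in a %.0f s run"),
                 n_ev, dur, isi_min, run_len), call. = FALSE)
  }
  runs <- purrr::map(seq_len(config$n_runs), function(r) {
    with_seed_(derive_seed(config$seed, 11L, subject, r), function() {
      conds <- sample(rep(seq_len(n_cond), reps))
      isi <- stats::runif(n_ev, isi_min, isi_max)
      budget <- run_len - n_ev * dur
      if (sum(isi) > budget) {
        g <- (budget - n_ev * isi_min) / (sum(isi) - n_ev * isi_min)
        isi <- isi_min + (isi - isi_min) * g
      }
      onset <- cumsum(isi) + (seq_len(n_ev) - 1) * dur
      tibble::tibble(run = r, onset = onset, duration = dur,
                     trial_type = conds)
    })
  })
  sched <- dplyr::bind_rows(runs)
  sched$room_type <- assign_rooms(sched, config, subject)
  sched
}

# Balanced cyclic room assignment: the events of each condition, in
# chronological order over the whole design, walk the 8 room types cyclically
# from a seeded per-condition starting offset. Counts per (condition, room)
# are exact when reps * n_runs divides by 8 and within +/-1 otherwise; within
# a run a condition's repetitions land in distinct rooms whenever
# reps_per_run <= 8.
assign_rooms <- function(sched, config, subject = 1L) {
  n_rooms <- 8L
  room <- integer(nrow(sched))
  offsets <- with_seed_(derive_seed(config$seed, 13L, subject), function() {
    sample(0:(n_rooms - 1), 10, replace = TRUE)
  })
  for (k in unique(sched$trial_type)) {
    idx <- which(sched$trial_type == k)
    idx <- idx[order(sched$run[idx], sched$onset[idx])]
    room[idx] <- ((offsets[k] + seq_along(idx) - 1) %% n_rooms) + 1L
  }
  room
}

#' Localizer block design and timing
#'
#' Reconstructs the category localizer's block structure: 21 blocks of 15 s
#' (16 stimulus blocks -- 4 per category, each 5 clips of 2.8 s with 0.2 s
#' ISI -- plus 5 fixation blocks at the start, end, and evenly spaced), for a
#' 315 s stimulus run acquired over `n_volumes` volumes. Category order in
#' the first block set is a seeded permutation and alternating sets are
#' palindromes of their predecessor.
#'
#' @param n_volumes Volumes acquired per localizer run.
#' @param tr Repetition time, seconds.
#' @param seed Seed for the category order.
#' @return A tibble with `onset`, `duration`, `block_type`; attributes
#'   `run_duration` (seconds of stimulus presentation), `acquisition_seconds`
#'   (`n_volumes * tr`), and `block_duration`.
#' @export
localizer_design <- function(n_volumes = 158, tr = 2, seed = 1L) {
  cats <- c("scenes", "objects", "faces", "scrambled")
  clip <- 2.8 + 0.2
  block_dur <- 5 * clip
  sets <- with_seed_(derive_seed(seed, 17L), function() {
    s1 <- sample(cats)
    s3 <- sample(cats)
    list(s1, rev(s1), s3, rev(s3))
  })
  blocks <- c("fixation", sets[[1]], "fixation", sets[[2]], "fixation",
              sets[[3]], "fixation", sets[[4]], "fixation")
  out <- tibble::tibble(
    onset = (seq_along(blocks) - 1) * block_dur,
    duration = block_dur,
    block_type = blocks
  )
  attr(out, "run_duration") <- nrow(out) * block_dur
  attr(out, "block_duration") <- block_dur
  attr(out, "acquisition_seconds") <- n_volumes * tr
  out
}

#' Design arithmetic summary
#'
#' Recomputes the headline timing quantities of the design from a generated
#' schedule and the localizer block structure: events and repetitions per
#' condition, run acquisition times, and localizer block/run durations.
#'
#' @param config A [sim_config()].
#' @return A one-row tibble.
#' @export
design_summary <- function(config = sim_config()) {
  sched <- generate_event_schedule(config)
  loc <- localizer_design(tr = config$tr, seed = config$seed)
  reps_total <- if (nrow(sched)) max(table(sched$trial_type)) else 0L
  tibble::tibble(
    events_per_run = nrow(sched) / max(1L, config$n_runs),
    reps_per_condition_total = as.integer(reps_total),
    experimental_acquisition_s = config$n_volumes * config$tr,
    localizer_acquisition_s = attr(loc, "acquisition_seconds"),
    localizer_run_s = attr(loc, "run_duration"),
    localizer_block_s = attr(loc, "block_duration")
  )
}

#' Read and write BIDS-style events tables
#'
#' Events are exchanged as tab-separated tables with columns `onset`,
#' `duration`, `trial_type`, `run`, `room_type` (extra columns pass through).
#'
#' @param events An event tibble as from [generate_event_schedule()].
#' @param path File path of the `.tsv`.
#' @return `write_events_tsv()` returns `path` invisibly; `read_events_tsv()`
#'   the event tibble.
#' @export
write_events_tsv <- function(events, path) {
  cols <- c("onset", "duration", "trial_type", "run", "room_type")
  missing <- setdiff(cols, names(events))
  if (length(missing))
    stop("events table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  readr::write_tsv(dplyr::relocate(events, dplyr::all_of(cols)), path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE)
  ev$trial_type <- as.integer(ev$trial_type)
  ev$run <- as.integer(ev$run)
  if ("room_type" %in% names(ev)) ev$room_type <- as.integer(ev$room_type)
  ev
}
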