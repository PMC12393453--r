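#' Windowed-minimum reference for a fluorescence trace
#'
#' Partitions the frames into consecutive non-overlapping windows of
#' `window` frames (the last window may be shorter) and returns, for every
#' frame, the minimum of the trace over that frame's window. This is the
#' per-period normalisation reference against which Ca2+ events are called.
#'
#' @param mfi Numeric trace.
#' @param window Window length in frames (default 100). A window longer than
#'   the trace degrades to a single window covering all frames.
#' @return Numeric vector of the same length as `mfi`.
#' @export
window_minima <- function(mfi, window = 100) {
  stopifnot(window >= 1, length(mfi) >= 1)
  win <- (seq_along(mfi) - 1L) %/% as.integer(window)
  stats::ave(mfi, win, FUN = min)
}

# Event calling on a single trace: returns start/end positional indices.
.call_events_one <- function(mfi, window, threshold_ratio, gap_tolerance) {
  ref <- window_minima(mfi, window)
  supra <- mfi > (1 + threshold_ratio) * ref
  if (gap_tolerance > 0 && any(supra)) {
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    interior <- !r$values & r$lengths <= gap_tolerance &
      seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
    for (k in which(interior)) supra[starts[k]:ends[k]] <- TRUE
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  list(start = starts[keep], end = ends[keep])
}

#' Call Ca2+ events from traces by windowed-minimum thresholding
#'
#' A frame is supra-threshold iff its intensity strictly exceeds
#' `(1 + threshold_ratio)` times the windowed minimum reference (the 50
#' percent-above-minimum rule at the default ratio). Maximal runs of
#' supra-threshold frames are events; runs crossing a window boundary are a
#' single event, and events touching the first or last frame are kept and
#' flagged `censored`. Runs separated by up to `gap_tolerance` sub-threshold
#' frames can optionally be merged (default 0: no gap merging).
#'
#' @param traces Tibble with `cell_id`, `frame`, `mfi` (frames contiguous and
#'   1-based per cell), as returned by [extract_traces()].
#' @param frame_interval Seconds per frame.
#' @param window Normalisation window in frames (default 100).
#' @param threshold_ratio Fractional increase over the windowed minimum that
#'   defines an event (default 0.5).
#' @param gap_tolerance Maximum sub-threshold gap (frames) merged into one
#'   event (default 0).
#' @return Tibble `cell_id`, `start_frame`, `end_frame` (inclusive),
#'   `duration_s = (end - start + 1) * frame_interval`, `censored`.
#' @export
call_events <- function(traces, frame_interval, window = 100,
                        threshold_ratio = 0.5, gap_tolerance = 0) {
  stopifnot(all(c("cell_id", "frame", "mfi") %in% names(traces)),
            frame_interval > 0)
  traces %>%
    arrange(.data$cell_id, .data$frame) %>%
    dplyr::reframe(
      {
        ev <- .call_events_one(.data$mfi, window, threshold_ratio, gap_tolerance)
        nf <- length(.data$mfi)
        fr <- .data$frame
        tibble(
          start_frame = fr[ev$start], end_frame = fr[ev$end],
          censored = ev$start == 1L | ev$end == nf
        )
      },
      .by = "cell_id"
    ) %>%
    mutate(duration_s = (.data$end_frame - .data$start_frame + 1) * frame_interval) %>%
    select("cell_id", "start_frame", "end_frame", "duration_s", "censored")
}

#' Per-cell activity status, frequency and average event duration
#'
#' A cell is `active` iff it has at least one event. Frequency is events per
#' minute over the recording (`n_frames * frame_interval / 60` minutes), so a
#' single event in a 300-frame, 3.44 s/frame recording is 1/17.2 events/min.
#' Average duration is total signalling seconds divided by the number of
#' events, and is `NA` for inactive cells.
#'
#' @param events Event tibble from [call_events()].
#' @param n_frames Frames in the recording.
#' @param frame_interval Seconds per frame.
#' @param cell_ids Optional vector of all cell ids, so cells without events
#'   appear as inactive rows.
#' @return Tibble `cell_id`, `status`, `n_events`, `frequency` (events/min),
#'   `total_duration_s`, `avg_duration` (s/event).
#' @export
compute_dynamics <- function(events, n_frames, frame_interval, cell_ids = NULL) {
  stopifnot(n_frames >= 1, frame_interval > 0)
  minutes <- n_frames * frame_interval / 60
  per_cell <- events %>%
    group_by(.data$cell_id) %>%
    summarise(
      n_events = n(),
      total_duration_s = sum(.data$duration_s),
      .groups = "drop"
    )
  if (!is.null(cell_ids)) {
    per_cell <- tibble(cell_id = sort(unique(cell_ids))) %>%
      left_join(per_cell, by = "cell_id") %>%
      mutate(
        n_events = dplyr::coalesce(.data$n_events, 0L),
        total_duration_s = dplyr::coalesce(.data$total_duration_s, 0)
      )
  }
  per_cell %>%
    mutate(
      status = ifelse(.data$n_events >= 1, "active", "inactive"),
      frequency = .data$n_events / minutes,
      avg_duration = ifelse(.data$n_events >= 1,
                            .data$total_duration_s / .data$n_events, NA_real_)
    ) %>%
    select("cell_id", "status", "n_events", "frequency", "total_duration_s",
           "avg_duration")
}

#' Detect persistent signalling from raw trace intensity
#'
#' The 50 percent-above-minimum rule cannot see cells whose intensity stays
#' high for the whole recording, so persistence is detected directly on the
#' 0-255 scale: every frame with MFI strictly exceeding `mfi_threshold`
#' (default 170) counts as signalling, and a cell is `persistent` iff that
#' supra-threshold time reaches `min_persistent_s` (default 120 s, the lower
#' end of the minutes-long persistent events this rule targets).
#'
#' @param traces Tibble `cell_id`, `frame`, `mfi` on (or rescaled to) the
#'   0-`scale_max` scale. Intensities above `scale_max` are a hard error:
#'   rescale 16-bit data first (divide by the acquisition maximum and
#'   multiply by 255).
#' @param frame_interval Seconds per frame.
#' @param mfi_threshold Intensity threshold (default 170).
#' @param scale_max Full scale (default 255).
#' @param min_persistent_s Minimum supra-threshold time to flag persistence,
#'   seconds (default 120).
#' @return Tibble `cell_id`, `persistent`, `persistent_duration_s`.
#' @export
detect_persistent <- function(traces, frame_interval, mfi_threshold = 170,
                              scale_max = 255, min_persistent_s = 120) {
  stopifnot(all(c("cell_id", "frame", "mfi") %in% names(traces)),
            frame_interval > 0)
  if (any(traces$mfi > scale_max)) {
    stop("trace intensities exceed scale_max = ", scale_max,
         "; rescale to the 0-", scale_max, " scale before persistence detection")
  }
  traces %>%
    group_by(.data$cell_id) %>%
    summarise(
      persistent_duration_s = sum(.data$mfi > mfi_threshold) * frame_interval,
      .groups = "drop"
    ) %>%
    mutate(persistent = .data$persistent_duration_s >= min_persistent_s) %>%
    select("cell_id", "persistent", "persistent_duration_s")
}

#' Flag high-frequency and high-average-duration cells (mean + 1 SD rule)
#'
#' Thresholds are the mean plus one sample standard deviation (denominator
#' n - 1) of frequency and of average duration over the active cells of the
#' reference population. The reference defaults to `dynamics` itself; for
#' revisits pass the day-0 dynamics, and for knockout analyses the
#' control-mouse dynamics, so thresholds stay fixed across comparisons. The
#' two flags are not mutually exclusive.
#'
#' @param dynamics Tibble from [compute_dynamics()].
#' @param reference Optional reference dynamics tibble; must contain at least
#'   two active cells.
#' @return `dynamics` with logical `high_frequency`, `high_avg_duration` and
#'   a `dynamics_class` label (`"normal"`, `"high_frequency"`,
#'   `"high_avg_duration"`, or both joined with `"+"`; `NA` for inactive
#'   cells). The thresholds used are attached as attribute `thresholds`.
#' @export
classify_dynamics <- function(dynamics, reference = NULL) {
  ref <- if (is.null(reference)) dynamics else reference
  ref_active <- ref %>% filter(.data$status == "active")
  if (nrow(ref_active) < 2) {
    stop("classification refused: fewer than 2 active cells in the reference population")
  }
  thr_f <- mean(ref_active$frequency) + sd(ref_active$frequency)
  thr_d <- mean(ref_active$avg_duration) + sd(ref_active$avg_duration)
  out <- dynamics %>%
    mutate(
      high_frequency = .data$status == "active" & .data$frequency > thr_f,
      high_avg_duration = .data$status == "active" &
        !is.na(.data$avg_duration) & .data$avg_duration > thr_d,
      dynamics_class = case_when(
        .data$status != "active" ~ NA_character_,
        .data$high_frequency & .data$high_avg_duration ~
          "high_frequency+high_avg_duration",
        .data$high_frequency ~ "high_frequency",
        .data$high_avg_duration ~ "high_avg_duration",
        TRUE ~ "normal"
      )
    )
  attr(out, "thresholds") <- c(frequency = thr_f, avg_duration = thr_d)
  out
}

#' Merge event-based dynamics with persistence into one per-cell summary
#'
#' Persistent cells show no threshold-crossing events (a 50 percent excursion
#' above a > 170 baseline is unrepresentable on an 8-bit scale), so the
#' merged summary marks a cell active if it has events or is persistent.
#'
#' @param dynamics Tibble from [compute_dynamics()] (optionally after
#'   [classify_dynamics()]).
#' @param persistence Tibble from [detect_persistent()].
#' @return Joined tibble with `status` upgraded to `"active"` for persistent
#'   cells.
#' @export
summarise_cells <- function(dynamics, persistence) {
  dynamics %>%
    left_join(persistence, by = "cell_id") %>%
    mutate(
      persistent = dplyr::coalesce(.data$persistent, FALSE),
      status = ifelse(.data$persistent | .data$n_events >= 1,
                      "active", "inactive")
    )
}

#' Build a binary cell-by-time activity raster
#'
#' `raster[c, t] = 1` iff frame `t` lies inside an event of cell `c`; the
#' time axis in seconds is `(frame - 1) * frame_interval`. Overlapping events
#' for one cell violate the event-table invariant and are a hard error.
#'
#' @param events Event tibble from [call_events()] (or with at least
#'   `cell_id`, `start_frame`, `end_frame`).
#' @param n_frames Frames in the recording.
#' @param frame_interval Seconds per frame.
#' @param cell_ids Optional vector of all cell ids (rows for event-less cells).
#' @return A `capnet_raster`: integer matrix cells x frames with rownames the
#'   cell ids and attributes `frame_interval`.
#' @export
build_raster <- function(events, n_frames, frame_interval, cell_ids = NULL) {
  stopifnot(n_frames >= 1, frame_interval > 0)
  if (nrow(events)) {
    stopifnot(all(events$start_frame >= 1), all(events$end_frame <= n_frames),
              all(events$start_frame <= events$end_frame))
    bad <- events %>%
      arrange(.data$cell_id, .data$start_frame) %>%
      group_by(.data$cell_id) %>%
      filter(row_number() > 1 &
               .data$start_frame <= dplyr::lag(.data$end_frame)) %>%
      ungroup()
    if (nrow(bad)) {
      stop("overlapping events for cell(s): ",
           paste(unique(bad$cell_id), collapse = ", "))
    }
  }
  ids <- sort(unique(c(events$cell_id, cell_ids)))
  ras <- matrix(0L, length(ids), n_frames,
                dimnames = list(as.character(ids), NULL))
  for (k in seq_len(nrow(events))) {
    i <- match(events$cell_id[k], ids)
    ras[i, events$start_frame[k]:events$end_frame[k]] <- 1L
  }
  structure(ras, frame_interval = frame_interval, class = "capnet_raster")
}

#' Recover the event table from an activity raster
#'
#' Inverse of [build_raster()]: maximal runs of 1s per row become events, so
#' `events -> raster -> events` is the identity.
#'
#' @param raster A `capnet_raster`.
#' @return Tibble `cell_id`, `start_frame`, `end_frame`, `duration_s`.
#' @export
raster_to_events <- function(raster) {
  stopifnot(inherits(raster, "capnet_raster"))
  fi <- attr(raster, "frame_interval")
  ids <- suppressWarnings(as.integer(rownames(raster)))
  if (anyNA(ids)) ids <- rownames(raster)
  out <- lapply(seq_len(nrow(raster)), function(i) {
    r <- rle(raster[i, ] == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    tibble(cell_id = ids[i], start_frame = starts[keep], end_frame = ends[keep])
  })
  bind_rows(out) %>%
    mutate(duration_s = (.data$end_frame - .data$start_frame + 1) * fi)
}
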