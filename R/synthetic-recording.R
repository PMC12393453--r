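#' Specify a synthetic capillary Ca2+ recording
#'
#' Bundles the parameters of the synthetic timelapse generator. Defaults
#' reproduce the acquisition and population statistics of homeostatic skin
#' capillary recordings: 300 frames at 3.44 s/frame (17 min 12 s), roughly
#' half the cells active, 0.445 events/min and 8.36 s mean event duration in
#' active cells, intensities on a 0-255 (8-bit) scale. The high-speed dialect
#' is obtained with `frame_interval = 0.62`.
#'
#' @param n_frames Number of frames (default 300).
#' @param frame_interval Seconds per frame (default 3.44).
#' @param n_cells Number of nuclear ROIs to place (default 100).
#' @param active_fraction Fraction of cells with at least one Ca2+ event
#'   (default 0.524, the observed homeostatic proportion).
#' @param event_rate Events per minute per active cell (default 0.445).
#' @param duration_mean Mean event duration in seconds (default 8.36).
#' @param persistent_fraction Fraction of active cells whose trace is held
#'   above the persistence threshold for the whole recording (default 0;
#'   around 0.19 emulates the gap-junction-knockout dialect).
#' @param baseline_mfi Baseline ROI intensity, 0-255 scale (default 100).
#' @param event_amplitude Multiplicative gain during an event; must exceed
#'   1.5 so planted events clear the 50 percent threshold (default 2).
#' @param persistent_mfi Constant intensity of persistent cells; must exceed
#'   170 (default 180).
#' @param noise_sd Gaussian pixel noise SD, clipped to 0-255 (default 5,
#'   i.e. 5 percent of baseline; 0 for noise-free).
#' @param bleach_rate Fractional baseline decay per frame (default 0).
#' @param background Intensity of non-ROI pixels (default 10).
#' @param image_size Side of the square field in pixels; by default scaled to
#'   the cell count.
#' @param pixel_size_mm Pixel pitch in mm (default 0.0015, a 0.3 mm field at
#'   200 px).
#' @param rng_seed Integer seed; the same seed reproduces the recording
#'   bit-for-bit.
#'
#' @return A `recording_spec` list.
#' @export
recording_spec <- function(n_frames = 300, frame_interval = 3.44, n_cells = 100,
                           active_fraction = 0.524, event_rate = 0.445,
                           duration_mean = 8.36, persistent_fraction = 0,
                           baseline_mfi = 100, event_amplitude = 2,
                           persistent_mfi = 180, noise_sd = 5, bleach_rate = 0,
                           background = 10, image_size = NULL,
                           pixel_size_mm = 0.0015, rng_seed = NULL) {
  stopifnot(
    n_frames >= 1, frame_interval > 0, n_cells >= 0,
    active_fraction >= 0, active_fraction <= 1,
    persistent_fraction >= 0, persistent_fraction <= 1,
    event_rate >= 0, duration_mean > 0,
    baseline_mfi > 0, baseline_mfi <= 255,
    event_amplitude > 1.5, persistent_mfi > 170, persistent_mfi <= 255,
    noise_sd >= 0, bleach_rate >= 0, bleach_rate < 1
  )
  if (is.null(image_size)) {
    image_size <- max(48L, ceiling(sqrt(max(n_cells, 1)) * 16))
  }
  structure(
    list(
      n_frames = as.integer(n_frames), frame_interval = frame_interval,
      n_cells = as.integer(n_cells), active_fraction = active_fraction,
      event_rate = event_rate, duration_mean = duration_mean,
      persistent_fraction = persistent_fraction, baseline_mfi = baseline_mfi,
      event_amplitude = event_amplitude, persistent_mfi = persistent_mfi,
      noise_sd = noise_sd, bleach_rate = bleach_rate, background = background,
      image_size = as.integer(image_size), pixel_size_mm = pixel_size_mm,
      rng_seed = rng_seed
    ),
    class = "recording_spec"
  )
}

# Place n_cells axis-aligned elliptical ROIs with >= 2 px margin between them.
# Returns an integer label matrix; errors if the retry budget is exhausted.
.place_rois <- function(n_cells, side, max_tries = 400L) {
  labels <- matrix(0L, side, side)
  blocked <- matrix(FALSE, side, side)   # existing ROIs dilated by the margin
  for (cell in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ry <- sample(3:4, 1)
      rx <- sample(2:3, 1)
      cy <- sample((ry + 1):(side - ry), 1)
      cx <- sample((rx + 1):(side - rx), 1)
      ys <- (cy - ry):(cy + ry)
      xs <- (cx - rx):(cx + rx)
      ell <- outer(ys, xs, function(y, x) ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1)
      sub <- blocked[ys, xs, drop = FALSE]
      if (any(sub & ell)) next
      labels[ys, xs][ell] <- cell
      # block the ROI dilated by the 2 px margin, computed on a local window
      ys2 <- max(1L, cy - ry - 2L):min(side, cy + ry + 2L)
      xs2 <- max(1L, cx - rx - 2L):min(side, cx + rx + 2L)
      local <- matrix(FALSE, length(ys2), length(xs2))
      local[cbind(match(ys, ys2)[row(ell)[ell]], match(xs, xs2)[col(ell)[ell]])] <- TRUE
      blocked[ys2, xs2] <- blocked[ys2, xs2] | .dilate_square(local, 2L)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("ROI placement failed: could not fit ", n_cells,
           " cells with a 2 px margin in a ", side, " px field")
    }
  }
  labels
}

# Draw disjoint event intervals (in frames) for one cell, separated by at
# least 2 frames so planted events are never merged by the detector.
.place_events <- function(n_frames, n_events, dur_frames) {
  starts <- integer(0)
  ends <- integer(0)
  for (d in as.integer(dur_frames)) {
    if (d > n_frames) d <- as.integer(n_frames)
    ok <- FALSE
    for (try in 1:100) {
      s <- sample.int(n_frames - d + 1L, 1)
      e <- s + d - 1L
      if (!any(s <= ends + 2L & e >= starts - 2L)) {
        starts <- c(starts, s)
        ends <- c(ends, e)
        ok <- TRUE
        break
      }
    }
    if (!ok) break  # field too crowded; keep what was placed
  }
  ord <- order(starts)
  list(start = starts[ord], end = ends[ord])
}

#' Generate a synthetic Ca2+ recording with planted ground truth
#'
#' Renders a timelapse movie (`y x x x frame` array), a nuclear label mask and
#' a ground-truth list. Active cells receive a censored-Poisson set of events
#' during which their ROI intensity is `event_amplitude` times the (bleached)
#' baseline; persistent cells are held at `persistent_mfi` (> 170) for the
#' whole recording and carry no threshold events, since on an 8-bit scale a
#' 50 percent excursion above such a baseline is unrepresentable. Events
#' truncated at the recording boundary are kept and flagged `censored`.
#'
#' @param spec A [recording_spec()].
#' @return A list with elements `movie` (numeric array y x x x frame),
#'   `labels` (integer matrix), and `truth`: a list with `events`
#'   (tibble `cell_id`, `start_frame`, `end_frame`, `censored`; 1-based,
#'   inclusive), `active_cells`, `persistent_cells`, and `cell_traces`
#'   (noise-free per-cell ROI mean, cells x frames).
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  run <- function() {
    side <- spec$image_size
    nt <- spec$n_frames
    labels <- .place_rois(spec$n_cells, side)
    minutes <- nt * spec$frame_interval / 60

    n_active <- round(spec$active_fraction * spec$n_cells)
    active <- sort(sample.int(spec$n_cells, n_active))
    n_pers <- round(spec$persistent_fraction * n_active)
    persistent <- sort(active[sample.int(max(n_active, 1L), n_pers)])

    decay <- (1 - spec$bleach_rate)^(seq_len(nt) - 1)
    traces <- matrix(rep(spec$baseline_mfi * decay, each = spec$n_cells),
                     spec$n_cells, nt)
    ev_cell <- integer(0); ev_start <- integer(0); ev_end <- integer(0)
    for (cell in active) {
      if (cell %in% persistent) {
        traces[cell, ] <- spec$persistent_mfi
        next
      }
      n_ev <- max(1L, rpois(1, spec$event_rate * minutes))
      dur <- pmax(1L, round(rexp(n_ev, 1 / spec$duration_mean) / spec$frame_interval))
      ev <- .place_events(nt, n_ev, dur)
      for (k in seq_along(ev$start)) {
        fr <- ev$start[k]:ev$end[k]
        traces[cell, fr] <- pmin(255, spec$event_amplitude * spec$baseline_mfi * decay[fr])
      }
      ev_cell <- c(ev_cell, rep(cell, length(ev$start)))
      ev_start <- c(ev_start, ev$start)
      ev_end <- c(ev_end, ev$end)
    }

    flat <- matrix(spec$background, side * side, nt)
    for (cell in seq_len(spec$n_cells)) {
      idx <- which(labels == cell)
      flat[idx, ] <- rep(traces[cell, ], each = length(idx))
    }
    if (spec$noise_sd > 0) {
      flat <- flat + rnorm(length(flat), 0, spec$noise_sd)
      flat <- pmin(255, pmax(0, flat))
    }
    movie <- flat
    dim(movie) <- c(side, side, nt)

    events <- tibble(
      cell_id = ev_cell, start_frame = ev_start, end_frame = ev_end,
      censored = ev_start == 1L | ev_end == nt
    ) %>% arrange(.data$cell_id, .data$start_frame)

    list(
      movie = movie,
      labels = labels,
      truth = list(
        events = events,
        active_cells = active,
        persistent_cells = persistent,
        cell_traces = traces,
        spec = spec
      )
    )
  }
  if (is.null(spec$rng_seed)) run() else withr::with_seed(spec$rng_seed, run())
}

#' Generate a paired revisit status table
#'
#' Each cell is active on day 0 with probability `p_active_day0`. On revisit
#' it keeps its day-0 status with probability `p_maintain` (the conservation
#' model); with `independent = TRUE` the revisit status is
#' instead drawn independently with probability `p_active_day0`, the
#' "random activity" null.
#'
#' @param n_cells Number of matched cells.
#' @param p_active_day0 Day-0 active probability (default 0.58, the observed
#'   24-hour-revisit day-0 proportion).
#' @param p_maintain Probability a cell keeps its status (default 0.711).
#' @param independent Draw the revisit independently of day 0.
#' @param rng_seed Optional integer seed.
#' @return Tibble with `cell_id`, `status_day0`, `status_dayn`
#'   (`"active"`/`"inactive"`).
#' @export
generate_revisit_pair <- function(n_cells, p_active_day0 = 0.58,
                                  p_maintain = 0.711, independent = FALSE,
                                  rng_seed = NULL) {
  stopifnot(n_cells >= 1, p_active_day0 >= 0, p_active_day0 <= 1,
            p_maintain >= 0, p_maintain <= 1)
  run <- function() {
    d0 <- rbinom(n_cells, 1, p_active_day0) == 1
    dn <- if (independent) {
      rbinom(n_cells, 1, p_active_day0) == 1
    } else {
      keep <- rbinom(n_cells, 1, p_maintain) == 1
      ifelse(keep, d0, !d0)
    }
    tibble(
      cell_id = seq_len(n_cells),
      status_day0 = ifelse(d0, "active", "inactive"),
      status_dayn = ifelse(dn, "active", "inactive")
    )
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}
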