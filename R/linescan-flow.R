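#' Detect intensity valleys (cell transits) in a line-scan profile
#'
#' Unlabelled cells moving through fluorescent plasma appear as dips in the
#' red (dextran) intensity series. A sample is a candidate valley if it is a
#' local minimum; candidates are kept iff their prominence reaches
#' `prominence`, their width at half prominence lies in `width_range`, their
#' minimum value does not exceed `intensity_ceiling` (the
#' intensity-qualification rule that rejects shallow noise dips), and they
#' are at least `min_distance` samples from any deeper kept valley.
#'
#' Data-driven defaults, recorded in the output attributes: `prominence` is
#' 0.3 x (median - minimum) of the profile, `intensity_ceiling` is 0.6 x the
#' median. These mirror the per-vessel parameter choices an operator would
#' make and are overridable.
#'
#' @param red Numeric intensity profile (concatenated scan lines).
#' @param prominence Minimum prominence; `NULL` for the default above.
#' @param min_distance Minimum sample separation between kept valleys
#'   (default 4, the expected valley width).
#' @param width_range Length-2 vector of admissible widths at half
#'   prominence, in samples (default `c(2, 50)`).
#' @param intensity_ceiling Maximum admissible valley value; `NULL` for the
#'   default above.
#' @return Tibble `position` (1-based sample), `value`, `prominence`,
#'   `width`; attribute `parameters` records the resolved settings. No
#'   valleys is a valid empty result.
#' @export
detect_valleys <- function(red, prominence = NULL, min_distance = 4,
                           width_range = c(2, 50), intensity_ceiling = NULL) {
  if (!length(red)) stop("empty line-scan profile")
  stopifnot(min_distance >= 1, length(width_range) == 2,
            width_range[1] <= width_range[2])
  if (is.null(prominence)) prominence <- 0.3 * (median(red) - min(red))
  if (is.null(intensity_ceiling)) intensity_ceiling <- 0.6 * median(red)
  n <- length(red)

  empty <- tibble(position = integer(), value = double(),
                  prominence = double(), width = double())
  params <- c(prominence = prominence, min_distance = min_distance,
              width_min = width_range[1], width_max = width_range[2],
              intensity_ceiling = intensity_ceiling)
  if (n < 3) {
    attr(empty, "parameters") <- params
    return(empty)
  }

  # local minima with plateau handling: previous non-zero slope down, next up
  d <- diff(red)
  s <- sign(d)
  # carry the last non-zero slope forward/backward across plateaus
  left_s <- s
  for (i in seq_along(left_s)) if (left_s[i] == 0 && i > 1) left_s[i] <- left_s[i - 1]
  right_s <- s
  for (i in rev(seq_along(right_s))) if (right_s[i] == 0 && i < length(right_s)) right_s[i] <- right_s[i + 1]
  cand <- which(left_s[-length(s)] < 0 & right_s[-1] > 0) + 1L

  if (!length(cand)) {
    attr(empty, "parameters") <- params
    return(empty)
  }

  prom <- numeric(length(cand))
  width <- numeric(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    v <- red[i]
    lmax <- -Inf
    j <- i - 1L
    while (j >= 1L && red[j] >= v) {
      if (red[j] > lmax) lmax <- red[j]
      j <- j - 1L
    }
    if (j < 1L) lmax <- max(lmax, if (i > 1) max(red[1:(i - 1)]) else v)
    rmax <- -Inf
    j <- i + 1L
    while (j <= n && red[j] >= v) {
      if (red[j] > rmax) rmax <- red[j]
      j <- j + 1L
    }
    if (j > n) rmax <- max(rmax, if (i < n) max(red[(i + 1):n]) else v)
    p <- min(lmax, rmax) - v
    prom[k] <- if (is.finite(p)) p else 0
    half <- v + prom[k] / 2
    wl <- 0L
    j <- i - 1L
    while (j >= 1L && red[j] < half) {
      wl <- wl + 1L
      j <- j - 1L
    }
    wr <- 0L
    j <- i + 1L
    while (j <= n && red[j] < half) {
      wr <- wr + 1L
      j <- j + 1L
    }
    width[k] <- wl + wr + 1L
  }

  keep <- prom >= prominence & width >= width_range[1] &
    width <= width_range[2] & red[cand] <= intensity_ceiling
  cand <- cand[keep]
  prom <- prom[keep]
  width <- width[keep]

  # enforce min_distance, deepest valleys first
  ord <- order(red[cand], cand)
  sel <- logical(length(cand))
  kept_pos <- integer(0)
  for (k in ord) {
    if (!length(kept_pos) || all(abs(cand[k] - kept_pos) >= min_distance)) {
      sel[k] <- TRUE
      kept_pos <- c(kept_pos, cand[k])
    }
  }

  out <- tibble(
    position = cand[sel], value = red[cand[sel]],
    prominence = prom[sel], width = width[sel]
  ) %>% arrange(.data$position)
  attr(out, "parameters") <- params
  out
}

#' Partition a line-scan profile into fixed-width blocks
#'
#' Assigns each valley to block `floor((position - 1) / block_width) + 1`
#' (a valley on the first sample of a block belongs to that block), counts
#' valleys and computes within-block valley-to-valley spacings, per-block
#' flux in cells/second (`count / block duration`), and the green-channel
#' block mean. Trailing samples short of a full block are dropped.
#'
#' @param valleys Tibble from [detect_valleys()].
#' @param red The red profile the valleys were detected on.
#' @param green Either per-sample green intensities (same length as `red`)
#'   or per-block means (length = number of full blocks); `NULL` for none.
#' @param block_width Samples per block (default 600).
#' @param lines_per_second Scan rate (default 300; 600 samples over 2 s).
#' @return Tibble `block`, `valley_count`, `flux`, `green_mean`, `spacings`
#'   (list column of within-block sample gaps).
#' @export
blockify <- function(valleys, red, green = NULL, block_width = 600,
                     lines_per_second = 300) {
  stopifnot(block_width >= 2, lines_per_second > 0)
  n_blocks <- length(red) %/% block_width
  if (n_blocks < 1) stop("profile shorter than one block")
  block_dur <- block_width / lines_per_second
  pos <- valleys$position[valleys$position <= n_blocks * block_width]
  blk <- (pos - 1L) %/% block_width + 1L
  spac <- lapply(seq_len(n_blocks), function(b) diff(sort(pos[blk == b])))
  counts <- tabulate(blk, nbins = n_blocks)
  gm <- if (is.null(green)) {
    rep(NA_real_, n_blocks)
  } else if (length(green) == n_blocks) {
    as.numeric(green)
  } else if (length(green) >= n_blocks * block_width) {
    vapply(seq_len(n_blocks), function(b) {
      mean(green[((b - 1L) * block_width + 1L):(b * block_width)])
    }, numeric(1))
  } else {
    stop("green must be per-sample (length >= profile) or per-block (length = ",
         n_blocks, ")")
  }
  out <- tibble(
    block = seq_len(n_blocks),
    valley_count = counts,
    flux = counts / block_dur,
    green_mean = gm
  )
  out$spacings <- spac
  out
}

#' Label blocks by Ca2+ event phase
#'
#' The event threshold is 1.5 x the minimum green block mean; a block is
#' `during` iff its green mean strictly exceeds it. Gap blocks between two
#' during-runs are split by proximity: nearer the preceding run is `after`,
#' nearer the following run is `before`, ties go to `before`. Blocks before
#' the first run are `before`, after the last run `after`. With no during
#' block the whole series is `no_event`.
#'
#' @param blocks Tibble from [blockify()] with a `green_mean` column.
#' @param threshold_factor Multiple of the minimum block mean (default 1.5).
#' @return `blocks` with a `label` column.
#' @export
label_blocks <- function(blocks, threshold_factor = 1.5) {
  stopifnot(nrow(blocks) >= 1, !anyNA(blocks$green_mean))
  thr <- threshold_factor * min(blocks$green_mean)
  during <- blocks$green_mean > thr
  lab <- rep("no_event", nrow(blocks))
  if (any(during)) {
    lab[during] <- "during"
    idx <- which(during)
    for (i in which(!during)) {
      prev <- suppressWarnings(max(idx[idx < i]))
      nxt <- suppressWarnings(min(idx[idx > i]))
      lab[i] <- if (!is.finite(prev)) {
        "before"
      } else if (!is.finite(nxt)) {
        "after"
      } else if ((i - prev) < (nxt - i)) {
        "after"
      } else {
        "before"
      }
    }
  }
  blocks %>% mutate(label = lab)
}

#' Smooth a flux series with a centred 5-point moving average
#'
#' Each time point is averaged with its two preceding and two following
#' points; at the series edges the window shrinks to the available points.
#'
#' @param flux Numeric series.
#' @param half_window Points on each side (default 2).
#' @return Numeric series of the same length.
#' @export
smooth_flux <- function(flux, half_window = 2) {
  n <- length(flux)
  stopifnot(n >= 1, half_window >= 0)
  vapply(seq_len(n), function(i) {
    mean(flux[max(1, i - half_window):min(n, i + half_window)])
  }, numeric(1))
}

#' Per-period flow change and average flux
#'
#' Periods are maximal runs of signalling (`during`) versus non-signalling
#' blocks. For each period the change in flow rate is the flux at the last
#' block minus the flux at the first (0 for single-block periods), and the
#' average flux is the mean over the period. Within each signalling class,
#' periods are split into duration classes at mean + 1 SD of the period
#' lengths.
#'
#' @param blocks Labelled tibble from [label_blocks()]. Pass smoothed flux in
#'   the `flux` column beforehand if the trend is wanted instead of raw flux.
#' @return Tibble `period_id`, `signaling`, `n_blocks`, `first_block`,
#'   `last_block`, `flux_first`, `flux_last`, `flow_change`, `avg_flux`,
#'   `duration_class` (`"le_1sd"` / `"gt_1sd"`).
#' @export
period_flow_change <- function(blocks) {
  stopifnot("label" %in% names(blocks))
  sig <- blocks$label == "during"
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- tibble(
    period_id = seq_along(r$values),
    signaling = r$values,
    n_blocks = r$lengths,
    first_block = blocks$block[starts],
    last_block = blocks$block[ends],
    flux_first = blocks$flux[starts],
    flux_last = blocks$flux[ends],
    flow_change = blocks$flux[ends] - blocks$flux[starts],
    avg_flux = vapply(seq_along(starts), function(k) {
      mean(blocks$flux[starts[k]:ends[k]])
    }, numeric(1))
  )
  out %>%
    group_by(.data$signaling) %>%
    mutate(duration_class = ifelse(
      n() >= 2 & .data$n_blocks > mean(.data$n_blocks) + sd(.data$n_blocks),
      "gt_1sd", "le_1sd"
    )) %>%
    ungroup()
}

#' Compare flow changes between signalling and non-signalling periods
#'
#' Unpaired two-tailed t-test on the per-period flow changes.
#'
#' @param periods Tibble from [period_flow_change()].
#' @param welch Use Welch's correction (default `FALSE`).
#' @return One-row tibble `mean_signaling`, `mean_nonsignaling`, `statistic`,
#'   `df`, `p.value`.
#' @export
flow_period_test <- function(periods, welch = FALSE) {
  a <- periods$flow_change[periods$signaling]
  b <- periods$flow_change[!periods$signaling]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 signalling and 2 non-signalling periods")
  }
  tt <- t.test(a, b, var.equal = !welch)
  tibble(
    mean_signaling = mean(a), mean_nonsignaling = mean(b),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p.value = tt$p.value
  )
}

#' Flag vessels with baseline drift during line scanning
#'
#' Vessels whose field shifted show large baseline changes; a vessel is
#' flagged when the range of per-block red medians exceeds
#' `max_range_frac` (default 0.3) of the global median.
#'
#' @param red Red intensity profile.
#' @param block_width Samples per block (default 600).
#' @param max_range_frac Tolerated fractional range (default 0.3).
#' @return One-row tibble `flagged`, `range_frac`, `global_median`.
#' @export
qc_baseline_shift <- function(red, block_width = 600, max_range_frac = 0.3) {
  n_blocks <- length(red) %/% block_width
  stopifnot(n_blocks >= 1)
  med <- vapply(seq_len(n_blocks), function(b) {
    median(red[((b - 1L) * block_width + 1L):(b * block_width)])
  }, numeric(1))
  gm <- median(red)
  rf <- diff(range(med)) / gm
  tibble(flagged = rf > max_range_frac, range_frac = rf, global_median = gm)
}
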