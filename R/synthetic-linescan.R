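#' Specify a synthetic line-scan profile
#'
#' Parameters for the line-scan generator. Defaults emulate the acquisition
#' used for capillary flow tracking: 600 scan lines per 2-second block at
#' 300 lines/s, 150 blocks (5 minutes per vessel), and a mean flux of
#' 28.9 cells/s (the homeostatic per-vessel average). Unlabelled cells moving
#' through the fluorescent dextran appear as intensity valleys; each planted
#' valley is a triangular dip of depth `valley_depth` and half-width
#' `valley_width` samples.
#'
#' @param n_blocks Number of fixed-width blocks (default 150).
#' @param block_width Samples per block (default 600).
#' @param lines_per_second Scan rate (default 300).
#' @param flux_true Cells per second, scalar or one value per block
#'   (default 28.9). The planted count per block is
#'   `round(flux_true * block_width / lines_per_second)`.
#' @param valley_depth Dip depth in intensity units (default 120).
#' @param valley_width Dip half-width in samples (default 3).
#' @param baseline Red-channel plasma intensity (default 200).
#' @param noise_sd Gaussian noise SD on the red profile (default 10).
#' @param green_event_blocks Integer block indices whose green block mean is
#'   elevated (a Ca2+ event); empty by default.
#' @param green_baseline,green_event_level Green block means outside/inside
#'   event blocks (defaults 10 and 40; the event level must exceed 1.5x the
#'   minimum block mean for the downstream labeller).
#' @param min_separation Minimum distance between valley centres in samples;
#'   `NULL` (default) places centres independently so collisions can occur,
#'   as in dense real data. When given, centres are rejection-sampled and the
#'   generator errors if the block cannot hold the requested count
#'   (overcrowding).
#' @param rng_seed Optional integer seed.
#' @return A `linescan_spec` list.
#' @export
linescan_spec <- function(n_blocks = 150, block_width = 600,
                          lines_per_second = 300, flux_true = 28.9,
                          valley_depth = 120, valley_width = 3,
                          baseline = 200, noise_sd = 10,
                          green_event_blocks = integer(),
                          green_baseline = 10, green_event_level = 40,
                          min_separation = NULL, rng_seed = NULL) {
  stopifnot(
    n_blocks >= 1, block_width >= 2, lines_per_second > 0,
    all(flux_true >= 0), length(flux_true) %in% c(1L, n_blocks),
    valley_depth > 0, valley_width >= 1, baseline > 0, noise_sd >= 0,
    all(green_event_blocks >= 1), all(green_event_blocks <= n_blocks),
    green_event_level > 1.5 * green_baseline
  )
  structure(
    list(
      n_blocks = as.integer(n_blocks), block_width = as.integer(block_width),
      lines_per_second = lines_per_second, flux_true = flux_true,
      valley_depth = valley_depth, valley_width = valley_width,
      baseline = baseline, noise_sd = noise_sd,
      green_event_blocks = as.integer(green_event_blocks),
      green_baseline = green_baseline, green_event_level = green_event_level,
      min_separation = min_separation, rng_seed = rng_seed
    ),
    class = "linescan_spec"
  )
}

#' Generate a synthetic line-scan profile with planted transits
#'
#' @param spec A [linescan_spec()].
#' @return A list with `red` (numeric profile of length
#'   `n_blocks * block_width`), `green_block_means` (length `n_blocks`), and
#'   `truth`: a tibble (`block`, `n_transits`) plus `centres` (list of valley
#'   centre positions per block, 1-based samples from profile start).
#' @export
generate_linescan <- function(spec) {
  stopifnot(inherits(spec, "linescan_spec"))
  run <- function() {
    w <- spec$block_width
    nb <- spec$n_blocks
    block_dur <- w / spec$lines_per_second
    flux <- rep(spec$flux_true, length.out = nb)
    counts <- as.integer(round(flux * block_dur))
    vw <- spec$valley_width

    if (!is.null(spec$min_separation)) {
      need <- counts * spec$min_separation
      if (any(need > w - 2 * vw)) {
        stop("overcrowded line-scan block: ", max(counts),
             " valleys with min_separation ", spec$min_separation,
             " cannot fit in ", w, " samples")
      }
    }

    red <- rep(spec$baseline, nb * w)
    centres <- vector("list", nb)
    lo <- vw + 1L
    for (b in seq_len(nb)) {
      k <- counts[b]
      if (k == 0L) {
        centres[[b]] <- integer(0)
        next
      }
      hi <- w - vw
      if (is.null(spec$min_separation)) {
        cen <- sample(lo:hi, k, replace = TRUE)
      } else {
        cen <- integer(0)
        tries <- 0L
        while (length(cen) < k && tries < 200L * k) {
          cand <- sample(lo:hi, 1)
          if (!length(cen) || all(abs(cand - cen) >= spec$min_separation)) {
            cen <- c(cen, cand)
          }
          tries <- tries + 1L
        }
        if (length(cen) < k) {
          stop("overcrowded line-scan block ", b,
               ": rejection sampling could not place ", k, " valleys")
        }
      }
      cen <- sort(cen)
      off <- (b - 1L) * w
      for (cc in cen) {
        xs <- (cc - vw):(cc + vw)
        dip <- spec$valley_depth * pmax(0, 1 - abs(xs - cc) / vw)
        red[off + xs] <- pmin(red[off + xs], spec$baseline - dip)
      }
      centres[[b]] <- off + cen
    }
    if (spec$noise_sd > 0) red <- red + rnorm(length(red), 0, spec$noise_sd)
    red <- pmax(0, red)

    green <- rep(spec$green_baseline, nb)
    green[spec$green_event_blocks] <- spec$green_event_level

    truth <- tibble(block = seq_len(nb), n_transits = counts)
    truth$centres <- centres
    list(red = red, green_block_means = green, truth = truth, spec = spec)
  }
  if (is.null(spec$rng_seed)) run() else withr::with_seed(spec$rng_seed, run())
}
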