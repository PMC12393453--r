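#' Generate synthetic vessel geometry with planted loops, skeleton and nuclei
#'
#' Builds a binary vessel mask containing `n_loops` fully enclosed square
#' annular loops, a one-pixel-wide skeleton made of straight (horizontal or
#' diagonal) segments, and nuclear centroids planted at known perpendicular
#' offsets from the skeleton. Everything needed to verify loop morphometry,
#' nucleus snapping and segment density downstream is recorded as ground
#' truth.
#'
#' Loops are laid out on a grid with random hole sizes (6-15 px) and a 3 px
#' ring; segments are disjoint paths placed below the loop field, alternating
#' horizontal and diagonal orientation.
#'
#' @param n_loops Number of enclosed loops (>= 0; default 4).
#' @param pixel_size_um Pixel pitch in micrometres (default 0.6).
#' @param nuclei_per_segment Integer vector: nuclei planted per segment
#'   (recycled; default `c(2, 3)`).
#' @param segment_lengths_px Path lengths in pixels per segment
#'   (default `c(81, 61)`).
#' @param nuclei_offset_um Perpendicular offsets of planted nuclei from the
#'   skeleton, in micrometres, recycled over nuclei (default `c(0, 2, 4)`).
#'   Offsets are realised to the nearest whole pixel.
#' @param rng_seed Optional integer seed.
#' @return List with `mask`, `skeleton` (logical matrices), `nuclei` (tibble
#'   `nucleus_id`, `y`, `x`, `segment_id`, `offset_um` with the realised
#'   pixel-snapped offset), and `truth`: `loops` (tibble `loop_id`,
#'   `hole_side`, `area_px`, `centroid_y`, `centroid_x`) and `segments`
#'   (tibble `segment_id`, `orientation`, `n_pixels`, `length_um`, and a
#'   `path` list column of pixel coordinate matrices).
#' @export
generate_vessel_geometry <- function(n_loops = 4, pixel_size_um = 0.6,
                                     nuclei_per_segment = c(2, 3),
                                     segment_lengths_px = c(81, 61),
                                     nuclei_offset_um = c(0, 2, 4),
                                     rng_seed = NULL) {
  stopifnot(n_loops >= 0, pixel_size_um > 0,
            all(nuclei_per_segment >= 0), all(segment_lengths_px >= 2))
  run <- function() {
    n_seg <- length(segment_lengths_px)
    cell_px <- 30L                       # layout cell for one loop
    loops_per_row <- max(1L, ceiling(sqrt(max(n_loops, 1))))
    loop_rows <- if (n_loops > 0) ceiling(n_loops / loops_per_row) else 0L
    max_len <- if (n_seg) max(segment_lengths_px) else 0L
    band_w <- max_len + 60L              # one x-band per segment, 60 px apart
    side_x <- max(loops_per_row * cell_px, n_seg * band_w) + 40L
    side_y <- loop_rows * cell_px + max_len + 100L
    mask <- matrix(FALSE, side_y, side_x)
    skeleton <- matrix(FALSE, side_y, side_x)

    loop_id <- integer(0); hole_side <- integer(0)
    cen_y <- numeric(0); cen_x <- numeric(0)
    for (i in seq_len(n_loops)) {
      row <- (i - 1L) %/% loops_per_row
      col <- (i - 1L) %% loops_per_row
      h <- sample(6:15, 1)               # hole side
      ring <- 3L
      outer_side <- h + 2L * ring
      y0 <- row * cell_px + 3L
      x0 <- col * cell_px + 3L
      ys <- y0:(y0 + outer_side - 1L)
      xs <- x0:(x0 + outer_side - 1L)
      mask[ys, xs] <- TRUE
      hy <- (y0 + ring):(y0 + ring + h - 1L)
      hx <- (x0 + ring):(x0 + ring + h - 1L)
      mask[hy, hx] <- FALSE
      loop_id <- c(loop_id, i)
      hole_side <- c(hole_side, h)
      cen_y <- c(cen_y, mean(hy))
      cen_x <- c(cen_x, mean(hx))
    }

    seg_id <- integer(0); seg_orient <- character(0)
    seg_npx <- integer(0); seg_len <- numeric(0)
    paths <- list()
    nuc_y <- numeric(0); nuc_x <- numeric(0)
    nuc_seg <- integer(0); nuc_off <- numeric(0)
    nuc_counts <- rep(nuclei_per_segment, length.out = n_seg)
    base_y <- loop_rows * cell_px + 60L
    k_nuc <- 0L
    for (s in seq_len(n_seg)) {
      npx <- segment_lengths_px[s]
      horiz <- s %% 2L == 1L
      y0 <- base_y
      x0 <- 20L + (s - 1L) * band_w
      if (horiz) {
        path <- cbind(rep(y0, npx), x0 + seq_len(npx) - 1L)
      } else {
        path <- cbind(y0 + seq_len(npx) - 1L, x0 + seq_len(npx) - 1L)
      }
      skeleton[path] <- TRUE
      step <- if (horiz) 1 else sqrt(2)
      seg_id <- c(seg_id, s)
      seg_orient <- c(seg_orient, if (horiz) "horizontal" else "diagonal")
      seg_npx <- c(seg_npx, npx)
      seg_len <- c(seg_len, (npx - 1) * step * pixel_size_um)
      paths[[s]] <- path
      if (nuc_counts[s] > 0) {
        at <- round(seq(0.2, 0.8, length.out = nuc_counts[s]) * npx)
        for (j in seq_len(nuc_counts[s])) {
          k_nuc <- k_nuc + 1L
          off_um <- nuclei_offset_um[(k_nuc - 1L) %% length(nuclei_offset_um) + 1L]
          p <- path[at[j], ]
          # offset perpendicular to the path; realised to whole pixels so the
          # recorded offset is the exact Euclidean pixel distance
          if (horiz) {
            off_px <- round(off_um / pixel_size_um)
            nuc_y <- c(nuc_y, p[1] - off_px)
            nuc_x <- c(nuc_x, p[2])
            nuc_off <- c(nuc_off, off_px * pixel_size_um)
          } else {
            off_px <- round(off_um / (pixel_size_um * sqrt(2)))
            nuc_y <- c(nuc_y, p[1] - off_px)
            nuc_x <- c(nuc_x, p[2] + off_px)
            nuc_off <- c(nuc_off, off_px * sqrt(2) * pixel_size_um)
          }
          nuc_seg <- c(nuc_seg, s)
        }
      }
    }

    list(
      mask = mask,
      skeleton = skeleton,
      nuclei = tibble(
        nucleus_id = seq_along(nuc_y), y = nuc_y, x = nuc_x,
        segment_id = nuc_seg, offset_um = nuc_off
      ),
      truth = list(
        loops = tibble(
          loop_id = loop_id, hole_side = hole_side,
          area_px = as.numeric(hole_side)^2,
          centroid_y = cen_y, centroid_x = cen_x
        ),
        segments = {
          tb <- tibble(
            segment_id = seg_id, orientation = seg_orient,
            n_pixels = seg_npx, length_um = seg_len
          )
          tb$path <- paths
          tb
        }
      )
    )
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}
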