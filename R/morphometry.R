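#' Detect fully enclosed vascular loops in a binary vessel mask
#'
#' Loops are connected components of the mask complement that do not touch
#' the image border (4-connectivity for the background, so diagonal gaps in
#' the vessel wall do not leak), with at least `min_area_px` pixels. Each
#' loop is measured: pixel-count area, boundary-contour perimeter
#' (8-connected Moore trace, unit orthogonal and sqrt(2) diagonal steps),
#' centroid, and equivalent diameter `sqrt(4 * area / pi)`.
#'
#' @param vessel_mask Logical (or 0/1) matrix; `TRUE` is vessel.
#' @param pixel_size_um Micrometres per pixel.
#' @param min_area_px Minimum hole area in pixels (default 4).
#' @return Tibble `loop_id`, `area_px`, `area_um2`, `perimeter_px`,
#'   `perimeter_um`, `centroid_y`, `centroid_x`, `equiv_diameter_px`,
#'   `equiv_diameter_um`. Empty mask gives zero loops.
#' @export
detect_loops <- function(vessel_mask, pixel_size_um, min_area_px = 4) {
  stopifnot(is.matrix(vessel_mask), pixel_size_um > 0)
  mask <- vessel_mask > 0
  comp <- .label_components(!mask, connectivity = 4)
  nr <- nrow(mask)
  nc <- ncol(mask)
  border <- unique(c(
    comp[1, ], comp[nr, ], comp[, 1], comp[, nc]
  ))
  ids <- setdiff(sort(unique(comp[comp > 0])), border)
  out <- lapply(seq_along(ids), function(k) {
    px <- which(comp == ids[k], arr.ind = TRUE)
    area <- nrow(px)
    if (area < min_area_px) return(NULL)
    hole <- matrix(FALSE, nr, nc)
    hole[px] <- TRUE
    per <- .boundary_perimeter(hole)
    tibble(
      area_px = area,
      area_um2 = area * pixel_size_um^2,
      perimeter_px = per,
      perimeter_um = per * pixel_size_um,
      centroid_y = mean(px[, 1]),
      centroid_x = mean(px[, 2]),
      equiv_diameter_px = sqrt(4 * area / pi),
      equiv_diameter_um = sqrt(4 * area / pi) * pixel_size_um
    )
  })
  out <- bind_rows(out)
  if (!nrow(out)) {
    return(tibble(
      loop_id = integer(), area_px = double(), area_um2 = double(),
      perimeter_px = double(), perimeter_um = double(),
      centroid_y = double(), centroid_x = double(),
      equiv_diameter_px = double(), equiv_diameter_um = double()
    ))
  }
  out %>% mutate(loop_id = row_number()) %>%
    select("loop_id", dplyr::everything())
}

#' Snap nuclear centroids onto a vessel skeleton
#'
#' Each nucleus maps to its nearest skeleton pixel (Euclidean distance;
#' ties broken towards the lexicographically smaller `(row, col)` pixel) and
#' is retained iff the snapping distance is strictly under `max_snap_um`.
#'
#' @param nuclei Tibble with `nucleus_id`, `y`, `x` centroids in pixel
#'   coordinates (fractional allowed).
#' @param skeleton Logical matrix, the one-pixel-wide vessel centreline.
#' @param pixel_size_um Micrometres per pixel.
#' @param max_snap_um Retention radius in micrometres (default 10, strict).
#' @return `nuclei` with `skel_y`, `skel_x`, `snap_dist_um`, `retained`.
#' @export
snap_nuclei <- function(nuclei, skeleton, pixel_size_um, max_snap_um = 10) {
  stopifnot(all(c("nucleus_id", "y", "x") %in% names(nuclei)),
            is.matrix(skeleton), pixel_size_um > 0, max_snap_um > 0)
  sk <- which(skeleton, arr.ind = TRUE)
  if (!nrow(sk)) stop("empty skeleton")
  sk <- sk[order(sk[, 1], sk[, 2]), , drop = FALSE]
  if (!nrow(nuclei)) {
    return(nuclei %>%
             mutate(skel_y = integer(0), skel_x = integer(0),
                    snap_dist_um = double(0), retained = logical(0)))
  }
  res <- lapply(seq_len(nrow(nuclei)), function(i) {
    d2 <- (sk[, 1] - nuclei$y[i])^2 + (sk[, 2] - nuclei$x[i])^2
    j <- which.min(d2)   # first minimum = lexicographically smallest pixel
    tibble(skel_y = unname(sk[j, 1]), skel_x = unname(sk[j, 2]),
           snap_dist_um = unname(sqrt(d2[j])) * pixel_size_um)
  })
  dplyr::bind_cols(nuclei, bind_rows(res)) %>%
    mutate(retained = .data$snap_dist_um < max_snap_um)
}

# Decompose a 1-px skeleton into maximal paths between nodes (branch points:
# > 2 8-connected neighbours; endpoints: exactly 1). Adjacent node pixels are
# grouped into single nodes before tracing. Returns a list of coordinate
# matrices (each path includes its terminal node pixels).
.trace_segments <- function(skeleton) {
  deg <- .neighbour_count(skeleton)
  deg[!skeleton] <- -1L
  nr <- nrow(skeleton)
  is_node <- skeleton & (deg == 1L | deg > 2L)
  lin <- function(p) p[1] + (p[2] - 1L) * nr
  neighbours <- function(p) {
    out <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      q <- c(p[1] + dr, p[2] + dc)
      if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= ncol(skeleton) &&
          skeleton[q[1], q[2]]) {
        out[[length(out) + 1L]] <- q
      }
    }
    out
  }
  node_px <- which(is_node, arr.ind = TRUE)
  if (nrow(node_px)) {
    node_px <- node_px[order(node_px[, 1], node_px[, 2]), , drop = FALSE]
  }
  segs <- list()
  seen <- character(0)
  for (i in seq_len(nrow(node_px))) {
    np <- as.integer(node_px[i, ])
    for (q in neighbours(np)) {
      path <- list(np, q)
      prev <- np
      cur <- q
      while (!is_node[cur[1], cur[2]]) {
        nb <- neighbours(cur)
        nxt <- NULL
        for (cand in nb) {
          if (!(cand[1] == prev[1] && cand[2] == prev[2])) nxt <- cand
        }
        if (is.null(nxt)) break                      # dead end (degree-1 marked node; safety)
        prev <- cur
        cur <- nxt
        path[[length(path) + 1L]] <- cur
      }
      m <- do.call(rbind, path)
      # adjacent branch pixels form one grouped node, not a segment
      if (nrow(m) == 2L && deg[m[1, 1], m[1, 2]] > 2L &&
          deg[m[2, 1], m[2, 2]] > 2L) next
      # canonical key: unordered endpoints + second pixel from the smaller end
      e1 <- lin(m[1, ]); e2 <- lin(m[nrow(m), ])
      s1 <- lin(m[2, ]); s2 <- lin(m[nrow(m) - 1, ])
      key <- if (e1 < e2 || (e1 == e2 && s1 <= s2)) {
        paste(e1, e2, s1, s2)
      } else {
        paste(e2, e1, s2, s1)
      }
      if (key %in% seen) next
      seen <- c(seen, key)
      segs[[length(segs) + 1L]] <- m
    }
  }
  # isolated cycles (no nodes at all) are skipped with a warning
  covered <- matrix(FALSE, nr, ncol(skeleton))
  for (m in segs) covered[m] <- TRUE
  if (any(skeleton & !covered & !is_node)) {
    warning("skeleton contains closed loops without branch points or ",
            "endpoints; these components were skipped")
  }
  segs
}

#' Segment-wise linear endothelial cell density along a skeleton
#'
#' Detects vessel segments as skeleton paths between branch points (> 2
#' 8-connected neighbours) or endpoints, measures each segment's geodesic
#' length (sum of 1 or sqrt(2) pixel steps times the pixel size), counts the
#' retained nuclei snapped onto its pixels, and reports linear density.
#' Branch-point pixels shared by several segments are credited to the first
#' incident segment in deterministic (lexicographic endpoint) order.
#'
#' @param skeleton Logical matrix, thinned to one pixel width.
#' @param assignments Output of [snap_nuclei()]; only `retained` nuclei count.
#' @param pixel_size_um Micrometres per pixel.
#' @return Tibble `segment_id`, `n_pixels`, `length_um`, `n_nuclei`,
#'   `density_per_100um` (cells per 100 micrometres), `density_per_um`, and a
#'   `path` list column of pixel coordinates.
#' @export
segment_density <- function(skeleton, assignments, pixel_size_um) {
  stopifnot(is.matrix(skeleton), pixel_size_um > 0)
  segs <- .trace_segments(skeleton)
  if (!length(segs)) {
    return(tibble(segment_id = integer(), n_pixels = integer(),
                  length_um = double(), n_nuclei = integer(),
                  density_per_100um = double(), density_per_um = double()))
  }
  nr <- nrow(skeleton)
  # deterministic segment order: by sorted endpoint linear indices
  keys <- vapply(segs, function(m) {
    e <- sort(c(m[1, 1] + (m[1, 2] - 1L) * nr,
                m[nrow(m), 1] + (m[nrow(m), 2] - 1L) * nr))
    e[1] * (nr * ncol(skeleton) + 1) + e[2]
  }, numeric(1))
  segs <- segs[order(keys)]

  owner <- integer(nr * ncol(skeleton))     # pixel -> first incident segment
  lengths_um <- numeric(length(segs))
  for (s in seq_along(segs)) {
    m <- segs[[s]]
    steps <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
    lengths_um[s] <- sum(steps) * pixel_size_um
    pix <- m[, 1] + (m[, 2] - 1L) * nr
    unclaimed <- owner[pix] == 0L
    owner[pix[unclaimed]] <- s
  }
  keep <- lengths_um > 0
  if (any(!keep)) warning("skipping zero-length segment(s)")

  ret <- assignments %>% filter(.data$retained)
  nuc_pix <- ret$skel_y + (ret$skel_x - 1L) * nr
  counts <- tabulate(owner[nuc_pix], nbins = length(segs))

  out <- tibble(
    segment_id = seq_along(segs),
    n_pixels = vapply(segs, nrow, integer(1)),
    length_um = lengths_um,
    n_nuclei = counts,
    density_per_100um = ifelse(lengths_um > 0, 100 * counts / lengths_um, NA_real_),
    density_per_um = ifelse(lengths_um > 0, counts / lengths_um, NA_real_)
  )
  out$path <- segs
  out[keep, ]
}

#' Normalised extravascular intensity (dextran extravasation) series
#'
#' The extravascular region is the complement of the vessel mask dilated by
#' `dilate_px` (default 2, guarding against partial-volume bleed at vessel
#' edges; 0 reproduces the literal mask complement). The per-frame mean
#' extravascular intensity of the post-injection movie is normalised to the
#' average extravascular intensity of the pre-dextran recording.
#'
#' @param movie Post-injection array `y x x x frame`.
#' @param vessel_mask Logical matrix (vessel surface), aligned to both movies.
#' @param pre_movie Pre-dextran array with the same spatial shape.
#' @param frame_interval Seconds per frame of the post movie.
#' @param dilate_px Dilation margin in pixels (default 2).
#' @param report_times_min Minutes post-injection at which to sample the
#'   series (nearest frame; default `c(0, 0.5, 1, 2, 5)`). Times beyond the
#'   recording are dropped.
#' @return A `capnet_permeability` list: `series` (tibble `frame`,
#'   `time_min`, `extravascular_mfi`, `normalized`), `at_times` (tibble
#'   `time_min`, `frame`, `normalized`), `pre_dextran_mean`.
#' @export
extravascular_permeability <- function(movie, vessel_mask, pre_movie,
                                       frame_interval,
                                       dilate_px = 2,
                                       report_times_min = c(0, 0.5, 1, 2, 5)) {
  stopifnot(is.array(movie), length(dim(movie)) == 3,
            is.array(pre_movie), length(dim(pre_movie)) == 3,
            frame_interval > 0, dilate_px >= 0)
  if (!all(dim(vessel_mask) == dim(movie)[1:2]) ||
      !all(dim(pre_movie)[1:2] == dim(movie)[1:2])) {
    stop("vessel mask and movies must share the spatial shape")
  }
  extra <- !.dilate_square(vessel_mask > 0, as.integer(dilate_px))
  if (!any(extra)) stop("no extravascular pixels after dilation")
  idx <- which(extra)
  pre_flat <- matrix(pre_movie, prod(dim(pre_movie)[1:2]), dim(pre_movie)[3])
  pre_mean <- mean(pre_flat[idx, ])
  if (pre_mean == 0) stop("pre-dextran extravascular mean is zero; normalisation undefined")
  flat <- matrix(movie, prod(dim(movie)[1:2]), dim(movie)[3])
  mfi <- colMeans(flat[idx, , drop = FALSE])
  nt <- dim(movie)[3]
  series <- tibble(
    frame = seq_len(nt),
    time_min = (seq_len(nt) - 1) * frame_interval / 60,
    extravascular_mfi = mfi,
    normalized = mfi / pre_mean
  )
  tmax <- max(series$time_min)
  times <- report_times_min[report_times_min <= tmax]
  at <- tibble(
    time_min = times,
    frame = vapply(times, function(t) which.min(abs(series$time_min - t)),
                   integer(1))
  ) %>%
    mutate(normalized = series$normalized[.data$frame])
  structure(
    list(series = series, at_times = at, pre_dextran_mean = pre_mean),
    class = "capnet_permeability"
  )
}
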