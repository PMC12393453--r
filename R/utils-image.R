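# Internal raster primitives shared by the morphometry and cluster modules.
# No image-processing package with these primitives is available, and several
# (hole detection, boundary perimeter, skeleton tracing) are the measurements
# themselves, so they are implemented here against small binary matrices.

# Linear indices of pairs of TRUE pixels separated by (dr, dc).
.adjacent_pairs <- function(mask, dr, dc) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  ra <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
  ca <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
  if (!length(ra) || !length(ca)) return(NULL)
  a <- mask[ra, ca, drop = FALSE]
  b <- mask[ra + dr, ca + dc, drop = FALSE]
  hit <- which(a & b)
  if (!length(hit)) return(NULL)
  r0 <- ra[(hit - 1L) %% length(ra) + 1L]
  c0 <- ca[(hit - 1L) %/% length(ra) + 1L]
  cbind(r0 + (c0 - 1L) * nr, (r0 + dr) + (c0 + dc - 1L) * nr)
}

# Label connected components of a logical matrix. Returns an integer matrix
# with 0 background and components numbered 1..k in first-pixel order.
.label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(lab)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(offs, function(o) .adjacent_pairs(mask, o[1], o[2])))
  vid <- integer(length(lab))
  vid[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, rbind(vid[edges[, 1]], vid[edges[, 2]]))
  }
  memb <- igraph::components(g)$membership
  # renumber by first occurrence so labelling is deterministic
  memb <- match(memb, unique(memb))
  lab[idx] <- memb
  lab
}

# Binary dilation with a (2*margin+1) square structuring element.
.dilate_square <- function(mask, margin) {
  if (margin <= 0) return(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- mask
  for (dr in -margin:margin) {
    for (dc in -margin:margin) {
      if (dr == 0 && dc == 0) next
      ra <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
      ca <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
      if (!length(ra) || !length(ca)) next
      out[ra + dr, ca + dc] <- out[ra + dr, ca + dc] | mask[ra, ca, drop = FALSE]
    }
  }
  out
}

# Count of TRUE 8-neighbours for every pixel.
.neighbour_count <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      ra <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
      ca <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
      if (!length(ra) || !length(ca)) next
      out[ra + dr, ca + dc] <- out[ra + dr, ca + dc] + mask[ra, ca, drop = FALSE]
    }
  }
  out
}

# Moore-neighbour boundary trace of a single connected component; returns the
# contour length with unit orthogonal and sqrt(2) diagonal steps. Components
# of 1 pixel have, by this estimator, perimeter 0.
.boundary_perimeter <- function(comp) {
  px <- which(comp, arr.ind = TRUE)
  if (nrow(px) <= 1) return(0)
  nr <- nrow(comp)
  # clockwise Moore neighbourhood starting West
  dirs <- rbind(
    c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
    c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L)
  )
  inside <- function(p) {
    p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= ncol(comp) && comp[p[1], p[2]]
  }
  ord <- order(px[, 1], px[, 2])
  start <- px[ord[1], ]                     # topmost-leftmost: W neighbour is bg
  backtrack_dir <- 1L                       # direction index pointing at W
  cur <- start
  perim <- 0
  first_move <- NULL
  steps <- 0L
  repeat {
    found <- FALSE
    d <- backtrack_dir
    for (k in 0:7) {
      di <- ((d - 1L + k) %% 8L) + 1L
      cand <- cur + dirs[di, ]
      if (inside(cand)) {
        step_len <- sqrt(sum(dirs[di, ]^2))
        # closure check: back at start making the same first move again
        if (steps > 0L && all(cur == start)) {
          if (!is.null(first_move) && di == first_move) return(perim)
        }
        if (is.null(first_move)) first_move <- di
        perim <- perim + step_len
        # new backtrack: direction from new pixel towards previous background
        prev_di <- ((di - 2L) %% 8L) + 1L
        bg <- cur + dirs[prev_di, ]
        delta <- bg - cand
        backtrack_dir <- which(dirs[, 1] == delta[1] & dirs[, 2] == delta[2])
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) return(0)                   # isolated pixel (shouldn't happen here)
    steps <- steps + 1L
    if (steps > 8L * nrow(px) + 8L) return(perim)  # safety cap
  }
}
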