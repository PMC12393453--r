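# Independent oracles used across the suite. These are deliberately naive
# (frame-by-frame loops, label propagation) and share no code with the
# package implementations they check.

# Brute-force event detector: per-frame windowed minimum computed by direct
# subsetting, explicit supra-threshold scan, run merge by linear pass.
oracle_events <- function(mfi, window = 100, ratio = 0.5) {
  n <- length(mfi)
  ref <- numeric(n)
  for (t in seq_len(n)) {
    w0 <- ((t - 1) %/% window) * window + 1
    w1 <- min(n, w0 + window - 1)
    ref[t] <- min(mfi[w0:w1])
  }
  supra <- mfi > (1 + ratio) * ref
  starts <- integer(0); ends <- integer(0); s <- NA_integer_
  for (t in seq_len(n)) {
    if (supra[t] && is.na(s)) s <- t
    if (!supra[t] && !is.na(s)) {
      starts <- c(starts, s); ends <- c(ends, t - 1L); s <- NA_integer_
    }
  }
  if (!is.na(s)) {
    starts <- c(starts, s); ends <- c(ends, n)
  }
  data.frame(start_frame = starts, end_frame = ends)
}

# Spatiotemporal flood fill by label propagation on active (row, col, frame)
# entries: two entries are linked iff grids identical/adjacent and frames
# within 1. Returns component ids numbered by first entry.
oracle_clusters <- function(entries, connectivity = 8) {
  n <- nrow(entries)
  if (n == 0) return(integer(0))
  dr <- abs(outer(entries$row, entries$row, "-"))
  dc <- abs(outer(entries$col, entries$col, "-"))
  df <- abs(outer(entries$frame, entries$frame, "-"))
  adj <- if (connectivity == 8) pmax(dr, dc) <= 1 else (dr + dc) <= 1
  adj <- adj & df <= 1
  diag(adj) <- TRUE
  lab <- seq_len(n)
  repeat {
    new_lab <- vapply(seq_len(n), function(i) min(lab[adj[i, ]]), integer(1))
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  match(lab, unique(lab))
}

# Event-level recall/precision: a planted event is recalled if any detected
# event of the same cell overlaps it, and vice versa for precision.
event_recall_precision <- function(truth, detected) {
  overlaps <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      any(b$cell_id == a$cell_id[i] &
            b$start_frame <= a$end_frame[i] &
            b$end_frame >= a$start_frame[i])
    }, logical(1))
  }
  c(
    recall = if (nrow(truth)) mean(overlaps(truth, detected)) else 1,
    precision = if (nrow(detected)) mean(overlaps(detected, truth)) else 1
  )
}

# Random grid raster as long-form entries on an nr x nc grid over nt frames.
random_raster_entries <- function(nr, nc, nt, density = 0.3) {
  on <- which(array(runif(nr * nc * nt) < density, dim = c(nr, nc, nt)))
  r <- ((on - 1) %% (nr * nc)) %% nr + 1
  cc <- ((on - 1) %% (nr * nc)) %/% nr + 1
  f <- (on - 1) %/% (nr * nc) + 1
  d <- data.frame(row = r, col = cc, frame = f)
  d$grid_id <- (d$row - 1L) * nc + d$col
  d[order(d$frame, d$row, d$col), ]
}

# Geometry tibble for a full nr x nc grid with unit-square mm bounds.
full_grid_geometry <- function(nr, nc) {
  g <- expand.grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L)
  tibble::tibble(
    grid_id = g$row * nc + g$col + 1L,
    row = g$row, col = g$col,
    y0_mm = as.numeric(g$row), y1_mm = g$row + 1,
    x0_mm = as.numeric(g$col), x1_mm = g$col + 1,
    n_pixels = 1L
  )
}
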