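#' Extract per-cell mean fluorescence traces from a movie
#'
#' For every nonzero label in the nuclear mask, computes the arithmetic mean
#' of the movie over the ROI's pixels at each frame. The nuclear ROI itself
#' is the cell proxy (no dilation into the cytoplasm).
#'
#' @param movie Numeric array `y x x x frame`.
#' @param labels Integer matrix of the same spatial shape; 0 is background,
#'   each positive integer one nuclear ROI.
#' @return Tibble with `cell_id`, `frame` (1-based), `mfi`, `n_pixels`,
#'   sorted by label. Labels in `1:max(labels)` with no pixels are skipped
#'   with a warning.
#' @export
extract_traces <- function(movie, labels) {
  stopifnot(is.array(movie), length(dim(movie)) == 3)
  if (!all(dim(labels) == dim(movie)[1:2])) {
    stop("label mask shape ", paste(dim(labels), collapse = "x"),
         " does not match movie frames ",
         paste(dim(movie)[1:2], collapse = "x"))
  }
  if (any(labels < 0)) stop("labels must be nonnegative integers")
  nt <- dim(movie)[3]
  flat <- matrix(movie, prod(dim(movie)[1:2]), nt)
  ids <- sort(unique(labels[labels > 0]))
  missing <- setdiff(seq_len(max(labels, 0)), ids)
  if (length(missing)) {
    warning("skipping empty labels: ", paste(missing, collapse = ", "))
  }
  pix <- split(which(labels > 0), labels[labels > 0])
  mfi <- vapply(ids, function(l) colMeans(flat[pix[[as.character(l)]], , drop = FALSE]),
                numeric(nt))
  npx <- vapply(ids, function(l) length(pix[[as.character(l)]]), integer(1))
  tibble(
    cell_id = rep(ids, each = nt),
    frame = rep(seq_len(nt), times = length(ids)),
    mfi = as.vector(mfi),
    n_pixels = rep(npx, each = nt)
  )
}

#' Extract per-grid traces over a vessel-surface tiling
#'
#' Tiles the field with square grids of physical side `grid_size_mm`
#' (default 0.0076 mm), anchored at the image origin; edge grids may be
#' partial. A grid is retained iff it overlaps at least one vessel-mask
#' pixel, and its trace is the per-frame mean over its vessel pixels only,
#' so every vessel pixel contributes to exactly one grid.
#'
#' @param movie Numeric array `y x x x frame`.
#' @param vessel_mask Logical matrix, same spatial shape.
#' @param pixel_size_mm Pixel pitch in mm.
#' @param grid_size_mm Grid side in mm (default 0.0076).
#' @return List with `traces` (tibble `grid_id`, `frame`, `mfi`) and
#'   `geometry` (tibble `grid_id`, `row`, `col` 0-based tile indices,
#'   half-open bounds `y0_mm`, `y1_mm`, `x0_mm`, `x1_mm`, `n_pixels`).
#'   An empty vessel mask yields zero grids.
#' @export
extract_grid_traces <- function(movie, vessel_mask, pixel_size_mm,
                                grid_size_mm = 0.0076) {
  stopifnot(is.array(movie), length(dim(movie)) == 3,
            pixel_size_mm > 0, grid_size_mm > 0)
  if (!all(dim(vessel_mask) == dim(movie)[1:2])) {
    stop("vessel mask shape does not match movie frames")
  }
  nt <- dim(movie)[3]
  idx <- which(vessel_mask)
  if (!length(idx)) {
    return(list(
      traces = tibble(grid_id = integer(), frame = integer(), mfi = double()),
      geometry = tibble(
        grid_id = integer(), row = integer(), col = integer(),
        y0_mm = double(), y1_mm = double(), x0_mm = double(), x1_mm = double(),
        n_pixels = integer()
      )
    ))
  }
  nr <- dim(movie)[1]
  rows <- (idx - 1L) %% nr
  cols <- (idx - 1L) %/% nr
  grow <- floor(rows * pixel_size_mm / grid_size_mm)
  gcol <- floor(cols * pixel_size_mm / grid_size_mm)
  key <- paste(grow, gcol)
  geom <- tibble(row = grow, col = gcol, key = key, idx = idx) %>%
    group_by(.data$row, .data$col, .data$key) %>%
    summarise(n_pixels = n(), .groups = "drop") %>%
    arrange(.data$row, .data$col) %>%
    mutate(
      grid_id = row_number(),
      y0_mm = .data$row * grid_size_mm, y1_mm = (.data$row + 1) * grid_size_mm,
      x0_mm = .data$col * grid_size_mm, x1_mm = (.data$col + 1) * grid_size_mm
    )
  flat <- matrix(movie, prod(dim(movie)[1:2]), nt)
  by_key <- split(idx, key)
  traces <- lapply(seq_len(nrow(geom)), function(i) {
    pix <- by_key[[geom$key[i]]]
    tibble(
      grid_id = geom$grid_id[i], frame = seq_len(nt),
      mfi = colMeans(flat[pix, , drop = FALSE])
    )
  })
  list(
    traces = bind_rows(traces),
    geometry = geom %>%
      select("grid_id", "row", "col", "y0_mm", "y1_mm", "x0_mm", "x1_mm",
             "n_pixels")
  )
}
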