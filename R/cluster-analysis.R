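#' Call Ca2+ events on vessel-surface grid traces
#'
#' Applies exactly the per-cell thresholding semantics of [call_events()] to
#' each grid trace: windowed-minimum normalisation and a strict
#' 50-percent-above-minimum rule at the defaults.
#'
#' @param grid_traces Tibble `grid_id`, `frame`, `mfi` (the `traces` element
#'   of [extract_grid_traces()]).
#' @param frame_interval Seconds per frame.
#' @param window,threshold_ratio,gap_tolerance As in [call_events()].
#' @return List with `entries` (tibble of active `grid_id`, `frame` pairs —
#'   the grid raster in long form) and `events` (per-grid event intervals).
#' @export
call_grid_events <- function(grid_traces, frame_interval, window = 100,
                             threshold_ratio = 0.5, gap_tolerance = 0) {
  ev <- grid_traces %>%
    rename(cell_id = "grid_id") %>%
    call_events(frame_interval, window, threshold_ratio, gap_tolerance) %>%
    rename(grid_id = "cell_id")
  entries <- tibble(
    grid_id = rep(ev$grid_id, ev$end_frame - ev$start_frame + 1),
    frame = as.integer(unlist(Map(seq.int, ev$start_frame, ev$end_frame),
                              use.names = FALSE))
  ) %>%
    arrange(.data$grid_id, .data$frame)
  list(entries = entries, events = ev)
}

#' Link supra-threshold grid activity into multicellular clusters
#'
#' Nodes are the active `(grid, frame)` entries. Two entries are linked iff
#' their grids are identical or spatially adjacent and their frames differ by
#' at most `frame_tolerance` (default 1: same frame or one frame apart);
#' clusters are the connected components of this relation. Spatial adjacency
#' defaults to 8-connectivity over grid `(row, col)` indices (vessels run
#' diagonally across the tiling); set `connectivity = 4` for edge-sharing
#' only.
#'
#' @param entries Tibble of active `grid_id`, `frame` pairs.
#' @param geometry Grid geometry tibble from [extract_grid_traces()].
#' @param connectivity 8 (default) or 4.
#' @param frame_tolerance Maximum frame gap linking two entries (default 1).
#' @return `entries` with `row`, `col` and a `cluster_id` column; clusters
#'   are numbered by first active entry.
#' @export
link_clusters <- function(entries, geometry, connectivity = 8,
                          frame_tolerance = 1) {
  stopifnot(connectivity %in% c(4, 8), frame_tolerance >= 0)
  nodes <- entries %>%
    inner_join(geometry %>% select("grid_id", "row", "col"), by = "grid_id") %>%
    arrange(.data$frame, .data$row, .data$col) %>%
    mutate(node = row_number())
  if (!nrow(nodes)) {
    return(nodes %>% mutate(cluster_id = integer(0)) %>% select(-"node"))
  }
  edges <- list()
  for (df in 0:frame_tolerance) {
    b <- nodes %>%
      mutate(frame = .data$frame - df) %>%
      rename(node_b = "node", row_b = "row", col_b = "col", grid_b = "grid_id")
    pair <- nodes %>%
      inner_join(b, by = "frame", relationship = "many-to-many") %>%
      filter(.data$node < .data$node_b | df > 0)
    pair <- if (connectivity == 8) {
      pair %>% filter(abs(.data$row - .data$row_b) <= 1,
                      abs(.data$col - .data$col_b) <= 1)
    } else {
      pair %>% filter(abs(.data$row - .data$row_b) +
                        abs(.data$col - .data$col_b) <= 1)
    }
    edges[[length(edges) + 1L]] <- pair %>% select("node", "node_b")
  }
  edges <- bind_rows(edges)
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$node, edges$node_b))
  }
  memb <- igraph::components(g)$membership
  nodes %>%
    mutate(cluster_id = match(memb, unique(memb))) %>%
    select(-"node")
}

#' Summarise linked clusters
#'
#' @param members Output of [link_clusters()].
#' @return Tibble `cluster_id`, `n_grids` (distinct grids — the maximum
#'   number of grids with connected activity), `n_entries`, `t_min`, `t_max`.
#' @export
summarise_clusters <- function(members) {
  if (!nrow(members)) {
    return(tibble(cluster_id = integer(), n_grids = integer(),
                  n_entries = integer(), t_min = integer(), t_max = integer()))
  }
  members %>%
    group_by(.data$cluster_id) %>%
    summarise(
      n_grids = n_distinct(.data$grid_id),
      n_entries = n(),
      t_min = min(.data$frame),
      t_max = max(.data$frame),
      .groups = "drop"
    )
}

#' Count endothelial cells participating in each cluster
#'
#' A nucleus belongs to a cluster iff its centroid lies inside the union of
#' the cluster's member-grid bounds; bounds are half-open (`[y0, y1)`), so a
#' centroid on a shared grid edge is counted exactly once.
#'
#' @param members Output of [link_clusters()].
#' @param geometry Grid geometry tibble (bounds in mm).
#' @param nuclei Tibble with `nucleus_id`, `y_mm`, `x_mm` centroids in the
#'   same frame of reference as the grid bounds.
#' @return [summarise_clusters()] output with an `n_cells` column.
#' @export
count_cluster_cells <- function(members, geometry, nuclei) {
  stopifnot(all(c("nucleus_id", "y_mm", "x_mm") %in% names(nuclei)))
  cluster_grids <- members %>%
    distinct(.data$cluster_id, .data$grid_id) %>%
    inner_join(geometry, by = "grid_id")
  hits <- cluster_grids %>%
    dplyr::cross_join(nuclei) %>%
    filter(.data$y_mm >= .data$y0_mm, .data$y_mm < .data$y1_mm,
           .data$x_mm >= .data$x0_mm, .data$x_mm < .data$x1_mm) %>%
    distinct(.data$cluster_id, .data$nucleus_id) %>%
    count(.data$cluster_id, name = "n_cells")
  summarise_clusters(members) %>%
    left_join(hits, by = "cluster_id") %>%
    mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L))
}

#' Distribution of Ca2+ activity by cluster size
#'
#' Bins clusters by the number of participating cells into the sizes used to
#' describe multicellular activity: single cells, 2-4 cells, and 5 or more.
#'
#' @param cluster_summary Tibble with an `n_cells` column (from
#'   [count_cluster_cells()]), or `n_grids` if cell counts are unavailable
#'   (set `size_col`).
#' @param size_col Column holding the cluster size (default `"n_cells"`).
#' @return Tibble `size_bin` (`"1"`, `"2-4"`, `">=5"`), `n_clusters`,
#'   `proportion` (sums to 1); the raw size histogram is attached as
#'   attribute `histogram`.
#' @export
cluster_size_distribution <- function(cluster_summary, size_col = "n_cells") {
  sizes <- cluster_summary[[size_col]]
  stopifnot(!is.null(sizes))
  bins <- cut(sizes, breaks = c(-Inf, 1, 4, Inf), labels = c("1", "2-4", ">=5"))
  out <- tibble(size_bin = factor(c("1", "2-4", ">=5"),
                                  levels = c("1", "2-4", ">=5"))) %>%
    left_join(
      tibble(size_bin = bins) %>% count(.data$size_bin, name = "n_clusters"),
      by = "size_bin"
    ) %>%
    mutate(
      n_clusters = dplyr::coalesce(.data$n_clusters, 0L),
      proportion = if (length(sizes)) .data$n_clusters / length(sizes) else 0
    )
  attr(out, "histogram") <- tibble(size = sizes) %>% count(.data$size)
  out
}

#' Identify persistently active clusters
#'
#' A cluster is persistently active iff at least one of its member grids is
#' active in at least `full_span_fraction` of the recording's frames
#' (default 1: simultaneously active for the entire recording).
#'
#' @param members Output of [link_clusters()].
#' @param n_frames Frames in the recording.
#' @param full_span_fraction Required active fraction per grid (default 1).
#' @return [summarise_clusters()] rows for the persistent clusters only, with
#'   a `persistent` column (all `TRUE`); empty tibble if none qualify.
#' @export
persistent_clusters <- function(members, n_frames, full_span_fraction = 1) {
  stopifnot(n_frames >= 1, full_span_fraction > 0, full_span_fraction <= 1)
  grid_activity <- members %>%
    count(.data$cluster_id, .data$grid_id, name = "n_active")
  keep <- grid_activity %>%
    filter(.data$n_active >= full_span_fraction * n_frames) %>%
    distinct(.data$cluster_id)
  summarise_clusters(members) %>%
    inner_join(keep, by = "cluster_id") %>%
    mutate(persistent = TRUE)
}
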