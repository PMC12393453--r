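entries_tbl <- function(...) {
  d <- tibble::tibble(...)
  d[, c("grid_id", "frame")]
}

test_that("grid event calling matches the cell-level detector semantics", {
  # all-baseline grids: empty raster
  gt <- tibble::tibble(grid_id = rep(1:3, each = 50),
                       frame = rep(1:50, 3), mfi = 100)
  expect_equal(nrow(call_grid_events(gt, 3.44)$entries), 0)
  # one grid excursion 1.6x min for 3 frames
  gt$mfi[gt$grid_id == 2 & gt$frame %in% 20:22] <- 160
  ge <- call_grid_events(gt, 3.44)
  expect_equal(ge$entries$grid_id, rep(2L, 3))
  expect_equal(ge$entries$frame, 20:22)
  # grid coinciding with a cell ROI gives identical events
  rec <- generate_recording(recording_spec(n_cells = 6, noise_sd = 0, rng_seed = 12))
  tr <- extract_traces(rec$movie, rec$labels)
  cell_ev <- call_events(tr, 3.44)
  grid_ev <- call_grid_events(
    tr |> dplyr::rename(grid_id = cell_id), 3.44
  )$events
  expect_equal(grid_ev$start_frame, cell_ev$start_frame)
  expect_equal(grid_ev$end_frame, cell_ev$end_frame)
})

test_that("adjacent grids one frame apart link; two steps or two frames do not", {
  geom <- full_grid_geometry(4, 4)
  # edge-adjacent grids active at frames 10 and 11: one cluster of 2 grids
  e1 <- entries_tbl(grid_id = c(1L, 2L), frame = c(10L, 11L))
  cl <- link_clusters(e1, geom)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1)
  expect_equal(summarise_clusters(cl)$n_grids, 2)
  # two frames apart: two clusters
  e2 <- entries_tbl(grid_id = c(1L, 2L), frame = c(10L, 12L))
  expect_equal(dplyr::n_distinct(link_clusters(e2, geom)$cluster_id), 2)
  # two grid steps apart (grid 1 and 3 in a row): two clusters
  e3 <- entries_tbl(grid_id = c(1L, 3L), frame = c(10L, 10L))
  expect_equal(dplyr::n_distinct(link_clusters(e3, geom)$cluster_id), 2)
  # diagonal neighbours link at 8- but not 4-connectivity
  e4 <- entries_tbl(grid_id = c(1L, 6L), frame = c(10L, 10L))
  expect_equal(dplyr::n_distinct(link_clusters(e4, geom, connectivity = 8)$cluster_id), 1)
  expect_equal(dplyr::n_distinct(link_clusters(e4, geom, connectivity = 4)$cluster_id), 2)
})

test_that("clusters equal the flood-fill oracle and partition the entries", {
  set.seed(77)
  for (k in 1:60) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1); nt <- sample(3:20, 1)
    e <- random_raster_entries(nr, nc, nt, density = 0.3)
    if (!nrow(e)) next
    geom <- full_grid_geometry(nr, nc)
    for (conn in c(8, 4)) {
      cl <- link_clusters(tibble::as_tibble(e[, c("grid_id", "frame")]),
                          geom, connectivity = conn)
      orc <- oracle_clusters(e, connectivity = conn)
      # identical partitions up to relabelling: compare canonical forms
      key <- paste(e$grid_id, e$frame)
      cl_key <- paste(cl$grid_id, cl$frame)
      canon <- function(keys, labels) {
        unname(sort(vapply(split(keys, labels),
                           function(g) paste(sort(g), collapse = ";"),
                           character(1))))
      }
      expect_equal(canon(cl_key, cl$cluster_id), canon(key, orc))
      # every active entry belongs to exactly one cluster
      expect_equal(nrow(cl), nrow(e))
      expect_false(any(duplicated(cl_key)))
    }
  }
})

test_that("cluster count is invariant under frame-axis reversal", {
  set.seed(13)
  for (k in 1:20) {
    e <- random_raster_entries(5, 5, 12, density = 0.25)
    if (!nrow(e)) next
    geom <- full_grid_geometry(5, 5)
    a <- link_clusters(tibble::as_tibble(e[, c("grid_id", "frame")]), geom)
    rev_e <- e
    rev_e$frame <- 13L - rev_e$frame
    b <- link_clusters(tibble::as_tibble(rev_e[, c("grid_id", "frame")]), geom)
    expect_equal(dplyr::n_distinct(a$cluster_id), dplyr::n_distinct(b$cluster_id))
  }
})

test_that("nuclei are counted once per cluster with half-open grid bounds", {
  geom <- full_grid_geometry(4, 4)
  e <- entries_tbl(grid_id = c(1L, 2L, 5L, 6L), frame = c(10L, 10L, 10L, 11L))
  cl <- link_clusters(e, geom)
  nuclei <- tibble::tibble(
    nucleus_id = 1:4,
    y_mm = c(0.5, 0.5, 1.5, 3.9),
    x_mm = c(0.2, 1.3, 0.4, 3.9)
  )
  cc <- count_cluster_cells(cl, geom, nuclei)
  expect_equal(cc$n_cells, 3)          # 3 centroids inside, 1 elsewhere
  # centroid exactly on a shared boundary: belongs to the right/lower grid only
  on_edge <- tibble::tibble(nucleus_id = 1L, y_mm = 0.5, x_mm = 1.0)
  cc2 <- count_cluster_cells(cl, geom, on_edge)
  expect_equal(cc2$n_cells, 1)
})

test_that("planted multicellular co-activity is recovered at the planted size", {
  # three cells under a 2x2 active grid patch firing together
  set.seed(3)
  sizes <- vapply(1:25, function(k) {
    geom <- full_grid_geometry(6, 6)
    rows <- sample(1:5, 1); cols <- sample(1:5, 1)
    gids <- geom$grid_id[geom$row %in% c(rows - 1, rows) &
                           geom$col %in% c(cols - 1, cols)]
    f0 <- sample(3:15, 1)
    e <- tibble::tibble(grid_id = rep(gids, 2),
                        frame = rep(c(f0, f0 + 1L), each = length(gids)))
    cl <- link_clusters(e, geom)
    nuclei <- tibble::tibble(
      nucleus_id = 1:3,
      y_mm = rows - 1 + c(0.2, 0.8, 1.2),
      x_mm = cols - 1 + c(0.3, 1.1, 0.6)
    )
    count_cluster_cells(cl, geom, nuclei)$n_cells[1]
  }, integer(1))
  expect_equal(unique(sizes), 3L)
})

test_that("cluster size distribution bins 1 / 2-4 / >=5 and sums to one", {
  all_single <- tibble::tibble(cluster_id = 1:7, n_cells = 1L)
  d1 <- cluster_size_distribution(all_single)
  expect_equal(d1$proportion, c(1, 0, 0))
  mixed <- tibble::tibble(cluster_id = 1:21,
                          n_cells = c(rep(1L, 10), rep(3L, 10), 6L))
  d2 <- cluster_size_distribution(mixed)
  expect_equal(d2$proportion, c(10 / 21, 10 / 21, 1 / 21))
  set.seed(4)
  rand <- tibble::tibble(cluster_id = 1:50, n_cells = sample(0:9, 50, TRUE))
  expect_equal(sum(cluster_size_distribution(rand)$proportion), 1)
})

test_that("persistent clusters require a grid active for the full span", {
  geom <- full_grid_geometry(3, 3)
  e <- entries_tbl(grid_id = rep(1L, 300), frame = 1:300)
  cl <- link_clusters(e, geom)
  expect_equal(nrow(persistent_clusters(cl, 300)), 1)
  # 299/300 frames: not persistent at fraction 1, persistent at 0.95
  e2 <- entries_tbl(grid_id = rep(1L, 299), frame = 1:299)
  cl2 <- link_clusters(e2, geom)
  expect_equal(nrow(persistent_clusters(cl2, 300, 1)), 0)
  expect_equal(nrow(persistent_clusters(cl2, 300, 0.95)), 1)
  expect_equal(nrow(persistent_clusters(cl2[0, ], 300)), 0)
})
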