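#' Write per-cell traces to a wide CSV
#'
#' One row per frame, one column per cell (`cell_<id>`), preceded by a
#' comment header recording the frame interval.
#'
#' @param traces Tibble `cell_id`, `frame`, `mfi`.
#' @param path Output file.
#' @param frame_interval Seconds per frame, stored in the header.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, frame_interval) {
  wide <- traces %>%
    select("cell_id", "frame", "mfi") %>%
    mutate(cell_id = paste0("cell_", .data$cell_id)) %>%
    tidyr::pivot_wider(names_from = "cell_id", values_from = "mfi") %>%
    arrange(.data$frame)
  writeLines(sprintf("# frame_interval: %.10g", frame_interval), path)
  readr::write_csv(wide, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read per-cell traces from a wide CSV
#'
#' Inverse of [write_traces()]. The frame interval from the comment header
#' (if present) is attached as attribute `frame_interval`.
#'
#' @param path CSV file with a `frame` column and `cell_<id>` columns.
#' @return Long tibble `cell_id`, `frame`, `mfi`.
#' @export
read_traces <- function(path) {
  first <- readLines(path, n = 1)
  fi <- NULL
  if (grepl("^#\\s*frame_interval:", first)) {
    fi <- as.numeric(sub("^#\\s*frame_interval:\\s*", "", first))
  }
  wide <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  out <- wide %>%
    tidyr::pivot_longer(-"frame", names_to = "cell_id", values_to = "mfi") %>%
    mutate(cell_id = as.integer(sub("^cell_", "", .data$cell_id))) %>%
    arrange(.data$cell_id, .data$frame)
  if (!is.null(fi)) attr(out, "frame_interval") <- fi
  out
}

#' Read an event-interval table
#'
#' Accepts `cell_id, start_frame, end_frame` (1-based inclusive frames) or
#' `cell_id, start_s, end_s` (converted using `frame_interval`). Durations
#' are (re)computed as `(end_frame - start_frame + 1) * frame_interval`.
#'
#' @param path CSV file.
#' @param frame_interval Seconds per frame; required to compute durations
#'   and to convert second-based tables.
#' @return Tibble `cell_id`, `start_frame`, `end_frame`, `duration_s`.
#' @export
read_event_table <- function(path, frame_interval) {
  stopifnot(frame_interval > 0)
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("start_frame", "end_frame") %in% names(d))) {
    ev <- d
  } else if (all(c("start_s", "end_s") %in% names(d))) {
    ev <- d %>% mutate(
      start_frame = as.integer(round(.data$start_s / frame_interval)) + 1L,
      end_frame = as.integer(round(.data$end_s / frame_interval))
    )
  } else {
    stop("expected columns cell_id,start_frame,end_frame or cell_id,start_s,end_s")
  }
  ev %>%
    mutate(duration_s = (.data$end_frame - .data$start_frame + 1) * frame_interval) %>%
    select("cell_id", "start_frame", "end_frame", "duration_s") %>%
    arrange(.data$cell_id, .data$start_frame)
}
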