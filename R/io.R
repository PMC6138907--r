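#' Read a cell table from CSV
#'
#' The on-disk cell-table dialect: comma-separated, UTF-8, mandatory header
#' row with at least `cell_id`, `x`, `y`, plus either marker intensity
#' columns (`CD4`, `PD1`, `FOXP3`, `Ki67`) or a `label` column of
#' pre-assigned phenotypes. Coordinates are micrometres, Cartesian, origin
#' at the window's lower-left corner. An optional sidecar header line
#' `#window: x_min y_min x_max y_max` before the CSV header declares the
#' observation window; otherwise the bounding rectangle of the coordinates
#' is used. Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param y_flip Set `TRUE` for image-convention input (y increasing
#'   downwards); coordinates are flipped about the window's horizontal
#'   midline so the in-memory convention is always y-up.
#' @return List with `cells` (data frame) and `window`
#'   ([tissue_window()]).
#' @export
read_cell_table <- function(path, y_flip = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  first <- readLines(path, n = 1)
  window <- NULL
  skip <- 0
  if (startsWith(first, "#window:")) {
    vals <- as.numeric(strsplit(trimws(sub("^#window:", "", first)),
                                "\\s+")[[1]])
    if (length(vals) != 4 || any(!is.finite(vals))) {
      stop("malformed #window: header; expected 4 numbers", call. = FALSE)
    }
    window <- tissue_window(vals[1], vals[2], vals[3], vals[4])
    skip <- 1
  }
  cells <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  header_line <- skip + 1
  mandatory <- c("cell_id", "x", "y")
  missing_col <- setdiff(mandatory, names(cells))
  if (length(missing_col)) {
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing_col, collapse = ", ")), call. = FALSE)
  }
  has_intensities <- any(c("CD4", "PD1", "FOXP3", "Ki67") %in% names(cells))
  if (!has_intensities && !"label" %in% names(cells)) {
    stop("need either marker intensity columns or a label column",
         call. = FALSE)
  }
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(cells[[col]]))
    bad <- which(is.na(v) & !is.na(cells[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at line %d: '%s'", col,
                   bad[1] + header_line, cells[[col]][bad[1]]), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing %s at line %d", col,
                   which(is.na(v))[1] + header_line), call. = FALSE)
    }
    cells[[col]] <- v
  }
  dup <- duplicated(cells$cell_id) | duplicated(cells$cell_id, fromLast = TRUE)
  if (any(dup)) {
    stop(sprintf("duplicate cell_id '%s' at lines %s",
                 cells$cell_id[which(dup)[1]],
                 paste(which(dup) + header_line, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(window)) window <- bounding_window(cells$x, cells$y)
  if (y_flip) cells$y <- window$y_max + window$y_min - cells$y
  assert_points_in_window(cells$x, cells$y, window, "cells")
  list(cells = cells, window = window)
}

#' Write a cell table to CSV
#'
#' Inverse of [read_cell_table()]: writes the `#window:` sidecar header when
#' a window is given, then the CSV body. Numeric columns are written with 9
#' significant digits, so a write-then-read round trip reproduces values to
#' that precision.
#'
#' @param cells Cell table data frame.
#' @param path Output path.
#' @param window Optional [tissue_window()] to declare in the header.
#' @return The path, invisibly.
#' @export
write_cell_table <- function(cells, path, window = NULL) {
  out <- cells
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 9, format = "g")
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(window)) {
    writeLines(sprintf("#window: %s %s %s %s",
                       formatC(window$x_min, digits = 9, format = "g"),
                       formatC(window$y_min, digits = 9, format = "g"),
                       formatC(window$x_max, digits = 9, format = "g"),
                       formatC(window$y_max, digits = 9, format = "g")), con)
  }
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
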