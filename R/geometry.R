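#' Planar electrode-grid geometry
#'
#' Describes a regular epidural grid of surface electrodes. Rows run along
#' the caudo-rostral axis (row 1 is the most caudal, labelled "A"), columns
#' along the medio-lateral axis (column 1 is the most medial). Electrode
#' planar coordinates are expressed in a fixed anatomical frame:
#' `x` increases towards caudal, `y` increases towards medial, both in
#' micrometres, with the most rostro-lateral electrode at the origin.
#'
#' @param n_rows Number of rows (caudo-rostral), default 6.
#' @param n_cols Number of columns (medio-lateral), default 10.
#' @param pitch Electrode separation in micrometres (both axes), default 400.
#' @return An object of class `grid_geometry` with fields `n_rows`,
#'   `n_cols`, `pitch`, the axis labels, and a `channels` data.frame
#'   (one row per channel: `channel`, `label`, `row`, `col`, `x`, `y`).
#' @examples
#' g <- grid_geometry()
#' nrow(g$channels)  # 60
#' @export
grid_geometry <- function(n_rows = 6L, n_cols = 10L, pitch = 400) {
  stopifnot(n_rows >= 2, n_cols >= 2, pitch > 0)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  ch <- data.frame(
    channel = seq_len(n_rows * n_cols),
    label = paste0(LETTERS[row], col),
    row = row, col = col,
    # row 1 ("A") is the most caudal, column 1 the most medial
    x = (n_rows - row) * pitch,
    y = (n_cols - col) * pitch,
    stringsAsFactors = FALSE
  )
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
         row_axis = "caudal->rostral", col_axis = "medial->lateral",
         channels = ch),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("uECoG grid geometry: %d x %d electrodes, %g um pitch (%d channels)\n",
              x$n_rows, x$n_cols, x$pitch, nrow(x$channels)))
  cat(sprintf("  rows %s (%s), cols 1-%d (%s)\n",
              paste(LETTERS[c(1, x$n_rows)], collapse = "-"), x$row_axis,
              x$n_cols, x$col_axis))
  invisible(x)
}

#' Laminar silicon-probe geometry
#'
#' A linear probe with equally spaced recording sites along cortical depth.
#' Site 1 is the most superficial; `insertion_depth` is the depth of the
#' deepest site below the cortical surface.
#'
#' @param n_sites Number of recording sites (>= 3; the second spatial
#'   derivative used for current source density needs interior sites).
#' @param site_spacing Distance between adjacent sites in micrometres.
#' @param insertion_depth Depth of the deepest site in micrometres.
#' @return An object of class `probe_geometry` with a `channels` data.frame
#'   carrying per-site depths (`depth`, micrometres).
#' @export
probe_geometry <- function(n_sites = 16L, site_spacing = 50,
                           insertion_depth = (n_sites - 1) * site_spacing + 100) {
  stopifnot(n_sites >= 3, site_spacing > 0, insertion_depth > 0)
  n_sites <- as.integer(n_sites)
  depth <- insertion_depth - (n_sites - seq_len(n_sites)) * site_spacing
  structure(
    list(n_sites = n_sites, site_spacing = site_spacing,
         insertion_depth = insertion_depth,
         channels = data.frame(channel = seq_len(n_sites),
                               label = paste0("D", seq_len(n_sites)),
                               depth = depth)),
    class = "probe_geometry"
  )
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("laminar probe geometry: %d sites, %g um spacing, deepest site %g um\n",
              x$n_sites, x$site_spacing, x$insertion_depth))
  invisible(x)
}

n_channels <- function(geometry) nrow(geometry$channels)

#' Resolve channel identifiers to indices
#'
#' Accepts integer indices or grid labels such as `"C5"` and returns
#' integer channel indices.
#'
#' @param ids Integer vector or character vector of channel labels.
#' @param geometry A `grid_geometry` or `probe_geometry`.
#' @return Integer channel indices.
#' @export
channel_index <- function(ids, geometry) {
  if (length(ids) == 0) return(integer(0))
  if (is.numeric(ids)) {
    idx <- as.integer(ids)
  } else {
    idx <- match(as.character(ids), geometry$channels$label)
  }
  if (anyNA(idx) || any(idx < 1) || any(idx > n_channels(geometry)))
    stop("unknown channel identifier(s): ",
         paste(ids[is.na(idx) | idx < 1 | idx > n_channels(geometry)], collapse = ", "))
  idx
}

# 4-neighbourhood on the grid (adjacent along depth for a probe)
channel_neighbors <- function(geometry, idx) {
  ch <- geometry$channels
  if (inherits(geometry, "grid_geometry")) {
    r <- ch$row[idx]; c <- ch$col[idx]
    nb <- ch$channel[(abs(ch$row - r) + abs(ch$col - c)) == 1L]
  } else {
    nb <- ch$channel[abs(ch$channel - idx) == 1L]
  }
  nb
}
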