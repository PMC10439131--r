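#' Generate a Visium-style hexagonal spot lattice
#'
#' Builds the staggered ("doubled-width") coordinate system used by hexagonal
#' spatial capture arrays: a spot exists at `(array_row, array_col)` only when
#' the row and column indices have equal parity, so that each interior spot
#' has exactly six direct neighbors.
#'
#' @param n_rows,n_cols Positive integers; the grid extent. Rows are indexed
#'   `0:(n_rows-1)` and columns `0:(n_cols-1)`.
#' @return A data.frame with columns `spot_id`, `array_row`, `array_col`,
#'   `in_tissue` (all `TRUE` by default), one row per lattice spot.
#' @examples
#' lat <- generate_hex_lattice(10, 10)
#' nrow(lat)  # 50: half the grid positions satisfy the parity rule
#' @export
generate_hex_lattice <- function(n_rows, n_cols) {
  stop_if_not(length(n_rows) == 1 && length(n_cols) == 1 &&
                n_rows >= 1 && n_cols >= 1,
              "n_rows and n_cols must be positive integers")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  grid <- expand.grid(array_col = seq_len(n_cols) - 1L,
                      array_row = seq_len(n_rows) - 1L)
  keep <- (grid$array_row %% 2L) == (grid$array_col %% 2L)
  grid <- grid[keep, c("array_row", "array_col")]
  rownames(grid) <- NULL
  data.frame(
    spot_id = sprintf("spot_%d_%d", grid$array_row, grid$array_col),
    array_row = grid$array_row,
    array_col = grid$array_col,
    in_tissue = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Direct hexagonal neighbors of a spot
#'
#' Neighbors are the up-to-six spots directly in contact on the staggered
#' grid: offsets `(0, +/-2)` and `(+/-1, +/-1)` relative to
#' `(array_row, array_col)`. Only positions present on the lattice and marked
#' `in_tissue` are returned.
#'
#' @param lattice A lattice data.frame as from [generate_hex_lattice()].
#' @param spot A `spot_id` present in `lattice`.
#' @return Character vector of neighboring `spot_id`s (length 0-6).
#' @export
hex_neighbors <- function(lattice, spot) {
  i <- match(spot, lattice$spot_id)
  stop_if_not(!is.na(i), sprintf("unknown spot '%s'", spot))
  r <- lattice$array_row[i]; c <- lattice$array_col[i]
  dr <- c(0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(-2L, 2L, -1L, 1L, -1L, 1L)
  key <- paste(r + dr, c + dc)
  hit <- match(key, paste(lattice$array_row, lattice$array_col))
  hit <- hit[!is.na(hit)]
  hit <- hit[lattice$in_tissue[hit]]
  lattice$spot_id[hit]
}

#' Full adjacency list of a lattice
#'
#' @param lattice A lattice data.frame.
#' @return Named list: for each `spot_id`, the character vector of its direct
#'   hexagonal neighbors.
#' @export
hex_adjacency <- function(lattice) {
  key <- paste(lattice$array_row, lattice$array_col)
  idx <- seq_len(nrow(lattice))
  names(idx) <- key
  dr <- c(0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(-2L, 2L, -1L, 1L, -1L, 1L)
  out <- vector("list", nrow(lattice))
  for (i in idx) {
    k <- paste(lattice$array_row[i] + dr, lattice$array_col[i] + dc)
    hit <- idx[k[k %in% names(idx)]]
    hit <- hit[lattice$in_tissue[hit]]
    out[[i]] <- lattice$spot_id[hit]
  }
  names(out) <- lattice$spot_id
  out
}

## Hex (ring) distance between spots in doubled-width coordinates:
## dy steps move one ring; remaining column offset costs (dx - dy)/2.
hex_distance <- function(row1, col1, row2, col2) {
  dy <- abs(row1 - row2)
  dx <- abs(col1 - col2)
  dy + pmax(0, (dx - dy)) / 2
}
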