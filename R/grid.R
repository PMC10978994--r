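#' Tile contigs into a fixed-width window grid
#'
#' Partitions each contig into consecutive, non-overlapping windows of
#' `width` bp starting at position 0. The terminal window of a contig is
#' truncated to the contig end (and kept), so window lengths per contig
#' always sum to the contig length. Coordinates are 0-based half-open
#' throughout the package; window identifiers are `"contig:start-end"`.
#'
#' @param contigs Named numeric vector of contig lengths (bp), or a
#'   data.frame with columns `name` and `length`.
#' @param width Window width in bp (default 300, the expected sequenced
#'   fragment size for MBD capture data).
#' @return A `window_grid`: a data.frame with columns `contig`, `start`,
#'   `end` and row names equal to the window ids, with attribute
#'   `window_width`.
#' @examples
#' tile_windows(c(chr1 = 1000), width = 300)
#' @export
tile_windows <- function(contigs, width = 300) {
  if (is.data.frame(contigs)) {
    lens <- setNames(as.numeric(contigs$length), as.character(contigs$name))
  } else {
    lens <- contigs
  }
  if (is.null(names(lens)) || any(!nzchar(names(lens)))) {
    stop("contigs must be named")
  }
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width <= 0L) {
    stop("window width must be a positive integer")
  }
  if (any(is.na(lens)) || any(lens <= 0)) {
    stop("all contig lengths must be positive")
  }
  pieces <- lapply(names(lens), function(nm) {
    len <- lens[[nm]]
    starts <- seq.int(0L, len - 1L, by = width)
    data.frame(
      contig = nm,
      start = starts,
      end = pmin(starts + width, len),
      stringsAsFactors = FALSE
    )
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- window_id(grid$contig, grid$start, grid$end)
  attr(grid, "window_width") <- width
  class(grid) <- c("window_grid", "data.frame")
  grid
}

#' Window identifier strings
#'
#' @param contig,start,end Vectors of contig names and 0-based half-open
#'   coordinates.
#' @return Character vector `"contig:start-end"`.
#' @export
window_id <- function(contig, start, end) {
  sprintf("%s:%d-%d", contig, as.integer(start), as.integer(end))
}

#' Parse window identifiers back into coordinates
#'
#' @param ids Character vector of `"contig:start-end"` ids.
#' @return data.frame with columns `contig`, `start`, `end`.
#' @export
parse_window_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed window id(s): ", paste(ids[bad], collapse = ", "))
  data.frame(
    contig = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    row.names = ids,
    stringsAsFactors = FALSE
  )
}

#' Write a window grid as BED
#'
#' BED uses the same 0-based half-open convention as the in-memory grid.
#'
#' @param grid A `window_grid`.
#' @param path Output file.
#' @export
write_grid_bed <- function(grid, path) {
  write.table(grid[, c("contig", "start", "end")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
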