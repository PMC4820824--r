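#' Tile a genome with fixed-width bins
#'
#' Divides each chromosome into non-overlapping bins of `width` base pairs,
#' using 0-based half-open coordinates. A trailing partial bin (shorter than
#' `width`) is dropped rather than rescaled, so every bin has exactly `width`
#' bases.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp, or a
#'   data frame with columns `chrom` and `size`.
#' @param width Bin width in bp (single positive integer).
#'
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   one row per bin, ordered by chromosome then position. The bin width and
#'   the chromosome sizes are carried in attributes `bin_width` and
#'   `chrom_sizes`.
#' @examples
#' bin_grid(c(chr1 = 1000), width = 150)
#' @export
bin_grid <- function(chrom_sizes, width) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- stats::setNames(as.numeric(chrom_sizes$size),
                             as.character(chrom_sizes$chrom))
  } else {
    sizes <- chrom_sizes
  }
  if (length(sizes) == 0) stop("empty chromosome set")
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
    stop("chromosome sizes must be named")
  }
  width <- as.integer(width)
  if (length(width) != 1 || is.na(width) || width < 1) {
    stop("bin width must be a single integer >= 1")
  }
  grid <- purrr::map2_dfr(names(sizes), sizes, function(ch, sz) {
    n <- sz %/% width
    if (n == 0) return(tibble::tibble(chrom = character(), start = numeric(),
                                      end = numeric()))
    start <- (seq_len(n) - 1) * width
    tibble::tibble(chrom = ch, start = start, end = start + width)
  })
  attr(grid, "bin_width") <- width
  attr(grid, "chrom_sizes") <- sizes
  grid
}

#' @keywords internal
bin_width_of <- function(grid) {
  w <- attr(grid, "bin_width", exact = TRUE)
  if (is.null(w)) w <- as.integer(grid$end[1] - grid$start[1])
  w
}

#' @keywords internal
chrom_sizes_of <- function(grid) {
  s <- attr(grid, "chrom_sizes", exact = TRUE)
  if (is.null(s)) {
    s <- tapply(grid$end, grid$chrom, max)
    s <- stats::setNames(as.numeric(s), names(s))
  }
  s
}

#' Attach a value column to a bin grid, making a signal track
#'
#' A signal track is the grid tibble plus a numeric `value` column; `NA`
#' marks undefined bins, which are excluded from all statistics downstream.
#'
#' @param grid A bin grid from [bin_grid()].
#' @param value Numeric vector, one value per bin (`NA` = undefined).
#' @return A tibble with columns `chrom`, `start`, `end`, `value`, carrying
#'   the grid attributes.
#' @export
as_track <- function(grid, value) {
  stopifnot(length(value) == nrow(grid))
  out <- grid
  out$value <- as.numeric(value)
  attr(out, "bin_width") <- bin_width_of(grid)
  attr(out, "chrom_sizes") <- chrom_sizes_of(grid)
  out
}

#' Genome-wide mean of a track over its defined bins
#' @param track A signal track.
#' @return A single number.
#' @export
track_mean <- function(track) mean(track$value, na.rm = TRUE)

#' @keywords internal
check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom[1], b$chrom[1]) ||
      !identical(a$start[1], b$start[1]) ||
      !identical(a$start[nrow(a)], b$start[nrow(b)])) {
    stop("tracks are not on the same bin grid")
  }
  invisible(TRUE)
}

#' @keywords internal
mask_values <- function(mask, n) {
  if (is.null(mask)) return(rep(FALSE, n))
  m <- if (is.data.frame(mask)) mask$masked else mask
  stopifnot(length(m) == n)
  as.logical(m)
}
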