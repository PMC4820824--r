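#' Align a signal track around anchor points
#'
#' Extracts the signal in a window of `half_width` bp on each side of every
#' anchor, at the track's bin resolution, normalized by the track's
#' genome-wide mean. Rows (anchors) are sorted by decreasing score (ties
#' broken by coordinate, stable and deterministic); minus-strand anchors
#' have their offsets reversed so that upstream is always to the left.
#' Offsets falling outside the genome (or on undefined bins) are `NA`.
#'
#' @param anchors Tibble with `chrom`, `pos` (0-based bp), optional
#'   `strand` (default "+") and `score`.
#' @param signal Signal track.
#' @param half_width Half window width in bp.
#' @return Object of class `alignment_matrix`: a numeric matrix (anchors x
#'   offsets) with attributes `offsets_bp`, `scores` (sorted), `norm`
#'   (the genome-wide mean used).
#' @export
align_signal <- function(anchors, signal, half_width = 4000) {
  if (nrow(anchors) == 0) stop("empty anchor set")
  if (!"strand" %in% names(anchors)) anchors$strand <- "+"
  if (!"score" %in% names(anchors)) anchors$score <- 0
  mu <- track_mean(signal)
  if (!is.finite(mu) || mu <= 0) stop("signal mean must be positive for normalization")
  W <- bin_width_of(signal)
  K <- floor(half_width / W)
  chroms <- unique(signal$chrom)
  nbins <- tapply(signal$start, factor(signal$chrom, chroms), length)
  nb <- as.numeric(nbins)
  offset0 <- stats::setNames(cumsum(c(0, nb[-length(nb)])), chroms)
  an <- anchors |>
    dplyr::arrange(dplyr::desc(.data$score), .data$chrom, .data$pos)
  vals <- signal$value
  mat <- matrix(NA_real_, nrow(an), 2 * K + 1)
  for (i in seq_len(nrow(an))) {
    ch <- an$chrom[i]
    if (!ch %in% chroms) next
    b0 <- an$pos[i] %/% W
    idx <- b0 + (-K:K)
    okk <- idx >= 0 & idx < nbins[[ch]]
    row <- rep(NA_real_, 2 * K + 1)
    row[okk] <- vals[offset0[[ch]] + idx[okk] + 1] / mu
    if (an$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  structure(mat, class = "alignment_matrix",
            offsets_bp = (-K:K) * W, scores = an$score, norm = mu)
}

#' Pixelate an alignment matrix for display
#'
#' Rows (in score order) and columns are grouped into at most `n_pixels`
#' contiguous blocks and block-averaged, ignoring undefined cells, so that
#' each horizontal line of pixels is the average of several alignment
#' features. No upsampling: a matrix smaller than the target keeps its
#' size in that dimension. The defined-cell-weighted mean of the pixelated
#' matrix equals that of the source.
#'
#' @param mat An `alignment_matrix` (or plain matrix).
#' @param n_pixels Target number of pixels per dimension (default 200).
#' @return A matrix (<= n_pixels x <= n_pixels) of class
#'   `alignment_matrix` with attribute `pixel_counts` (defined source
#'   cells per pixel).
#' @export
pixelate <- function(mat, n_pixels = 200) {
  if (nrow(mat) < 1) stop("matrix must have at least one row")
  rg <- block_groups(nrow(mat), n_pixels)
  cg <- block_groups(ncol(mat), n_pixels)
  def <- !is.na(mat)
  m0 <- ifelse(def, mat, 0)
  sums <- rowsum(t(rowsum(m0, rg, reorder = FALSE)), cg, reorder = FALSE)
  cnts <- rowsum(t(rowsum(def + 0, rg, reorder = FALSE)), cg, reorder = FALSE)
  px <- t(ifelse(cnts > 0, sums / cnts, NA_real_))
  cnt <- t(cnts)
  structure(px, class = "alignment_matrix", pixel_counts = cnt,
            offsets_bp = attr(mat, "offsets_bp", exact = TRUE),
            scores = attr(mat, "scores", exact = TRUE))
}

#' @keywords internal
block_groups <- function(n, n_pixels) {
  k <- min(n, n_pixels)
  # contiguous, near-equal blocks; remainder spread over the first blocks
  sort(rep_len(seq_len(k), n))
}

#' Median signal profiles by score quartile
#'
#' Groups the alignment rows (already in score order) into four
#' equal-count quartiles (remainder rows assigned to the lower quartiles)
#' and returns the column-wise median profile of each, ignoring undefined
#' cells. Quartile 1 holds the highest scores.
#'
#' @param mat An `alignment_matrix`.
#' @return Tibble with `offset_bp`, `quartile` (factor 1-4), `median`.
#' @export
quartile_median_profiles <- function(mat) {
  n <- nrow(mat)
  if (n < 4) stop("need at least 4 rows")
  base <- n %/% 4; extra <- n %% 4
  sizes <- base + (seq_len(4) > 4 - extra)  # remainder to lower quartiles
  qt <- rep(1:4, sizes)  # quartile 1 = highest scores (first rows)
  offs <- attr(mat, "offsets_bp", exact = TRUE)
  if (is.null(offs)) offs <- seq_len(ncol(mat))
  purrr::map_dfr(1:4, function(q) {
    block <- mat[qt == q, , drop = FALSE]
    tibble::tibble(offset_bp = offs, quartile = factor(q, levels = 1:4),
                   median = apply(block, 2, stats::median, na.rm = TRUE))
  })
}

#' @rdname align_signal
#' @param object An `alignment_matrix`.
#' @param ... Unused.
#' @method autoplot alignment_matrix
#' @export
autoplot.alignment_matrix <- function(object, ...) {
  offs <- attr(object, "offsets_bp", exact = TRUE)
  if (is.null(offs)) offs <- seq_len(ncol(object))
  d <- tibble::tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    offset_bp = rep(offs, each = nrow(object)),
    value = as.vector(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset_bp, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "offset (bp)", y = "anchors (by decreasing score)",
                  fill = "signal / mean") +
    ggplot2::theme_minimal()
}
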