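#' Per-bin fragment coverage
#'
#' Projects sequencing fragments onto a bin grid. Records may be full
#' intervals (`start`, `end`) or read starts (`end` missing or `NA`), in
#' which case each read is extended 3' by `extension` bp from its mapped
#' coordinate (`[start, start + extension)` on the plus strand,
#' `(start - extension, start]` on the minus strand). Fragments extending
#' beyond a chromosome end are clipped; the number of clipped bases is
#' reported in the attribute `clipped_bases`.
#'
#' @param fragments Tibble with columns `chrom`, `start` and optionally
#'   `end` and `strand` (0-based half-open coordinates).
#' @param grid Bin grid from [bin_grid()].
#' @param extension Fragment length in bp used to extend bare read starts
#'   (e.g. 200 for ChIP fragments, 146 for mononucleosomes). Ignored for
#'   records that already carry an `end`.
#' @param stat `"mean"` (default): mean per-base coverage within the bin;
#'   `"center"`: coverage at the bin's central base.
#' @return A signal track (grid + `value`).
#' @export
fragment_coverage <- function(fragments, grid, extension = 0,
                              stat = c("mean", "center")) {
  stat <- match.arg(stat)
  stopifnot(extension >= 0)
  W <- bin_width_of(grid)
  sizes <- chrom_sizes_of(grid)
  fr <- fragments
  if (!"end" %in% names(fr)) fr$end <- NA_real_
  if (!"strand" %in% names(fr)) fr$strand <- "+"
  bare <- is.na(fr$end)
  if (any(bare)) {
    minus <- bare & fr$strand == "-"
    fr$end[bare] <- fr$start[bare] + extension
    fr$end[minus] <- fr$start[minus] + 1
    fr$start[minus] <- fr$start[minus] - extension + 1
  }
  if (any(fr$start >= fr$end)) stop("fragments must have start < end")
  clipped <- 0
  values <- lapply(split(grid, factor(grid$chrom, unique(grid$chrom))),
                   function(g) {
    ch <- g$chrom[1]
    sz <- sizes[[ch]]
    f <- fr[fr$chrom == ch, ]
    s <- pmax(f$start, 0)
    e <- pmin(f$end, sz)
    keep <- s < e
    clipped <<- clipped + sum(f$end - f$start) - sum(e[keep] - s[keep])
    cov <- IRanges::coverage(IRanges::IRanges(start = s[keep] + 1,
                                              end = e[keep]),
                             width = sz)
    if (stat == "mean") {
      v <- IRanges::viewMeans(IRanges::Views(cov, start = g$start + 1,
                                             width = W))
    } else {
      mid <- g$start + (W + 1) %/% 2  # 1-based central base
      v <- as.numeric(cov[mid])
    }
    as.numeric(v)
  })
  out <- as_track(grid, unlist(values, use.names = FALSE))
  attr(out, "clipped_bases") <- clipped
  if (clipped > 0) {
    message(clipped, " fragment bases clipped at chromosome ends")
  }
  out
}

#' @keywords internal
pad_intervals <- function(df, pad, sizes) {
  if (nrow(df) == 0) return(df)
  df$start <- pmax(df$start - pad, 0)
  df$end <- pmin(df$end + pad, sizes[df$chrom])
  df
}

#' Mask anomalous genomic regions
#'
#' Two masking rules are applied and their union returned: (a) bins whose
#' occupancy exceeds `occ_threshold` are masked together with the
#' surrounding `pad` bp on each side; (b) the mappability track is averaged
#' into `map_bin`-bp bins, and any run of at least `map_run` consecutive
#' low-mappability bins (mean below `map_level`) is masked, again padded by
#' `pad`. The mask is projected back onto the grid of `occupancy`: a bin is
#' masked when it overlaps any masked interval.
#'
#' @param occupancy Signal track on the analysis grid (e.g. nucleosome
#'   occupancy counts).
#' @param mappability Optional signal track of mappability in `[0, 1]` on
#'   its own (finer) grid; `NULL` disables rule (b).
#' @param occ_threshold Occupancy above which a bin is anomalous.
#' @param map_bin Width (bp) of the mappability averaging bins.
#' @param map_level Mappability below which a 1 kb bin counts as low.
#' @param map_run Minimum run length (bins) of low mappability.
#' @param pad Padding (bp) added around both kinds of flagged loci.
#' @return A mask track: grid columns plus logical `masked`. The masked
#'   intervals are attached as attribute `intervals`.
#' @export
build_mask <- function(occupancy, mappability = NULL, occ_threshold = 100,
                       map_bin = 1000, map_level = 0.5, map_run = 10,
                       pad = 10000) {
  sizes <- chrom_sizes_of(occupancy)
  occ_iv <- occupancy[!is.na(occupancy$value) &
                        occupancy$value > occ_threshold,
                      c("chrom", "start", "end")]
  ivs <- pad_intervals(occ_iv, pad, sizes)

  if (!is.null(mappability)) {
    mp <- mappability
    mp$mb <- (mp$start %/% map_bin) * map_bin
    agg <- mp |>
      dplyr::group_by(.data$chrom, .data$mb) |>
      dplyr::summarise(m = mean(.data$value, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::arrange(.data$chrom, .data$mb)
    low_iv <- agg |>
      dplyr::group_by(.data$chrom) |>
      dplyr::group_modify(function(d, key) {
        r <- rle(d$m < map_level)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        keep <- r$values & r$lengths >= map_run
        tibble::tibble(start = d$mb[starts[keep]],
                       end = d$mb[ends[keep]] + map_bin)
      }) |>
      dplyr::ungroup()
    ivs <- dplyr::bind_rows(ivs, pad_intervals(low_iv, pad, sizes))
  }

  masked <- rep(FALSE, nrow(occupancy))
  for (ch in unique(ivs$chrom)) {
    iv <- ivs[ivs$chrom == ch, ]
    sel <- occupancy$chrom == ch
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(occupancy$start[sel] + 1, occupancy$end[sel]),
      IRanges::reduce(IRanges::IRanges(iv$start + 1, iv$end)))
    masked[sel] <- hit
  }
  out <- occupancy[, c("chrom", "start", "end")]
  out$masked <- masked
  attr(out, "bin_width") <- bin_width_of(occupancy)
  attr(out, "chrom_sizes") <- sizes
  attr(out, "intervals") <- ivs
  out
}
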