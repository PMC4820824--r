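#' Read and write genome tracks and intervals
#'
#' Thin wrappers around rtracklayer for the standard plain-text genomics
#' formats, converting between files and the package's tibble
#' representation. `write_track_bedgraph()` omits undefined (`NA`) bins;
#' `read_track_bedgraph()` projects a bedGraph onto a grid, leaving bins
#' without a record undefined.
#'
#' @param track Signal track tibble.
#' @param path File path.
#' @name track_io
NULL

#' @rdname track_io
#' @export
write_track_bedgraph <- function(track, path) {
  d <- track[!is.na(track$value), ]
  gr <- GenomicRanges::GRanges(d$chrom,
                               IRanges::IRanges(d$start + 1, d$end),
                               score = d$value)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' @rdname track_io
#' @param grid Bin grid to project onto.
#' @export
read_track_bedgraph <- function(path, grid) {
  gr <- rtracklayer::import.bedGraph(path)
  d <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      value = gr$score)
  key <- paste(grid$chrom, grid$start)
  v <- d$value[match(key, paste(d$chrom, d$start))]
  as_track(grid, v)
}

#' @rdname track_io
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based
#'   half-open) and optional `name`, `score`, `strand`.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start + 1, intervals$end),
    strand = if ("strand" %in% names(intervals)) intervals$strand else "*")
  if ("score" %in% names(intervals)) gr$score <- intervals$score
  if ("name" %in% names(intervals)) gr$name <- intervals$name
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname track_io
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  out <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1,
                        end = GenomicRanges::end(gr))
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  out
}

#' @rdname track_io
#' @param sites Site-call tibble (see [read_cytosine_report()]).
#' @export
write_cytosine_report <- function(sites, path) {
  out <- tibble::tibble(chrom = sites$chrom, pos = sites$pos + 1L,
                        strand = sites$strand, context = sites$context,
                        n_m = sites$n_m, n_tot = sites$n_tot)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
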