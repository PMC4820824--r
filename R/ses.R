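#' Signal extraction scaling (SES) of ChIP against Input
#'
#' Separates ChIP-enriched signal from non-specific background by ordering
#' bins by increasing ChIP coverage (ties broken by increasing Input, then
#' bin index) and accumulating the cumulative fractions `f_chip` and
#' `f_input` of the two channels along that order. The percentile `p_star`
#' of maximal gap `|f_chip - f_input|` separates background from signal, and
#' the ratio of the two cumulative fractions there is the factor that
#' matches the background contribution of the ChIP track to the Input track.
#'
#' Two scaling factors are returned, differing only by the ratio of channel
#' totals:
#' \describe{
#'   \item{`upsilon`}{`f_input(p*) / f_chip(p*)`, the ratio of cumulative
#'     fractions. It is invariant to rescaling either channel and is the
#'     factor that equalizes backgrounds once both tracks are normalized by
#'     their genome-wide means.}
#'   \item{`upsilon_counts`}{`sum(input) / sum(chip)` over the background
#'     bins (up to `p*`), i.e. `upsilon * total_input / total_chip`. It is
#'     scale-equivariant (multiplying ChIP counts by c divides it by c) and
#'     is the factor that matches backgrounds of the raw count tracks, hence
#'     the one to use in [enrichment_track()] on unnormalized coverage.}
#' }
#'
#' @param chip,input Signal tracks on the same grid (fragment counts or
#'   coverage).
#' @param mask Optional mask track (or logical vector); masked bins are
#'   excluded from the scaling computation.
#' @return An object of class `ses_fit` with elements `upsilon`,
#'   `upsilon_counts`, `p_star` (percentile in (0, 1]), `max_gap`, `n`
#'   (bins used), and `curve`, a tibble of the cumulative-fraction curves.
#'   [tidy()] returns the curve, [glance()] the scalar summaries.
#' @examples
#' g <- bin_grid(c(chr = 600), 150)
#' ses_scale(as_track(g, c(2, 2, 2, 14)), as_track(g, c(10, 10, 10, 10)))
#' @export
ses_scale <- function(chip, input, mask = NULL) {
  check_same_grid(chip, input)
  m <- mask_values(mask, nrow(chip))
  ok <- !m & !is.na(chip$value) & !is.na(input$value)
  x <- chip$value[ok]; y <- input$value[ok]
  if (length(x) < 2) stop("need at least 2 unmasked, defined bins")
  if (sum(x) <= 0 || sum(y) <= 0) stop("total counts must be positive in both channels")
  o <- order(x, y, seq_along(x))
  cx <- cumsum(x[o]); cy <- cumsum(y[o])
  f_chip <- cx / sum(x); f_input <- cy / sum(y)
  gap <- abs(f_chip - f_input)
  p <- which.max(gap)  # first index attaining the max (smallest percentile)
  if (f_chip[p] == 0) {
    stop("degenerate separation: cumulative ChIP fraction is zero at the ",
         "maximal-gap percentile (", round(p / length(x), 4),
         "); the ChIP channel has no counts in the background bins")
  }
  structure(list(
    upsilon = f_input[p] / f_chip[p],
    upsilon_counts = cy[p] / cx[p],
    p_star = p / length(x),
    max_gap = gap[p],
    n = length(x),
    curve = tibble::tibble(percentile = seq_along(x) / length(x),
                           f_chip = f_chip, f_input = f_input, gap = gap)
  ), class = "ses_fit")
}

#' @export
print.ses_fit <- function(x, ...) {
  cat("SES normalization fit\n")
  cat(sprintf("  bins used:       %d\n", x$n))
  cat(sprintf("  upsilon:         %.4g (cumulative-fraction ratio)\n", x$upsilon))
  cat(sprintf("  upsilon_counts:  %.4g (count-scale factor)\n", x$upsilon_counts))
  cat(sprintf("  p_star:          %.4g   max gap: %.4g\n", x$p_star, x$max_gap))
  invisible(x)
}

#' @rdname ses_scale
#' @param x A `ses_fit` object.
#' @param ... Unused.
#' @method tidy ses_fit
#' @export
tidy.ses_fit <- function(x, ...) x$curve

#' @rdname ses_scale
#' @method glance ses_fit
#' @export
glance.ses_fit <- function(x, ...) {
  tibble::tibble(upsilon = x$upsilon, upsilon_counts = x$upsilon_counts,
                 p_star = x$p_star, max_gap = x$max_gap, n = x$n)
}

#' @rdname ses_scale
#' @param object A `ses_fit` object.
#' @method autoplot ses_fit
#' @export
autoplot.ses_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$curve, c("f_chip", "f_input"),
                           names_to = "channel", values_to = "f")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$percentile, y = .data$f,
                                  colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$p_star, linetype = 2) +
    ggplot2::labs(x = "percentile of bins ordered by ChIP",
                  y = "cumulative fraction",
                  title = sprintf("SES separation: upsilon = %.3g", object$upsilon)) +
    ggplot2::theme_minimal()
}

#' Pseudocounted ChIP/Input enrichment track
#'
#' E(i) = upsilon * (chip(i) + eps) / (input(i) + eps). The pseudocount
#' regularizes bins with small Input; with the count-scale factor from
#' [ses_scale()] the non-enriched background has E near 1. Undefined or
#' masked bins propagate `NA`.
#'
#' @param chip,input Signal tracks on the same grid.
#' @param upsilon Scaling factor (> 0); for raw count tracks use
#'   `upsilon_counts` from [ses_scale()].
#' @param eps Pseudocount (default 0.1; results are not sensitive to it).
#' @param mask Optional mask track or logical vector.
#' @return A signal track of enrichment values.
#' @export
enrichment_track <- function(chip, input, upsilon, eps = 0.1, mask = NULL) {
  check_same_grid(chip, input)
  stopifnot(upsilon > 0, eps >= 0)
  if (eps == 0 && any(input$value == 0, na.rm = TRUE)) {
    stop("eps = 0 with zero Input bins; use a positive pseudocount")
  }
  v <- upsilon * (chip$value + eps) / (input$value + eps)
  v[mask_values(mask, nrow(chip))] <- NA_real_
  as_track(chip, v)
}
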