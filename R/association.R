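#' @keywords internal
joint_values <- function(tracks, mask = NULL) {
  n <- nrow(tracks[[1]])
  for (t in tracks) check_same_grid(tracks[[1]], t)
  m <- mask_values(mask, n)
  vals <- vapply(tracks, function(t) t$value, numeric(n))
  ok <- !m & stats::complete.cases(vals)
  vals[ok, , drop = FALSE]
}

#' Pearson correlation between two genome tracks
#'
#' Product-moment correlation over the bins where both tracks are defined
#' and unmasked.
#'
#' @param x,y Signal tracks on the same grid.
#' @param mask Optional mask track or logical vector.
#' @return One-row tibble with `r` and `n` (bins used).
#' @export
track_cor <- function(x, y, mask = NULL) {
  v <- joint_values(list(x, y), mask)
  if (nrow(v) < 3) stop("need at least 3 jointly defined, unmasked bins")
  if (stats::sd(v[, 1]) == 0 || stats::sd(v[, 2]) == 0) {
    stop("zero variance in one of the tracks")
  }
  tibble::tibble(r = stats::cor(v[, 1], v[, 2]), n = nrow(v))
}

#' Partial correlation between two tracks given control tracks
#'
#' Correlation between `x` and `y` after removing the linear dependence of
#' both on the control tracks; computed as the Pearson correlation of the
#' least-squares residuals of `x` and `y` on the controls. With a single
#' control this equals the textbook formula
#' (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)); with no controls it
#' reduces to [track_cor()].
#'
#' @param x,y Signal tracks on the same grid.
#' @param controls List of control tracks (may be empty).
#' @param mask Optional mask track or logical vector.
#' @return One-row tibble with `r`, `n` and `n_controls`.
#' @export
partial_cor <- function(x, y, controls = list(), mask = NULL) {
  if (is.data.frame(controls)) controls <- list(controls)
  v <- joint_values(c(list(x, y), controls), mask)
  k <- length(controls)
  if (nrow(v) < k + 3) stop("too few jointly defined bins for ", k, " controls")
  if (k == 0) {
    return(tibble::tibble(r = stats::cor(v[, 1], v[, 2]), n = nrow(v),
                          n_controls = 0L))
  }
  Z <- cbind(1, v[, -(1:2), drop = FALSE])
  for (j in 3:ncol(v)) {
    rxz <- abs(stats::cor(v[, 1], v[, j]))
    ryz <- abs(stats::cor(v[, 2], v[, j]))
    if (max(rxz, ryz) > 1 - 1e-12) {
      stop("degenerate control: control ", j - 2,
           " is collinear with x or y")
    }
  }
  rx <- stats::lm.fit(Z, v[, 1])$residuals
  ry <- stats::lm.fit(Z, v[, 2])$residuals
  tibble::tibble(r = stats::cor(rx, ry), n = nrow(v), n_controls = k)
}

#' Conditional enrichment map over (GC%, CpG%)
#'
#' Groups bins into cells of a two-dimensional grid over (f_GC, f_CpG) and
#' computes the mean signal, the number of contributing windows and the
#' empirical density per cell. Cells supported by fewer than `min_count`
#' windows are masked (their mean is unreliable because that corner of
#' composition space is undersampled). Reading the map along rows of fixed
#' GC shows whether the signal depends on CpG beyond its dependence on GC.
#'
#' @param features Feature table with `f_GC` and `f_CpG`.
#' @param signal Signal track on the same grid, normalized by its
#'   genome-wide mean (a warning is issued when the mean is far from 1).
#' @param gc_res,cpg_res Cell widths in fraction units.
#' @param min_count Minimum windows per cell; smaller cells are masked.
#' @return A tibble of class `conditional_map` with columns `f_GC`, `f_CpG`
#'   (cell lower edges), `mean`, `n`, `density`, `masked`.
#' @export
conditional_enrichment_map <- function(features, signal, gc_res = 0.02,
                                       cpg_res = 0.01, min_count = 50) {
  check_same_grid(features, signal)
  ok <- !is.na(features$f_GC) & !is.na(features$f_CpG) & !is.na(signal$value)
  if (!any(ok)) stop("no jointly defined bins")
  mu <- mean(signal$value[ok])
  if (abs(mu - 1) > 0.1) {
    warning("signal genome-wide mean is ", signif(mu, 3),
            "; the map expects a mean-normalized signal")
  }
  d <- tibble::tibble(
    f_GC = floor(features$f_GC[ok] / gc_res) * gc_res,
    f_CpG = floor(features$f_CpG[ok] / cpg_res) * cpg_res,
    v = signal$value[ok])
  out <- d |>
    dplyr::group_by(.data$f_GC, .data$f_CpG) |>
    dplyr::summarise(mean = mean(.data$v), n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(density = .data$n / sum(.data$n),
                  masked = .data$n < min_count)
  out$mean[out$masked] <- NA_real_
  class(out) <- c("conditional_map", class(out))
  attr(out, "min_count") <- min_count
  out
}

#' @rdname conditional_enrichment_map
#' @param object A `conditional_map`.
#' @param ... Unused.
#' @method autoplot conditional_map
#' @export
autoplot.conditional_map <- function(object, ...) {
  ggplot2::ggplot(object[!object$masked, ],
                  ggplot2::aes(x = .data$f_GC, y = .data$f_CpG,
                               fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "GC fraction", y = "CpG fraction",
                  fill = "mean signal") +
    ggplot2::theme_minimal()
}

#' Peak versus flank signal contrast
#'
#' Compares the mean signal inside each peak with the mean in its two
#' flanking regions. Peaks are merged when overlapping; flanks are clipped
#' at chromosome ends and trimmed where they would run into a neighbouring
#' peak. Bins are assigned to an interval when their midpoint falls inside
#' it. Peaks without any defined bin in peak or flank are dropped (count
#' reported in attribute `dropped`).
#'
#' @param peaks Tibble of peak intervals (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param signal Signal track.
#' @param flank_width Width in bp of each flank; `NULL` (default) uses each
#'   peak's own width.
#' @return An object of class `contrast_result`: a tibble with per-peak
#'   `peak_mean`, `flank_mean` and `fold`, carrying attributes and a
#'   [glance()] method with the global fold of means (all peak bins vs all
#'   flank bins), the fraction of peaks with peak > flank, and the two-sided
#'   Wilcoxon rank-sum p-value comparing the per-peak means.
#' @export
peak_flank_contrast <- function(peaks, signal, flank_width = NULL) {
  sizes <- chrom_sizes_of(signal)
  mid <- signal$start + (signal$end - signal$start) / 2
  per_chrom <- lapply(split(peaks, peaks$chrom), function(pk) {
    ch <- pk$chrom[1]
    ir <- IRanges::reduce(IRanges::IRanges(pk$start + 1, pk$end))
    ps <- IRanges::start(ir) - 1; pe <- IRanges::end(ir)
    fw <- if (is.null(flank_width)) pe - ps else rep(flank_width, length(ps))
    # flank boundaries clipped at chromosome ends and neighbouring peaks
    prev_end <- c(0, pe[-length(pe)])
    next_start <- c(ps[-1], sizes[[ch]])
    lf_s <- pmax(ps - fw, prev_end); lf_e <- ps
    rf_s <- pe; rf_e <- pmin(pe + fw, next_start)
    sel <- signal$chrom == ch
    m <- mid[sel]; v <- signal$value[sel]
    t(vapply(seq_along(ps), function(i) {
      pv <- v[m >= ps[i] & m < pe[i]]
      fv <- v[(m >= lf_s[i] & m < lf_e[i]) | (m >= rf_s[i] & m < rf_e[i])]
      c(peak_sum = sum(pv, na.rm = TRUE), peak_n = sum(!is.na(pv)),
        flank_sum = sum(fv, na.rm = TRUE), flank_n = sum(!is.na(fv)))
    }, numeric(4)))
  })
  res <- tibble::as_tibble(do.call(rbind, per_chrom))
  dropped <- sum(res$peak_n == 0 | res$flank_n == 0)
  if (dropped > 0) {
    message(dropped, " peak(s) without defined bins dropped from the contrast")
  }
  res <- res[res$peak_n > 0 & res$flank_n > 0, ]
  if (nrow(res) == 0) stop("no peaks with defined signal bins")
  out <- tibble::tibble(
    peak_mean = res$peak_sum / res$peak_n,
    flank_mean = res$flank_sum / res$flank_n)
  out$fold <- out$peak_mean / out$flank_mean
  global_peak <- sum(res$peak_sum) / sum(res$peak_n)
  global_flank <- sum(res$flank_sum) / sum(res$flank_n)
  wt <- suppressWarnings(stats::wilcox.test(out$peak_mean, out$flank_mean))
  structure(out, class = c("contrast_result", class(out)),
            dropped = dropped,
            glance = tibble::tibble(
              global_peak_mean = global_peak,
              global_flank_mean = global_flank,
              fold = global_peak / global_flank,
              fraction_peak_higher = mean(out$peak_mean > out$flank_mean),
              p_ranksum = wt$p.value,
              n_peaks = nrow(out)))
}

#' @rdname peak_flank_contrast
#' @param x A `contrast_result`.
#' @param ... Unused.
#' @method glance contrast_result
#' @export
glance.contrast_result <- function(x, ...) attr(x, "glance", exact = TRUE)

#' Autocorrelation half width at half maximum
#'
#' Mean-subtracted autocorrelation of a track, pooled across chromosomes
#' (pairs involving undefined bins are excluded pairwise), and the lag at
#' which it first falls to half its zero-lag value, linearly interpolated
#' and reported in base pairs.
#'
#' @param signal Signal track.
#' @param max_lag Maximum lag in bins.
#' @return A list of class `acf_result`: `hwhm_bp` (NA when the
#'   autocorrelation never crosses half maximum within `max_lag`, flagged by
#'   `crossed = FALSE`), `rho` (tibble of lag_bp, rho) and `crossed`.
#' @export
autocorrelation_hwhm <- function(signal, max_lag = 50) {
  stopifnot(max_lag >= 1)
  W <- bin_width_of(signal)
  mu <- track_mean(signal)
  chunks <- split(signal$value - mu, factor(signal$chrom, unique(signal$chrom)))
  num <- numeric(max_lag + 1); cnt <- numeric(max_lag + 1)
  for (x in chunks) {
    n <- length(x)
    for (lag in 0:min(max_lag, n - 1)) {
      a <- x[seq_len(n - lag)]; b <- x[seq_len(n - lag) + lag]
      ok <- !is.na(a) & !is.na(b)
      num[lag + 1] <- num[lag + 1] + sum(a[ok] * b[ok])
      cnt[lag + 1] <- cnt[lag + 1] + sum(ok)
    }
  }
  rho <- (num / cnt) / (num[1] / cnt[1])
  below <- which(rho < 0.5)
  crossed <- length(below) > 0
  hwhm <- NA_real_
  if (crossed) {
    k <- below[1] - 1  # rho[k] >= 0.5 > rho[k+1], 1-based index k
    r1 <- rho[k]; r2 <- rho[k + 1]
    hwhm <- ((k - 1) + (r1 - 0.5) / (r1 - r2)) * W
  } else {
    warning("autocorrelation never crossed half maximum within max_lag; ",
            "HWHM is at least ", max_lag * W, " bp")
  }
  structure(list(hwhm_bp = hwhm, crossed = crossed,
                 rho = tibble::tibble(lag_bp = (0:max_lag) * W, rho = rho)),
            class = "acf_result")
}

#' Normalized cross-correlation between two tracks over signed offsets
#'
#' Pearson correlation between `a` shifted against `b` at each signed bin
#' offset, pooled across chromosomes, with the offset of maximal correlation
#' reported in bp. A sharp peak at zero offset indicates bin-level
#' co-localization of the two signals.
#'
#' @param a,b Signal tracks on the same grid.
#' @param max_offset Maximum |offset| in bins.
#' @return A tibble of class `xcorr_result` (`offset_bp`, `r`) with
#'   attributes `argmax_bp` and `max_r`.
#' @export
cross_correlation <- function(a, b, max_offset = 20) {
  check_same_grid(a, b)
  W <- bin_width_of(a)
  chroms <- unique(a$chrom)
  av <- split(a$value, factor(a$chrom, chroms))
  bv <- split(b$value, factor(b$chrom, chroms))
  offs <- -max_offset:max_offset
  r <- vapply(offs, function(k) {
    xs <- c(); ys <- c()
    for (ch in chroms) {
      x <- av[[ch]]; y <- bv[[ch]]; n <- length(x)
      if (n <= abs(k)) next
      if (k >= 0) { xi <- seq_len(n - k); yi <- xi + k }
      else { yi <- seq_len(n + k); xi <- yi - k }
      xs <- c(xs, x[xi]); ys <- c(ys, y[yi])
    }
    ok <- !is.na(xs) & !is.na(ys)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(xs[ok], ys[ok])
  }, numeric(1))
  out <- tibble::tibble(offset_bp = offs * W, r = r)
  class(out) <- c("xcorr_result", class(out))
  attr(out, "argmax_bp") <- out$offset_bp[which.max(out$r)]
  attr(out, "max_r") <- max(out$r, na.rm = TRUE)
  out
}
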