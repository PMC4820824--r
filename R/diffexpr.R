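#' Filter genes by expression level
#'
#' Keeps genes whose geometric mean FPKM between the two conditions exceeds
#' 1 (strictly). FPKM values of genes with multiple transcripts are assumed
#' to be pooled upstream.
#'
#' @param expr Expression tibble with columns `gene`, `fpkm_wt`, `fpkm_ko`,
#'   `log2fc` (log2 WT/KO) and optionally `length` and covariates.
#' @return The filtered tibble, with a `fpkm_geo` column appended.
#' @export
filter_genes <- function(expr) {
  if (nrow(expr) == 0) stop("empty expression table")
  expr |>
    dplyr::mutate(fpkm_geo = sqrt(.data$fpkm_wt * .data$fpkm_ko)) |>
    dplyr::filter(.data$fpkm_geo > 1)
}

#' Empirical expression-dependent dispersion of fold changes
#'
#' Bins the filtered genes into equal-count bins of log2 geometric-mean
#' expression, computes the mean and variance of log2 fold change within
#' each bin, and fits quadratic least-squares curves mu(e) and sigma2(e) of
#' both against the bin-centre expression. These describe the systematic
#' trend and the expression-dependent noise of the fold changes, against
#' which individual genes are standardized.
#'
#' @param expr Filtered expression tibble (from [filter_genes()]).
#' @param n_bins Number of equal-count expression bins (default 20).
#' @return Object of class `dispersion_fit` with the bin table and the
#'   quadratic coefficients; use [predict_dispersion()] to evaluate it.
#' @export
fit_dispersion <- function(expr, n_bins = 20) {
  if (n_bins < 3) stop("n_bins must be at least 3")
  if (nrow(expr) < 200) stop("need at least 200 filtered genes")
  e <- log2(expr$fpkm_geo)
  ord <- order(e, expr$gene)  # ties broken by gene id for determinism
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bin <- pmin(bin, n_bins)
  d <- tibble::tibble(e = e[ord], lfc = expr$log2fc[ord], bin = bin)
  bins <- d |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(centre = mean(.data$e), mean_lfc = mean(.data$lfc),
                     var_lfc = stats::var(.data$lfc), n = dplyr::n(),
                     .groups = "drop")
  mu_fit <- stats::lm(mean_lfc ~ centre + I(centre^2), data = bins)
  var_fit <- stats::lm(var_lfc ~ centre + I(centre^2), data = bins)
  structure(list(bins = bins,
                 mu_coef = stats::coef(mu_fit),
                 var_coef = stats::coef(var_fit),
                 range = range(bins$centre)),
            class = "dispersion_fit")
}

#' Evaluate a dispersion fit at given expression levels
#'
#' Expression values outside the fitted bin-centre range are clamped to it
#' (the quadratics are not trusted to extrapolate).
#'
#' @param fit A `dispersion_fit`.
#' @param e Log2 geometric-mean expression values.
#' @return Tibble with `mu` and `sigma2`.
#' @export
predict_dispersion <- function(fit, e) {
  e <- pmin(pmax(e, fit$range[1]), fit$range[2])
  X <- cbind(1, e, e^2)
  tibble::tibble(mu = as.numeric(X %*% fit$mu_coef),
                 sigma2 = as.numeric(X %*% fit$var_coef))
}

#' @rdname fit_dispersion
#' @param x A `dispersion_fit`.
#' @param ... Unused.
#' @method tidy dispersion_fit
#' @export
tidy.dispersion_fit <- function(x, ...) x$bins

#' @rdname fit_dispersion
#' @param object A `dispersion_fit`.
#' @method autoplot dispersion_fit
#' @export
autoplot.dispersion_fit <- function(object, ...) {
  grid <- seq(object$range[1], object$range[2], length.out = 100)
  pd <- predict_dispersion(object, grid)
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$centre)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_lfc)) +
    ggplot2::geom_line(data = tibble::tibble(centre = grid, mu = pd$mu),
                       ggplot2::aes(y = .data$mu)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$var_lfc), shape = 2) +
    ggplot2::geom_line(data = tibble::tibble(centre = grid, s2 = pd$sigma2),
                       ggplot2::aes(y = .data$s2), linetype = 2) +
    ggplot2::labs(x = "log2 geometric-mean FPKM",
                  y = "bin mean (circles) / variance (triangles) of log2 FC") +
    ggplot2::theme_minimal()
}

#' Expression-standardized Z-scores of differential expression
#'
#' Z_g = (log2fc_g - mu(e_g)) / sigma(e_g), with mu and sigma2 from the
#' empirical dispersion fit evaluated at the gene's log2 geometric-mean
#' expression.
#'
#' @param expr Filtered expression tibble.
#' @param fit A `dispersion_fit`.
#' @return `expr` with a `z` column appended.
#' @export
gene_zscores <- function(expr, fit) {
  pd <- predict_dispersion(fit, log2(expr$fpkm_geo))
  if (any(pd$sigma2 <= 0)) {
    stop("fitted variance is non-positive for some genes; the dispersion ",
         "fit is degenerate on this table")
  }
  dplyr::mutate(expr, z = (.data$log2fc - pd$mu) / sqrt(pd$sigma2))
}

#' GO-term aggregated differential expression
#'
#' For every annotation term with at least `min_genes` filtered genes,
#' computes the aggregated fold change (mean log2 WT/KO over member genes),
#' tests the member Z-scores against zero with a two-sided one-sample
#' t-test, and controls the false discovery rate across all tested terms
#' with Benjamini-Hochberg. Terms are ranked by aggregated fold change.
#'
#' @param expr Expression tibble with `gene`, `log2fc` and `z` columns
#'   (see [gene_zscores()]).
#' @param annotation Two-column tibble mapping `gene` to `term`.
#' @param min_genes Minimum member genes per tested term (default 10).
#' @return Tibble of class `go_result`: `term`, `n`, `agg_fold`, `t`, `p`,
#'   `q`, `degenerate` (TRUE when the member Z-scores had zero variance and
#'   p was set to 1).
#' @export
aggregate_go <- function(expr, annotation, min_genes = 10) {
  if (nrow(annotation) == 0) stop("empty annotation")
  d <- dplyr::inner_join(annotation, expr[, c("gene", "log2fc", "z")],
                         by = "gene")
  out <- d |>
    dplyr::group_by(.data$term) |>
    dplyr::filter(dplyr::n() >= min_genes) |>
    dplyr::summarise(
      n = dplyr::n(),
      agg_fold = mean(.data$log2fc),
      sd_z = stats::sd(.data$z),
      mean_z = mean(.data$z),
      .groups = "drop")
  if (nrow(out) == 0) stop("no terms with at least ", min_genes, " genes")
  out$degenerate <- out$sd_z == 0
  out$t <- ifelse(out$degenerate, NA_real_,
                  out$mean_z / (out$sd_z / sqrt(out$n)))
  out$p <- ifelse(out$degenerate, 1,
                  2 * stats::pt(-abs(out$t), df = out$n - 1))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out |>
    dplyr::select("term", "n", "agg_fold", "t", "p", "q", "degenerate") |>
    dplyr::arrange(.data$agg_fold)
  class(out) <- c("go_result", class(out))
  out
}

#' Rank-based conditional slope test
#'
#' Tests whether the response still depends on covariate `b` after
#' conditioning on covariate `a`: all three variables are rank-transformed,
#' the response ranks are regressed on both covariate ranks by least
#' squares, and the two-sided t-test p-value of the `b` coefficient is
#' reported. A quintile-by-quintile table of mean response is attached for
#' display.
#'
#' @param data Data frame of genes.
#' @param response,a,b Column names (strings) of the response and the two
#'   covariates.
#' @return List of class `slope_test`: `t`, `p`, `n`, `coef` (rank-scale
#'   slope of `b`), `quintile_table` (tibble a_quintile x b_quintile with
#'   mean response and count).
#' @export
rank_conditional_slope_test <- function(data, response, a, b) {
  d <- data[stats::complete.cases(data[, c(response, a, b)]), ]
  if (nrow(d) < 30) stop("need at least 30 complete rows")
  rr <- rank(d[[response]]); ra <- rank(d[[a]]); rb <- rank(d[[b]])
  for (v in list(ra, rb)) {
    if (length(unique(v)) < 3) stop("ties collapse a covariate to fewer than 3 distinct ranks")
  }
  if (abs(stats::cor(ra, rb)) > 1 - 1e-12) stop("covariates have collinear ranks")
  fit <- stats::lm(rr ~ ra + rb)
  sm <- summary(fit)$coefficients
  qa <- dplyr::ntile(d[[a]], 5); qb <- dplyr::ntile(d[[b]], 5)
  qt <- tibble::tibble(a_quintile = qa, b_quintile = qb,
                       response = d[[response]]) |>
    dplyr::group_by(.data$a_quintile, .data$b_quintile) |>
    dplyr::summarise(mean_response = mean(.data$response), n = dplyr::n(),
                     .groups = "drop")
  structure(list(t = sm["rb", "t value"], p = sm["rb", "Pr(>|t|)"],
                 coef = sm["rb", "Estimate"], n = nrow(d),
                 quintile_table = qt),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat("Rank-based conditional slope test (b | a)\n")
  cat(sprintf("  n = %d, slope t = %.3f, p = %.3g\n", x$n, x$t, x$p))
  invisible(x)
}
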