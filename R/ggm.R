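#' Gaussian graphical model over binned genome tracks
#'
#' Computes the pairwise Pearson correlation matrix R of a set of tracks
#' over the bins where every track is defined and unmasked (complete-case
#' selection), inverts it to the precision matrix J = R^-1, and derives the
#' edge weights as full partial correlations
#' w_ij = -J_ij / sqrt(J_ii * J_jj): the correlation between tracks i and j
#' conditioned on all remaining tracks. For two tracks the edge weight
#' equals the marginal Pearson r.
#'
#' @param tracks Named list of signal tracks on a common grid, or a data
#'   frame whose numeric columns are the per-bin track values.
#' @param mask Optional mask track or logical vector.
#' @return An object of class `ggm_fit`: `nodes`, `R`, `J`, `weights`
#'   (matrices), `n` (bins used). [tidy()] returns the edge list,
#'   [glance()] a one-row summary.
#' @export
fit_ggm <- function(tracks, mask = NULL) {
  if (is.data.frame(tracks)) {
    num <- vapply(tracks, is.numeric, logical(1))
    vals <- as.matrix(tracks[, num, drop = FALSE])
    m <- mask_values(mask, nrow(vals))
    vals <- vals[!m & stats::complete.cases(vals), , drop = FALSE]
  } else {
    if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
      stop("tracks must be named")
    }
    vals <- joint_values(tracks, mask)
    colnames(vals) <- names(tracks)
  }
  p <- ncol(vals)
  if (p < 2) stop("need at least 2 tracks")
  if (nrow(vals) < p + 3) {
    stop("insufficient jointly defined bins (", nrow(vals), ") for ", p,
         " tracks")
  }
  R <- stats::cor(vals)
  # name the collinear pair before attempting inversion
  off <- abs(R - diag(p))
  if (any(off > 1 - 1e-10)) {
    ij <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop("collinear tracks: ", colnames(R)[ij[1]], " and ", colnames(R)[ij[2]])
  }
  if (kappa(R, exact = TRUE) > 1e8) {
    stop("correlation matrix is near-singular (condition number > 1e8)")
  }
  J <- solve(R)
  w <- -J / sqrt(diag(J) %o% diag(J))
  diag(w) <- 1
  structure(list(nodes = colnames(R), R = R, J = J, weights = w,
                 n = nrow(vals)),
            class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat("Gaussian graphical model over", length(x$nodes), "tracks,",
      x$n, "bins\nEdge weights (full partial correlations):\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' @rdname fit_ggm
#' @param x A `ggm_fit`.
#' @param ... Unused.
#' @method tidy ggm_fit
#' @export
tidy.ggm_fit <- function(x, ...) {
  p <- length(x$nodes)
  idx <- which(upper.tri(x$weights), arr.ind = TRUE)
  tibble::tibble(
    from = x$nodes[idx[, 1]],
    to = x$nodes[idx[, 2]],
    weight = x$weights[idx],
    r_marginal = x$R[idx]
  ) |> dplyr::arrange(dplyr::desc(abs(.data$weight)))
}

#' @rdname fit_ggm
#' @method glance ggm_fit
#' @export
glance.ggm_fit <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_bins = x$n,
                 condition_number = kappa(x$R, exact = TRUE))
}

#' @rdname fit_ggm
#' @param object A `ggm_fit`.
#' @method autoplot ggm_fit
#' @export
autoplot.ggm_fit <- function(object, ...) {
  e <- tidy(object)
  e$pair <- paste(e$from, "–", e$to)
  ggplot2::ggplot(e, ggplot2::aes(x = stats::reorder(.data$pair, abs(.data$weight)),
                                  y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "full partial correlation") +
    ggplot2::theme_minimal()
}
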