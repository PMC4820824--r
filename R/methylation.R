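#' Read a per-cytosine methylation report
#'
#' Expects a tab-delimited file without header with columns: chromosome,
#' 1-based position, strand (+/-), context (CG, CHG or CHH), count of reads
#' supporting methylation (`n_m`), total covering reads (`n_tot`).
#' Positions are converted to 0-based and the CHG/CHH contexts are collapsed
#' to a single CH context (methylation outside CpG is reported as one pooled
#' quantity).
#'
#' @param path File path.
#' @return A tibble of site calls: `chrom`, `pos` (0-based), `strand`,
#'   `context` (`"CG"` or `"CH"`), `n_m`, `n_tot`.
#' @export
read_cytosine_report <- function(path) {
  sites <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "strand", "context", "n_m", "n_tot"),
    col_types = "ciccii", progress = FALSE)
  sites$pos <- sites$pos - 1L
  sites$context <- ifelse(sites$context == "CG", "CG", "CH")
  validate_site_calls(sites)
  sites
}

#' @keywords internal
validate_site_calls <- function(sites) {
  bad <- which(sites$n_m > sites$n_tot | sites$n_m < 0)
  if (length(bad) > 0) {
    stop("invalid site call (n_m > n_tot) at ", sites$chrom[bad[1]], ":",
         sites$pos[bad[1]], " (record ", bad[1], ")")
  }
  invisible(TRUE)
}

#' Coverage-weighted binned methylation level
#'
#' The methylation level of a bin is the weighted average of the per-site
#' levels l(x) = n_m(x)/n_tot(x) with weights w(x) = n_tot(x), which reduces
#' to l(i) = sum(n_m) / sum(n_tot) over sites in the bin. Down-weighting
#' low-coverage sites reduces the variance of the estimate. Bins containing
#' no covered site (sum n_tot = 0, including bins with no site at all) are
#' left undefined (`NA`). Calls on both strands of a CpG are distinct
#' records and both contribute to the bin holding their position.
#'
#' @param sites Site calls tibble (see [read_cytosine_report()]).
#' @param grid Bin grid.
#' @param context Which context to aggregate, `"CG"` (default) or `"CH"`.
#' @return A signal track of per-bin levels in `[0, 1]` (NA = undefined).
#' @export
bin_methylation_level <- function(sites, grid, context = "CG") {
  validate_site_calls(sites)
  s <- sites[sites$context == context, ]
  W <- bin_width_of(grid)
  chroms <- unique(grid$chrom)
  nbins <- tapply(grid$start, factor(grid$chrom, chroms), length)
  nb <- as.numeric(nbins)
  offset <- stats::setNames(cumsum(c(0, nb[-length(nb)])), chroms)
  s <- s[s$chrom %in% chroms, ]
  local_bin <- s$pos %/% W
  keep <- local_bin < nbins[s$chrom] & s$pos >= 0
  s <- s[keep, ]
  idx <- offset[s$chrom] + local_bin[keep] + 1
  num <- rep(0, nrow(grid)); den <- rep(0, nrow(grid))
  agg_m <- tapply(s$n_m, idx, sum)
  agg_t <- tapply(s$n_tot, idx, sum)
  ii <- as.integer(names(agg_t))
  num[ii] <- agg_m; den[ii] <- agg_t
  as_track(grid, ifelse(den > 0, num / den, NA_real_))
}

#' Methylation density track (mCpG% or mCpH%)
#'
#' The density of methylated CpG in a bin is the product of the bin's
#' methylation level and its CpG fraction: f_mCpG(i) = l(i) * f_CpG(i)
#' (analogously for CpH). Bins with no CpG (f_CpG = 0) are defined to have
#' f_mCpG = 0 even though the level is undefined there; bins with CpG but no
#' coverage (level undefined) are left undefined and excluded from
#' correlations.
#'
#' @param l_track Binned methylation level from [bin_methylation_level()].
#' @param features Feature table from [sequence_features()] on the same grid
#'   (needs `f_CpG` or `f_CpH`).
#' @param context `"CpG"` or `"CpH"`.
#' @return A signal track of methylation densities.
#' @export
methylation_density <- function(l_track, features, context = c("CpG", "CpH")) {
  context <- match.arg(context)
  check_same_grid(l_track, features)
  f_ctx <- if (context == "CpG") features$f_CpG else features$f_CpH
  v <- l_track$value * f_ctx
  v[!is.na(f_ctx) & f_ctx == 0] <- 0
  as_track(l_track, v)
}
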