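track_pair <- function(x, y) {
  g <- bin_grid(c(c1 = length(x) * 150), 150)
  list(x = as_track(g, x), y = as_track(g, y), g = g)
}

test_that("track correlation matches a two-pass oracle and handles exact linearity", {
  withr::with_seed(4, {
    x <- rnorm(2000)
    tp <- track_pair(x, 2 * x + 1)
    expect_equal(track_cor(tp$x, tp$y)$r, 1, tolerance = 1e-12)
    y <- rnorm(2000)
    tp2 <- track_pair(x, y)
    r <- track_cor(tp2$x, tp2$y)
    # naive two-pass oracle
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r$r, oracle, tolerance = 1e-12)
    expect_equal(r$n, 2000)
    const <- track_pair(x, rep(1, 2000))
    expect_error(track_cor(const$x, const$y), "variance")
  })
})

test_that("partial correlation removes a shared driver", {
  withr::with_seed(8, {
    n <- 30000
    z <- rnorm(n)
    x <- z + rnorm(n)
    y <- z + rnorm(n)
    g <- bin_grid(c(c1 = n * 150), 150)
    tx <- as_track(g, x); ty <- as_track(g, y); tz <- as_track(g, z)
    marg <- track_cor(tx, ty)$r
    part <- partial_cor(tx, ty, list(tz))$r
    expect_gt(marg, 0.3)
    expect_lt(abs(part), 0.025)
    # no controls reduces to Pearson
    expect_equal(partial_cor(tx, ty)$r, marg, tolerance = 1e-12)
    # formula path equals the residual-regression path for one control
    rxy <- track_cor(tx, ty)$r
    rxz <- track_cor(tx, tz)$r
    ryz <- track_cor(ty, tz)$r
    formula_r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(part, formula_r, tolerance = 1e-10)
    # degenerate control
    expect_error(partial_cor(tx, ty, list(tx)), "collinear|degenerate")
  })
})

test_that("conditional map averages within cells and conserves counts", {
  withr::with_seed(15, {
    n <- 5000
    g <- bin_grid(c(c1 = n * 150), 150)
    ft <- g
    ft$f_GC <- runif(n, 0.2, 0.8)
    ft$f_CpG <- runif(n, 0, 0.1)
    sig <- as_track(g, rep(1, n))
    m <- conditional_enrichment_map(ft, sig, min_count = 10)
    expect_true(all(m$mean[!m$masked] == 1))
    expect_equal(sum(m$n), n)
    expect_equal(sum(m$density), 1, tolerance = 1e-12)
    # masked cells are monotone in min_count
    m2 <- conditional_enrichment_map(ft, sig, min_count = 25)
    joined <- dplyr::inner_join(
      m[, c("f_GC", "f_CpG", "masked")], m2[, c("f_GC", "f_CpG", "masked")],
      by = c("f_GC", "f_CpG"))
    expect_true(all(joined$masked.y[joined$masked.x]))
    # a GC-only signal is flat across CpG within rows of fixed GC
    sig2 <- as_track(g, 2 * ft$f_GC + rnorm(n, 0, 0.01))
    sig2$value <- sig2$value / mean(sig2$value)
    m3 <- conditional_enrichment_map(ft, sig2, gc_res = 0.05,
                                     cpg_res = 0.02, min_count = 30)
    spread <- m3 |>
      dplyr::filter(!.data$masked) |>
      dplyr::group_by(.data$f_GC) |>
      dplyr::filter(dplyr::n() > 1) |>
      dplyr::summarise(rng = max(.data$mean) - min(.data$mean),
                       .groups = "drop")
    expect_lt(max(spread$rng), 0.12)  # within-row variation ~ cell width * slope
  })
})

test_that("peak/flank contrast recovers a constructed fold of 2", {
  withr::with_seed(23, {
    n <- 4000
    g <- bin_grid(c(c1 = n * 150), 150)
    base <- runif(n, 0.8, 1.2)
    peaks <- tibble::tibble(chrom = "c1",
                            start = seq(20, n - 40, by = 80) * 150,
                            end = (seq(20, n - 40, by = 80) + 4) * 150)
    in_peak <- rep(FALSE, n)
    for (i in seq_len(nrow(peaks))) {
      in_peak[(peaks$start[i] / 150 + 1):(peaks$end[i] / 150)] <- TRUE
    }
    sig <- as_track(g, ifelse(in_peak, 2 * base, base))
    ct <- peak_flank_contrast(peaks, sig)
    gl <- glance(ct)
    expect_equal(gl$fold, 2, tolerance = 0.05)
    expect_gt(gl$fraction_peak_higher, 0.95)
    expect_lt(gl$p_ranksum, 1e-6)
    # uniform signal: fold 1, fraction near 0.5
    ct0 <- peak_flank_contrast(peaks, as_track(g, rep(1, n) + rnorm(n, 0, 1e-6)))
    gl0 <- glance(ct0)
    expect_equal(gl0$fold, 1, tolerance = 0.01)
    expect_gt(gl0$fraction_peak_higher, 0.2)
    expect_lt(gl0$fraction_peak_higher, 0.8)
  })
})

test_that("flanks are clipped at neighbouring peaks (interval oracle)", {
  g <- bin_grid(c(c1 = 60 * 150), 150)
  v <- rep(1, 60)
  v[31:40] <- 100  # second peak: would pollute the first peak's right flank
  sig <- as_track(g, v)
  peaks <- tibble::tibble(chrom = "c1", start = c(3000, 4500),
                          end = c(3750, 6000))
  # peak 1 = bins 21-25, peak 2 = bins 31-40 (values 100)
  ct <- peak_flank_contrast(peaks, sig, flank_width = 3000)
  # right flank of peak 1 must stop at 4500 (bins 26-30, all value 1)
  expect_equal(ct$flank_mean[1], 1)
  expect_equal(ct$peak_mean[1], 1)
})

test_that("autocorrelation HWHM matches closed forms", {
  withr::with_seed(31, {
    n <- 20000; W <- 150
    g <- bin_grid(c(c1 = n * W), W)
    # iid noise: delta autocorrelation, HWHM below one bin
    iid <- autocorrelation_hwhm(as_track(g, rnorm(n)), max_lag = 20)
    expect_lte(iid$hwhm_bp, W)
    # Gaussian-smoothed noise: acf is Gaussian with sd sigma*sqrt(2)
    sigma <- 5
    kern <- dnorm(-30:30, sd = sigma)
    sm <- stats::filter(rnorm(n + 60), kern, sides = 2)
    sm <- sm[31:(n + 30)]
    hw <- autocorrelation_hwhm(as_track(g, as.numeric(sm)), max_lag = 60)
    expected <- sigma * sqrt(2) * sqrt(2 * log(2)) * W
    expect_lt(abs(hw$hwhm_bp - expected), W)
    # boxcar bumps of width w: triangular acf, HWHM = w/2
    w <- 8
    x <- rep(0, n)
    starts <- seq(50, n - 50, by = 200)
    for (s in starts) x[s:(s + w - 1)] <- 1
    hb <- autocorrelation_hwhm(as_track(g, x), max_lag = 40)
    expect_lt(abs(hb$hwhm_bp - w / 2 * W), W)
    # never crossing: flagged, NA
    expect_warning(nc <- autocorrelation_hwhm(as_track(g, as.numeric(sm)),
                                              max_lag = 2), "at least")
    expect_false(nc$crossed)
  })
})

test_that("cross-correlation finds shifts and is bounded on independent tracks", {
  withr::with_seed(37, {
    n <- 10000; W <- 150
    g <- bin_grid(c(c1 = n * W), W)
    a <- as.numeric(stats::filter(rnorm(n), rep(1, 5), sides = 2))
    ta <- as_track(g, a)
    xc0 <- cross_correlation(ta, ta, max_offset = 10)
    expect_equal(attr(xc0, "argmax_bp"), 0)
    expect_equal(attr(xc0, "max_r"), 1, tolerance = 1e-10)
    # shifted copy peaks at k bins
    b <- c(rep(NA, 3), a[1:(n - 3)])
    xc3 <- cross_correlation(ta, as_track(g, b), max_offset = 10)
    expect_equal(attr(xc3, "argmax_bp"), 3 * W)
    ind <- cross_correlation(ta, as_track(g, rnorm(n)), max_offset = 10)
    expect_lt(max(abs(ind$r), na.rm = TRUE), 3 / sqrt(n - 10))
  })
})

test_that("statistics are invariant to chromosome ordering", {
  withr::with_seed(41, {
    g1 <- bin_grid(c(a = 300000, b = 150000), 150)
    v <- rnorm(nrow(g1))
    w <- v + rnorm(nrow(g1))
    g2 <- bin_grid(c(b = 150000, a = 300000), 150)
    perm <- c(which(g1$chrom == "b"), which(g1$chrom == "a"))
    r1 <- track_cor(as_track(g1, v), as_track(g1, w))$r
    r2 <- track_cor(as_track(g2, v[perm]), as_track(g2, w[perm]))$r
    expect_equal(r1, r2, tolerance = 1e-12)
  })
})
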