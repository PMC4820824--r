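#' Configuration for the synthetic epigenome generator
#'
#' Bundles and validates every parameter of the synthetic data model. The
#' defaults describe the regime the downstream analyses assume: a genome
#' whose window GC% follows a smooth autocorrelated process, CpG density
#' coupled to GC, ChIP/Input Poisson counts sharing a log-normal background
#' with enrichment that is a function of GC alone, ~70% background CpG
#' methylation with hypomethylated promoter-proximal and hypermethylated
#' distal CpG islands, and expression fold changes driven by promoter
#' binding and gene length with optional planted GO-term effects.
#'
#' @param seed Integer master seed. Each emitted dataset uses an
#'   independent stream seeded at `seed` plus a fixed per-output offset, so
#'   outputs are individually reproducible.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param bin_width Analysis bin width in bp (default 150).
#' @param rf_window Window width for the binding predictor (default 200).
#' @param gc_mean,gc_sd Mean and spread of the window GC-fraction target.
#' @param gc_corr_length Autocorrelation scale (bp) of the GC process.
#' @param cpg_coupling Multiplier on the baseline (independent-placement)
#'   CpG rate used to plant extra CpG dinucleotides; 0 leaves dinucleotide
#'   placement independent.
#' @param upsilon_true Background scaling factor dividing the ChIP channel
#'   rates (> 0).
#' @param enrich_beta Enrichment amplitude, in units of the mean background
#'   rate, added in peak bins as an increasing function of GC. The default
#'   (6) keeps enriched bins separable from background by count ordering
#'   even at the shallowest ChIP depth the scaling grid produces, which the
#'   background-separation construction requires.
#' @param peak_fraction Fraction of bins that are enriched (peaks are the
#'   runs of bins whose GC exceeds the matching quantile).
#' @param depth_chip,depth_input,depth_mnase Mean fragments per bin.
#' @param mnase_gamma Exponential GC coefficient of the nucleosome
#'   occupancy rate.
#' @param meth_background,meth_cgi_proximal,meth_cgi_distal Methylation
#'   levels (fractions) of background CpGs and of CpGs in
#'   promoter-proximal / distal CpG islands.
#' @param site_coverage_mean Mean reads per cytosine site.
#' @param ch_meth,ch_site_fraction Methylation level of CH sites and the
#'   fraction of CH sites emitted (subsampled for size).
#' @param n_cgi,cgi_width Number (per genome) and width (bp) of CpG
#'   islands; half are placed at promoters, half distal.
#' @param n_genes,n_go_terms Number of genes and GO terms.
#' @param binding_effect log2-fold units per standardized promoter-binding
#'   unit.
#' @param length_effect log2-fold units per log10 bp of gene length.
#' @param n_planted_terms,planted_go_effect Number of GO terms receiving a
#'   planted mean shift, and the shift in log2-fold units.
#' @param expr_sd0,expr_sd1 Fold-change noise model: sd(e) = expr_sd0 +
#'   expr_sd1 * 2^(-e/2) at log2 geometric-mean expression e.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length = 1.5e6,
                       bin_width = 150, rf_window = 200,
                       gc_mean = 0.42, gc_sd = 0.09, gc_corr_length = 1000,
                       cpg_coupling = 1,
                       upsilon_true = 4.41, enrich_beta = 6,
                       peak_fraction = 0.1,
                       depth_chip = 20, depth_input = 20, depth_mnase = 30,
                       mnase_gamma = 1.5,
                       meth_background = 0.70, meth_cgi_proximal = 0.10,
                       meth_cgi_distal = 0.90, site_coverage_mean = 10,
                       ch_meth = 0.02, ch_site_fraction = 0.05,
                       n_cgi = 40, cgi_width = 1000,
                       n_genes = 3000, n_go_terms = 100,
                       binding_effect = -0.15, length_effect = -0.05,
                       n_planted_terms = 0, planted_go_effect = -1,
                       expr_sd0 = 0.25, expr_sd1 = 0.5) {
  cfg <- as.list(environment())
  fracs <- c("gc_mean", "peak_fraction", "meth_background",
             "meth_cgi_proximal", "meth_cgi_distal", "ch_meth",
             "ch_site_fraction")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (upsilon_true <= 0) stop("upsilon_true must be > 0")
  if (chrom_length < bin_width) stop("chrom_length smaller than bin_width")
  if (chrom_length %% bin_width != 0) {
    stop("bin_width must divide chrom_length")
  }
  if (min(depth_chip, depth_input, depth_mnase) <= 0) {
    stop("sequencing depths must be positive")
  }
  if (n_genes < 10 * n_go_terms) {
    warning("fewer than 10 genes per GO term on average; terms may be undersized")
  }
  structure(cfg, class = "sim_config")
}

# fixed per-output seed offsets (independent reproducibility per output)
.sim_offsets <- c(genome = 101L, chip = 202L, methylation = 303L,
                  expression = 404L, features = 505L)

#' @keywords internal
sim_gc_process <- function(cfg, n_bins) {
  # AR(1) on the logit scale, clamped to [0.2, 0.8]
  phi <- exp(-cfg$bin_width / cfg$gc_corr_length)
  z <- numeric(n_bins)
  innov <- stats::rnorm(n_bins)
  z[1] <- innov[1]
  for (i in seq_len(n_bins - 1)) {
    z[i + 1] <- phi * z[i] + sqrt(1 - phi^2) * innov[i + 1]
  }
  sd_logit <- cfg$gc_sd / (cfg$gc_mean * (1 - cfg$gc_mean))
  pmin(pmax(stats::plogis(stats::qlogis(cfg$gc_mean) + sd_logit * z),
            0.2), 0.8)
}

#' Simulate a genome with controlled GC and CpG structure
#'
#' Per 150 bp (bin-width) window, a GC target follows a clamped logit-scale
#' AR(1) process with autocorrelation scale `gc_corr_length`; bases are
#' drawn independently within each window at that GC level, and extra CpG
#' dinucleotides are planted at a rate `cpg_coupling` times the baseline
#' independent-placement rate (g/2)^2, tying CpG density to GC beyond the
#' product of base frequencies. With `cpg_coupling = 0` dinucleotide
#' placement is exactly independent.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a `Biostrings::DNAStringSet`), `targets`
#'   (tibble chrom/start/end/gc_target on the bin grid) and `grid`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + .sim_offsets[["genome"]], {
    W <- config$bin_width
    nb <- config$chrom_length %/% W
    sizes <- stats::setNames(rep(nb * W, config$n_chroms),
                             paste0("chr", seq_len(config$n_chroms)))
    grid <- bin_grid(sizes, W)
    seqs <- character(config$n_chroms)
    gc_target <- numeric(0)
    for (cc in seq_len(config$n_chroms)) {
      g <- sim_gc_process(config, nb)
      gc_target <- c(gc_target, g)
      gb <- rep(g, each = W)
      u <- stats::runif(nb * W)
      # P(A) = P(T) = (1-g)/2, P(C) = P(G) = g/2
      base <- ifelse(u < (1 - gb) / 2, "A",
              ifelse(u < (1 - gb), "T",
              ifelse(u < 1 - gb / 2, "C", "G")))
      if (config$cpg_coupling > 0) {
        # plant CpGs at non-overlapping dinucleotide starts
        starts <- seq(1, nb * W - 1, by = 2)
        rate <- config$cpg_coupling * (gb[starts] / 2)^2
        hit <- starts[stats::runif(length(starts)) < rate]
        base[hit] <- "C"; base[hit + 1] <- "G"
      }
      seqs[cc] <- paste(base, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- names(sizes)
    targets <- grid
    targets$gc_target <- gc_target
    list(genome = genome, targets = targets, grid = grid)
  })
}

#' Window-level (GC, CpG) features without sequence realization
#'
#' Draws per-window GC and CpG fractions directly at the window level: the
#' same GC process as [simulate_genome()], with the CpG rate a local-linear
#' function of the realized window GC (the tangent of the
#' independent-placement rate (1 + cpg_coupling/2) (g/2)^2 at the mean GC)
#' plus independent binomial placement noise. The linear coupling makes the
#' window-level conditional-independence construction exactly removable by
#' linear partial correlation. Useful for large track-level simulations
#' (e.g. normalization recovery at 1e5 bins) where base-level sequence is
#' irrelevant.
#'
#' @param config A [sim_config()].
#' @param n_bins Number of windows to draw (single chromosome).
#' @return Feature-table-like tibble with `f_GC`, `f_CpG`, `defined`.
#' @export
simulate_bin_features <- function(config, n_bins) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + .sim_offsets[["features"]], {
    W <- config$bin_width
    g <- sim_gc_process(config, n_bins)
    gc_real <- stats::rbinom(n_bins, W, g) / W
    scale_k <- 1 + config$cpg_coupling / 2
    rate <- scale_k * (config$gc_mean / 2)^2 +
      scale_k * (config$gc_mean / 2) * (gc_real - config$gc_mean)
    rate <- pmin(pmax(rate, 1e-4), 1)
    cpg_real <- stats::rbinom(n_bins, W - 1, rate) / (W - 1)
    grid <- bin_grid(stats::setNames(n_bins * W, "chrSim"), W)
    out <- grid
    out$f_GC <- gc_real
    out$f_CpG <- cpg_real
    out$defined <- TRUE
    out
  })
}

#' Simulate a ChIP/Input/MNase experiment on given window features
#'
#' Bins share a log-normal background rate lambda_i (sd 0.5 on the log
#' scale, mean `depth_input`). Input counts are Poisson(lambda_i). ChIP
#' counts are Poisson((lambda_i + e_i)/upsilon_true) where the enrichment
#' e_i is positive only in peak bins — the bins whose GC fraction exceeds
#' the (1 - peak_fraction) quantile — and within them is an increasing
#' function of GC alone: e_i = enrich_beta * depth_input * (1 + 5 (gc_i -
#' threshold)). Because e depends on GC only (and the Poisson noise is
#' independent), ChIP is conditionally independent of CpG given GC by
#' construction. MNase counts are Poisson with rate proportional to
#' exp(mnase_gamma * (gc - mean gc)). Peak intervals are the runs of
#' enriched bins.
#'
#' @param config A [sim_config()].
#' @param features Feature table (needs `f_GC`; grid columns) from
#'   [sequence_features()] or [simulate_bin_features()].
#' @param emit_fragments Also materialize fragment tibbles (one interval
#'   per fragment, spanning its source bin). Default TRUE; disable for
#'   very large simulations where only the count tracks are needed.
#' @return List: `chip`, `input`, `mnase` (count signal tracks), `peaks`
#'   (interval tibble), `fragments` (list of 3 tibbles or NULL), `truth`
#'   (class `sim_truth`: `upsilon_true`, `enrichment` and `lambda`
#'   per-bin vectors, `peak_bins`, `conditional_independence` flag,
#'   `ses_identifiable` flag — FALSE when peak_fraction = 0, since a pure
#'   rescaling leaves no signature in the count shapes).
#' @export
simulate_chip_experiment <- function(config, features, emit_fragments = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!"f_GC" %in% names(features)) stop("features must carry f_GC")
  withr::with_seed(config$seed + .sim_offsets[["chip"]], {
    n <- nrow(features)
    gc <- features$f_GC
    gc[is.na(gc)] <- config$gc_mean
    lambda <- stats::rlnorm(n, log(config$depth_input) - 0.125, 0.5)
    e <- numeric(n)
    if (config$peak_fraction > 0) {
      thr <- stats::quantile(gc, 1 - config$peak_fraction, names = FALSE)
      in_peak <- gc > thr
      e[in_peak] <- config$enrich_beta * config$depth_input *
        (1 + 5 * (gc[in_peak] - thr))
    }
    chip_rate <- (lambda + e) / config$upsilon_true *
      (config$depth_chip / config$depth_input)
    input <- stats::rpois(n, lambda)
    chip <- stats::rpois(n, chip_rate)
    mn_shape <- exp(config$mnase_gamma * (gc - mean(gc)))
    mnase <- stats::rpois(n, config$depth_mnase * mn_shape / mean(mn_shape))
    grid <- features[, c("chrom", "start", "end")]
    attr(grid, "bin_width") <- bin_width_of(features)
    attr(grid, "chrom_sizes") <- chrom_sizes_of(features)
    peak_bins <- e > 0
    peaks <- runs_to_intervals(grid, peak_bins)
    frags <- NULL
    if (emit_fragments) {
      frags <- list(
        chip = bin_fragments(grid, chip),
        input = bin_fragments(grid, input),
        mnase = bin_fragments(grid, mnase))
    }
    truth <- structure(list(upsilon_true = config$upsilon_true,
                            enrichment = e, lambda = lambda,
                            chip_rate = chip_rate,
                            peak_bins = peak_bins,
                            conditional_independence = TRUE,
                            ses_identifiable = config$peak_fraction > 0),
                       class = "sim_truth")
    list(chip = as_track(grid, chip), input = as_track(grid, input),
         mnase = as_track(grid, mnase), peaks = peaks,
         fragments = frags, truth = truth)
  })
}

#' @keywords internal
runs_to_intervals <- function(grid, flag) {
  out <- list()
  for (ch in unique(grid$chrom)) {
    sel <- grid$chrom == ch
    r <- rle(flag[sel])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep) == 0) next
    s <- grid$start[sel][starts[keep]]
    e <- grid$end[sel][ends[keep]]
    out[[ch]] <- tibble::tibble(chrom = ch, start = s, end = e)
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  dplyr::bind_rows(out)
}

#' @keywords internal
bin_fragments <- function(grid, counts) {
  idx <- rep.int(seq_len(nrow(grid)), counts)
  tibble::tibble(chrom = grid$chrom[idx], start = grid$start[idx],
                 end = grid$end[idx], strand = "+")
}

#' Simulate per-cytosine methylation calls
#'
#' Every CpG in the genome is emitted on both strands with coverage
#' n_tot ~ Poisson(site_coverage_mean) and methylated counts
#' n_m ~ Binomial(n_tot, pi), where pi is `meth_background` outside CpG
#' islands, `meth_cgi_proximal` in promoter-proximal islands and
#' `meth_cgi_distal` in distal islands. A subsample of CH sites (fraction
#' `ch_site_fraction`) is emitted at level `ch_meth`. Promoter positions
#' (TSSs) and CGI intervals are generated here and returned so that
#' expression simulation can reuse the same anchors. Zero-coverage sites
#' are retained (they exercise undefined-bin handling downstream).
#'
#' @param config A [sim_config()].
#' @param genome A `Biostrings::DNAStringSet` from [simulate_genome()].
#' @return List: `sites` (tibble chrom/pos/strand/context/n_m/n_tot),
#'   `cgis` (tibble with `type` proximal/distal), `promoters` (tibble
#'   chrom/pos/strand of TSSs, one per gene).
#' @export
simulate_methylation <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + .sim_offsets[["methylation"]], {
    chroms <- names(genome)
    sizes <- stats::setNames(Biostrings::width(genome), chroms)
    # promoters: one TSS per gene, uniform, away from chromosome edges
    n_per <- table(factor(sample(chroms, config$n_genes, replace = TRUE),
                          chroms))
    promoters <- purrr::map_dfr(chroms, function(ch) {
      n <- n_per[[ch]]
      tibble::tibble(
        chrom = ch,
        pos = sort(sample.int(sizes[[ch]] - 2000L, n) + 1000L),
        strand = sample(c("+", "-"), n, replace = TRUE))
    })
    promoters$gene <- paste0("g", seq_len(nrow(promoters)))
    # CGIs: half proximal (centred on sampled TSSs), half distal (uniform)
    n_prox <- config$n_cgi %/% 2
    n_dist <- config$n_cgi - n_prox
    prox_idx <- sample.int(nrow(promoters), min(n_prox, nrow(promoters)))
    half <- config$cgi_width / 2
    cgis <- dplyr::bind_rows(
      tibble::tibble(chrom = promoters$chrom[prox_idx],
                     start = pmax(promoters$pos[prox_idx] - half, 0),
                     type = "proximal"),
      {
        ch_assign <- sample(chroms, n_dist, replace = TRUE)
        purrr::map_dfr(chroms, function(ch) {
          n <- sum(ch_assign == ch)
          tibble::tibble(chrom = ch,
                         start = as.numeric(sample.int(sizes[[ch]] -
                                                         config$cgi_width, n)),
                         type = "distal")
        })
      })
    cgis$end <- cgis$start + config$cgi_width
    sites <- purrr::map_dfr(chroms, function(ch) {
      cpg <- Biostrings::start(Biostrings::matchPattern("CG", genome[[ch]])) - 1
      pos <- c(cpg, cpg + 1)           # both strands of each CpG
      strand <- rep(c("+", "-"), each = length(cpg))
      pi0 <- rep(config$meth_background, length(pos))
      for (ty in c("proximal", "distal")) {
        iv <- cgis[cgis$chrom == ch & cgis$type == ty, ]
        if (nrow(iv) == 0) next
        inside <- IRanges::overlapsAny(
          IRanges::IRanges(pos + 1, pos + 1),
          IRanges::IRanges(iv$start + 1, iv$end))
        pi0[inside] <- if (ty == "proximal") config$meth_cgi_proximal else
          config$meth_cgi_distal
      }
      # CH sites: plus-strand C not followed by G, subsampled
      cvec <- Biostrings::start(Biostrings::matchPattern("C", genome[[ch]])) - 1
      ch_pos <- setdiff(cvec, cpg)
      ch_pos <- ch_pos[stats::runif(length(ch_pos)) < config$ch_site_fraction]
      all_pos <- c(pos, ch_pos)
      all_strand <- c(strand, rep("+", length(ch_pos)))
      all_ctx <- c(rep("CG", length(pos)), rep("CH", length(ch_pos)))
      all_pi <- c(pi0, rep(config$ch_meth, length(ch_pos)))
      n_tot <- stats::rpois(length(all_pos), config$site_coverage_mean)
      n_m <- stats::rbinom(length(all_pos), n_tot, all_pi)
      tibble::tibble(chrom = ch, pos = all_pos, strand = all_strand,
                     context = all_ctx, n_m = n_m, n_tot = n_tot) |>
        dplyr::arrange(.data$pos)
    })
    list(sites = sites, cgis = cgis[, c("chrom", "start", "end", "type")],
         promoters = promoters)
  })
}

#' Simulate an expression table with planted GO effects
#'
#' Gene log2 fold changes (log2 WT/KO) are generated as
#' `binding_effect * standardized promoter binding + length_effect *
#' (log10 length - 4) + planted GO shift + noise`, where the noise standard
#' deviation depends on expression as `expr_sd0 + expr_sd1 * 2^(-e/2)`
#' (e = log2 geometric-mean FPKM). Promoter binding is the mean of the
#' binding track over the 500 bp downstream of the TSS. FPKM pairs are
#' reconstructed from the geometric mean and the fold change.
#'
#' @param config A [sim_config()].
#' @param binding Signal track of binding enrichment, or `NULL` for no
#'   binding effect (pure noise model).
#' @param promoters Tibble of gene TSSs (`gene`, `chrom`, `pos`, `strand`),
#'   e.g. from [simulate_methylation()].
#' @return List: `expr` (tibble gene/fpkm_wt/fpkm_ko/log2fc/significant/
#'   length/binding), `annotation` (tibble gene/term), `truth` (class
#'   `sim_truth`: planted terms, per-gene true signal components).
#' @export
simulate_expression <- function(config, binding = NULL, promoters = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + .sim_offsets[["expression"]], {
    ng <- config$n_genes
    if (is.null(promoters)) {
      promoters <- tibble::tibble(gene = paste0("g", seq_len(ng)),
                                  chrom = NA_character_, pos = NA_real_,
                                  strand = "+")
    }
    ng <- nrow(promoters)
    len <- round(10^stats::runif(ng, 2.7, 5.5))
    e_log2 <- stats::rnorm(ng, 3, 2)
    bind_val <- numeric(ng)
    if (!is.null(binding)) {
      W <- bin_width_of(binding)
      chroms <- unique(binding$chrom)
      nbins <- tapply(binding$start, factor(binding$chrom, chroms), length)
      nb <- as.numeric(nbins)
      off <- stats::setNames(cumsum(c(0, nb[-length(nb)])), chroms)
      for (i in seq_len(ng)) {
        ch <- promoters$chrom[i]
        if (is.na(ch) || !ch %in% chroms) next
        dir <- if (promoters$strand[i] == "-") -1 else 1
        # first 500 bp downstream of the TSS
        lo <- if (dir == 1) promoters$pos[i] else promoters$pos[i] - 500
        bins <- unique(pmax(pmin((lo + c(0, 250, 499)) %/% W,
                                 nbins[[ch]] - 1), 0))
        bind_val[i] <- mean(binding$value[off[[ch]] + bins + 1], na.rm = TRUE)
      }
      bind_val[is.na(bind_val)] <- mean(bind_val, na.rm = TRUE)
      if (stats::sd(bind_val) > 0) bind_val <- as.numeric(scale(bind_val))
    }
    # GO annotation: random member sets; planted terms shift their genes
    terms <- paste0("GO:", sprintf("%07d", seq_len(config$n_go_terms)))
    annotation <- purrr::map_dfr(terms, function(tm) {
      size <- sample(10:80, 1)
      tibble::tibble(term = tm,
                     gene = promoters$gene[sample.int(ng, min(size, ng))])
    })
    planted <- character(0)
    go_shift <- numeric(ng)
    if (config$n_planted_terms > 0) {
      planted <- terms[seq_len(config$n_planted_terms)]
      pg <- unique(annotation$gene[annotation$term %in% planted])
      go_shift[match(pg, promoters$gene)] <- config$planted_go_effect
    }
    sd_e <- config$expr_sd0 + config$expr_sd1 * 2^(-e_log2 / 2)
    signal <- config$binding_effect * bind_val +
      config$length_effect * (log10(len) - 4) + go_shift
    lfc <- signal + stats::rnorm(ng, 0, sd_e)
    expr <- tibble::tibble(
      gene = promoters$gene,
      fpkm_wt = 2^(e_log2 + lfc / 2),
      fpkm_ko = 2^(e_log2 - lfc / 2),
      log2fc = lfc,
      significant = abs(lfc) > 2 * sd_e,
      length = len,
      binding = bind_val)
    truth <- structure(list(planted_terms = planted,
                            true_signal = signal, noise_sd = sd_e),
                       class = "sim_truth")
    list(expr = expr, annotation = annotation[, c("gene", "term")],
         truth = truth)
  })
}
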