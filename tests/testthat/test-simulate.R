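test_that("config validation catches bad parameters", {
  expect_error(sim_config(upsilon_true = 0), "upsilon_true")
  expect_error(sim_config(peak_fraction = 1.2), "peak_fraction")
  expect_error(sim_config(chrom_length = 100, bin_width = 150), "smaller")
  expect_error(sim_config(chrom_length = 1000, bin_width = 150), "divide")
  expect_warning(sim_config(n_genes = 50, n_go_terms = 100), "undersized")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 7, n_chroms = 1, chrom_length = 150000)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  ft <- simulate_bin_features(cfg, 2000)
  s1 <- simulate_chip_experiment(cfg, ft)
  s2 <- simulate_chip_experiment(cfg, ft)
  expect_identical(s1$chip$value, s2$chip$value)
  expect_identical(s1$fragments$input, s2$fragments$input)
  m1 <- simulate_methylation(cfg, g1$genome)
  m2 <- simulate_methylation(cfg, g1$genome)
  expect_identical(m1$sites, m2$sites)
  e1 <- simulate_expression(cfg)
  e2 <- simulate_expression(cfg)
  expect_identical(e1$expr, e2$expr)
  # different seeds change the data
  cfg2 <- sim_config(seed = 8, n_chroms = 1, chrom_length = 150000)
  expect_false(identical(as.character(simulate_genome(cfg2)$genome),
                         as.character(g1$genome)))
})

test_that("zero CpG coupling leaves dinucleotides at independent-placement rates", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length = 990000,
                    cpg_coupling = 0)
  gen <- simulate_genome(cfg)
  big <- bin_grid(c(chr1 = 990000), 9900)  # 66 fine segments per window
  ft <- sequence_features(gen$genome, big, k_set = 1)
  # realized CpG frequency ~ product of realized C and G frequencies, taken
  # per 150 bp segment (GC varies across the ~10 kb window) and averaged
  fine <- Biostrings::letterFrequency(
    Biostrings::Views(gen$genome[[1]],
                      start = seq(1, 990000, by = 150), width = 150),
    c("C", "G")) / 150
  seg_prod <- fine[, "C"] * fine[, "G"]
  per_window <- colMeans(matrix(seg_prod, nrow = 66))
  resid <- ft$f_CpG - per_window
  se <- sqrt(per_window / 9900)
  expect_lt(mean(abs(resid) > 4 * se), 0.05)
  expect_lt(abs(mean(resid)), 1e-3)
})

test_that("positive coupling raises CpG above the independence product", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length = 480000,
                    cpg_coupling = 2)
  gen <- simulate_genome(cfg)
  big <- bin_grid(c(chr1 = 480000), 9900)
  ft <- sequence_features(gen$genome, big, k_set = 1)
  fC <- Biostrings::letterFrequency(
    Biostrings::Views(gen$genome[[1]], big$start + 1, width = 10000),
    c("C", "G")) / 10000
  expect_gt(mean(ft$f_CpG - fC[, "C"] * fC[, "G"]), 0)
})

test_that("window GC targets are realized in sequence (r >= 0.8)", {
  cfg <- sim_config(seed = 19, n_chroms = 1, chrom_length = 1.0005e6,
                    gc_corr_length = 1000)
  gen <- simulate_genome(cfg)
  ft <- sequence_features(gen$genome, gen$grid, k_set = NULL)
  expect_gt(cor(gen$targets$gc_target, ft$f_GC), 0.8)
  expect_gt(mean(ft$f_GC), 0.35); expect_lt(mean(ft$f_GC), 0.5)
})

test_that("chip simulation plants conditional independence of CpG given GC", {
  sim <- small_sim(seed = 23, n_bins = 60000)
  chip <- sim$sim$chip
  g <- chip[, c("chrom", "start", "end")]
  attr(g, "bin_width") <- 150
  gc <- as_track(sim$feats, sim$feats$f_GC)
  cpg <- as_track(sim$feats, sim$feats$f_CpG)
  marg <- track_cor(chip, cpg)$r
  part <- partial_cor(chip, cpg, list(gc))$r
  expect_gt(marg, 0.1)
  expect_lt(abs(part), 0.025)
  # enrichment is a function of GC alone, positive only in peak bins
  tr <- sim$sim$truth
  expect_true(all(tr$enrichment[!tr$peak_bins] == 0))
  expect_true(all(tr$enrichment[tr$peak_bins] > 0))
  # peaks intervals match the enriched runs
  pk_bins <- chipdissect:::window_peak_overlap(sim$feats, sim$sim$peaks) > 0
  expect_equal(pk_bins, tr$peak_bins)
})

test_that("fragment emission conserves the Poisson draws", {
  cfg <- sim_config(seed = 29)
  ft <- simulate_bin_features(cfg, 3000)
  sim <- simulate_chip_experiment(cfg, ft)
  expect_equal(nrow(sim$fragments$chip), sum(sim$chip$value))
  expect_equal(nrow(sim$fragments$mnase), sum(sim$mnase$value))
  # coverage of the emitted fragments reproduces the count track exactly
  g <- sim$chip[, c("chrom", "start", "end")]
  attr(g, "bin_width") <- bin_width_of(ft)
  attr(g, "chrom_sizes") <- chrom_sizes_of(ft)
  cov <- fragment_coverage(sim$fragments$chip, g)
  expect_equal(cov$value, sim$chip$value)
  expect_error(simulate_chip_experiment(sim_config(depth_input = 0), ft))
})

test_that("MNase occupancy tracks GC in the intended regime", {
  sim <- small_sim(seed = 31, n_bins = 40000)
  gc <- as_track(sim$feats, sim$feats$f_GC)
  r <- track_cor(sim$sim$mnase, gc)$r
  expect_gt(r, 0.4); expect_lt(r, 0.8)
})

test_that("methylation levels separate proximal and distal CpG islands", {
  cfg <- sim_config(seed = 37, n_chroms = 1, chrom_length = 6e5,
                    meth_cgi_proximal = 0.1, meth_cgi_distal = 0.9,
                    n_cgi = 30, n_genes = 200, n_go_terms = 20)
  gen <- simulate_genome(cfg)
  met <- simulate_methylation(cfg, gen$genome)
  lt <- bin_methylation_level(met$sites, gen$grid)
  lab_level <- function(type) {
    iv <- met$cgis[met$cgis$type == type, ]
    hit <- rep(FALSE, nrow(gen$grid))
    for (i in seq_len(nrow(iv))) {
      hit <- hit | (gen$grid$chrom == iv$chrom[i] &
                      gen$grid$start >= iv$start[i] &
                      gen$grid$end <= iv$end[i])
    }
    lt$value[hit & !is.na(lt$value)]
  }
  prox <- lab_level("proximal"); dist <- lab_level("distal")
  expect_gt(length(prox), 10); expect_gt(length(dist), 10)
  expect_lt(stats::wilcox.test(prox, dist)$p.value, 0.01)
  expect_lt(median(prox), 0.3); expect_gt(median(dist), 0.7)
  # some zero-coverage sites are emitted
  expect_gt(sum(met$sites$n_tot == 0), 0)
})

test_that("expression simulation plants binding, length and GO structure", {
  cfg <- sim_config(seed = 43, n_planted_terms = 1, planted_go_effect = -1,
                    length_effect = -0.2, binding_effect = -0.3)
  sim <- simulate_expression(cfg)
  expect_equal(length(sim$truth$planted_terms), 1)
  planted <- sim$truth$planted_terms
  pg <- unique(sim$annotation$gene[sim$annotation$term == planted])
  # planted genes have the shift baked into the true signal
  expect_lt(mean(sim$truth$true_signal[match(pg, sim$expr$gene)]) -
              mean(sim$truth$true_signal), -0.8)
  # length effect present in realized fold changes
  expect_lt(cor(sim$expr$log2fc, log10(sim$expr$length)), -0.05)
  # fpkm pair reconstructs the fold change
  expect_equal(log2(sim$expr$fpkm_wt / sim$expr$fpkm_ko), sim$expr$log2fc,
               tolerance = 1e-10)
})
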