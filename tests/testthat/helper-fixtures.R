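# Shared fixtures, built in code.

# random DNA string of length n (seeded by caller)
random_dna <- function(n, p = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

as_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

# naive per-position k-mer counter, the oracle for sequence_features()
naive_bin_features <- function(seq_str, start, width, k_set = c(1, 2)) {
  s <- substr(seq_str, start + 1, start + width)
  chars <- strsplit(s, "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "T"))) return(NULL)
  f_gc <- sum(chars %in% c("C", "G")) / width
  dints <- paste0(chars[-width], chars[-1])
  out <- list(f_GC = f_gc,
              f_CpG = sum(dints == "CG") / (width - 1),
              f_CpH = sum(dints %in% c("CA", "CC", "CT")) / (width - 1))
  for (k in k_set) {
    words <- vapply(seq_len(width - k + 1),
                    function(i) paste(chars[i:(i + k - 1)], collapse = ""),
                    character(1))
    cls <- chipdissect::kmer_classes(k)
    for (j in seq_len(nrow(cls))) {
      out[[paste0("kc_", cls$class[j])]] <-
        sum(words %in% cls$members[[j]]) / (width - k + 1)
    }
  }
  out
}

# brute-force per-base coverage oracle
naive_coverage <- function(fragments, chrom_size, grid_starts, width) {
  acc <- numeric(chrom_size)
  for (i in seq_len(nrow(fragments))) {
    s <- max(fragments$start[i], 0) + 1
    e <- min(fragments$end[i], chrom_size)
    if (s <= e) acc[s:e] <- acc[s:e] + 1
  }
  vapply(grid_starts, function(st) mean(acc[(st + 1):(st + width)]),
         numeric(1))
}

# a small simulated experiment reused by several test files
small_sim <- function(seed = 42, peak_fraction = 0.1, n_bins = 20000,
                      upsilon_true = 4.41, ...) {
  cfg <- chipdissect::sim_config(seed = seed, peak_fraction = peak_fraction,
                                 upsilon_true = upsilon_true, ...)
  feats <- chipdissect::simulate_bin_features(cfg, n_bins)
  sim <- chipdissect::simulate_chip_experiment(cfg, feats,
                                               emit_fragments = FALSE)
  list(cfg = cfg, feats = feats, sim = sim)
}
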