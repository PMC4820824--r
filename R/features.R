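#' Reverse-complement equivalence classes of k-mers
#'
#' Because sequencing signals are strand-symmetric, a k-mer and its reverse
#' complement carry the same information; features are therefore collapsed
#' into equivalence classes \{w, revcomp(w)\}. The canonical representative
#' of a class is its lexicographically smaller member.
#'
#' @param k Word length, one of 1, 2, 3.
#' @return A tibble with one row per class: `class` (canonical word),
#'   `members` (list column of the one or two words), `palindromic`
#'   (TRUE when w == revcomp(w)).
#' @examples
#' kmer_classes(2) # 10 classes
#' @export
kmer_classes <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || !(k %in% 1:3)) {
    stop("k must be 1, 2 or 3")
  }
  words <- sort(apply(do.call(expand.grid,
                              rep(list(c("A", "C", "G", "T")), k)),
                      1, function(r) paste(rev(r), collapse = "")))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  canon <- pmin(words, rc)
  cls <- sort(unique(canon))
  tibble::tibble(
    class = cls,
    members = purrr::map(cls, ~ sort(unique(c(.x, rc[match(.x, words)])))),
    palindromic = purrr::map_lgl(members, ~ length(.x) == 1)
  )
}

#' @keywords internal
load_genome <- function(fasta) {
  if (inherits(fasta, "DNAStringSet")) {
    g <- fasta
  } else {
    g <- Biostrings::readDNAStringSet(fasta)
  }
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Per-bin sequence composition features
#'
#' For every bin of the grid computes the GC fraction `f_GC`, the CpG
#' dinucleotide fraction `f_CpG` (CpG starts within the bin divided by
#' W - 1; bin-spanning dinucleotides are ignored), the CpH fraction `f_CpH`
#' (plus-strand C followed by A/C/T), and reverse-complement-collapsed
#' k-mer class frequencies for each requested k (columns `kc_<class>`,
#' denominated by W - k + 1). Bins containing any non-ACGT base are marked
#' undefined (`defined = FALSE`) and their features set to `NA`.
#'
#' @param fasta Path to a FASTA file or a `Biostrings::DNAStringSet`.
#' @param grid Bin grid from [bin_grid()].
#' @param k_set Integer vector of k-mer lengths for class frequencies
#'   (subset of 1:3); `NULL` for none.
#' @return The grid tibble with feature columns appended.
#' @export
sequence_features <- function(fasta, grid, k_set = c(1L, 2L)) {
  genome <- load_genome(fasta)
  missing <- setdiff(unique(grid$chrom), names(genome))
  if (length(missing) > 0) {
    stop("chromosomes missing from FASTA: ", paste(missing, collapse = ", "))
  }
  W <- bin_width_of(grid)
  per_chrom <- lapply(split(grid, factor(grid$chrom, unique(grid$chrom))),
                      function(g) {
    seqs <- Biostrings::Views(genome[[g$chrom[1]]], start = g$start + 1,
                              width = W)
    base <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
    defined <- rowSums(base) == W
    f_gc <- (base[, "C"] + base[, "G"]) / W
    di <- Biostrings::oligonucleotideFrequency(seqs, width = 2)
    f_cpg <- di[, "CG"] / (W - 1)
    f_cph <- (di[, "CA"] + di[, "CC"] + di[, "CT"]) / (W - 1)
    out <- tibble::tibble(f_GC = f_gc, f_CpG = f_cpg, f_CpH = f_cph)
    for (k in k_set) {
      classes <- kmer_classes(k)
      cnt <- Biostrings::oligonucleotideFrequency(seqs, width = k)
      freq <- vapply(classes$members, function(m) {
        rowSums(cnt[, m, drop = FALSE]) / (W - k + 1)
      }, numeric(nrow(g)))
      colnames(freq) <- paste0("kc_", classes$class)
      out <- dplyr::bind_cols(out, tibble::as_tibble(freq))
    }
    out$defined <- defined
    out[!defined, setdiff(names(out), "defined")] <- NA_real_
    out
  })
  feats <- dplyr::bind_rows(per_chrom)
  out <- dplyr::bind_cols(grid, feats)
  attr(out, "bin_width") <- W
  attr(out, "chrom_sizes") <- chrom_sizes_of(grid)
  out
}
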