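# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive results by the most direct method available
# (exhaustive dynamic programming, enumeration, direct translation) and never
# call the code paths they check.

# exhaustive affine-gap local alignment score (Gotoh), convention: a gap of
# length L costs gap_open + L * gap_ext; N never matches
oracle_local_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = -4, gap_ext = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_ext,
                             X[i, j + 1] + gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_ext,
                             Y[i + 1, j] + gap_ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# enumeration oracle for probe tiling offsets (set union, as sets of integers)
oracle_tile_offsets <- function(L, probe_len = 60, step = 4,
                                edge = FALSE, edge_window = 30) {
  last <- L - probe_len
  off <- union(seq(0, last, by = step), last)
  if (edge) {
    off <- union(off, seq(0, min(edge_window - 1, last)))
    off <- union(off, seq(max(0, last - edge_window + 1), last))
  }
  sort(off)
}

# brute-force per-k-mer scan for soft masking
oracle_masked <- function(probe, ref_seqs, k = 15, threshold = 50) {
  count_one <- function(kmer) {
    rc_ref <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(ref_seqs)))
    sum(vapply(c(ref_seqs, rc_ref), function(s) {
      n <- nchar(s)
      if (n < k) return(0L)
      sum(substring(s, 1:(n - k + 1), k:n) == kmer)
    }, integer(1)))
  }
  n <- nchar(probe)
  kmers <- substring(probe, 1:(n - k + 1), k:n)
  any(vapply(kmers, count_one, integer(1)) >= threshold)
}

# direct codon-translation oracle via the standard genetic code
oracle_codon_effect <- function(codon, pos, alt) {
  gc <- Biostrings::GENETIC_CODE
  alt_codon <- codon
  substr(alt_codon, pos, pos) <- alt
  if (gc[[codon]] == gc[[alt_codon]]) "synonymous" else "non_synonymous"
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# mutate a sequence with point substitutions at a given rate
mutate_seq <- function(seq, rate) {
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < rate)
  for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  paste(s, collapse = "")
}

# a mixed-divergence species: half the genes at d_low (close-relative level),
# half at d_high (divergent probe-design source), one evolve call
mixed_species <- function(space, d_low, d_high, seed, het = 0.002) {
  gids <- names(space$genomes)
  dv <- stats::setNames(rep(c(d_low, d_high), length.out = length(gids)), gids)
  evolve_species(space, dv, het, seed, "mixed")
}
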