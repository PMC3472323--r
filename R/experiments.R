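# ---- composed desk-scale experiments ---------------------------------------

#' Per-target divergence over known in-target spans
#'
#' Mismatches divided by alignable bases between each target sequence and its
#' in-target span on the contig.  When the map's spans are reliable (no
#' indels), this is the divergence of the natural gap-free alignment; a fully
#' local re-alignment would trim mismatch-dense ends at high divergence and
#' underestimate.
#'
#' @param map an `"in_target_map"` with its `contigs` attribute (or pass
#'   `contigs`).
#' @param target_seqs named character vector of target sequences.
#' @param contigs named character vector (defaults to `attr(map, "contigs")`).
#' @return numeric vector of divergences, one per map row.
#' @export
target_divergence <- function(map, target_seqs, contigs = NULL) {
  if (is.null(contigs)) contigs <- attr(map, "contigs")
  stopifnot(!is.null(contigs))
  vapply(seq_len(nrow(map)), function(i) {
    tgt <- target_seqs[[map$target_id[i]]]
    sub <- substr(contigs[[map$contig_id[i]]], map$c_start[i] + 1L,
                  map$c_end[i])
    n <- min(nchar(tgt), nchar(sub))
    .hamming(substr(tgt, 1, n), substr(sub, 1, n)) / n
  }, numeric(1))
}

#' Divergence-decay capture experiment
#'
#' Simulates one multiplexed library over a two-strata target panel --
#' ~1 kb single-exon loci at a close-relative divergence (0.58%) and at the
#' divergent-genome level (planted uniformly in 8.76-8.98%) -- captures
#' reads under the exponential decay model, normalizes libraries by
#' subsampling to a common pair count, and bins normalized per-target
#' coverage by measured divergence (1% bins).
#'
#' @param seed RNG seed.
#' @param n_loci total loci (half per stratum).
#' @param n_samples libraries to simulate and normalize across.
#' @param d_close close-relative divergence.
#' @param d_far_range divergent-source range (uniform per locus).
#' @param fragments_per_target mean fragment attempts per locus per library.
#' @return list with `table` (the [divergence_coverage()] bins), `fold`
#'   (mean coverage of bins at or below 5% divided by the 8-9% bin mean),
#'   `divergence`, `coverage` per target, and `n_pairs_used`.
#' @export
divergence_decay_experiment <- function(seed, n_loci = 80L, n_samples = 2L,
                                        d_close = 0.0058,
                                        d_far_range = c(0.0876, 0.0898),
                                        fragments_per_target = 25) {
  cfg <- sim_config(seed = seed, n_genes = n_loci,
                    exons_per_gene = c(1L, 1L), exon_len = c(999L, 999L),
                    x_fraction = 0, fragments_per_target = fragments_per_target,
                    offtarget_fraction = 0.3)
  space <- simulate_gene_space(cfg)
  gids <- names(space$genomes)
  far <- gids[seq_along(gids) > length(gids) / 2]
  dv <- stats::setNames(rep(d_close, length(gids)), gids)
  dv[far] <- with_seed(seed + 1L, stats::runif(length(far), d_far_range[1],
                                               d_far_range[2]))
  sp <- evolve_species(space, dv, cfg$heterozygosity, seed + 2L, "mixed")
  samples <- sim_samples(n_samples, "mixed")
  reads <- simulate_capture_reads(sp, space, samples, cfg, seed = seed + 3L)
  # normalize: equal pair counts per library before coverage
  pairs <- reads$pairs[!reads$pairs$is_contam, , drop = FALSE]
  per_lib <- split(pairs, pairs$true_sample)
  n_common <- min(vapply(per_lib, nrow, integer(1)))
  keep_ids <- unlist(lapply(seq_along(per_lib), function(i)
    subsample_pairs(per_lib[[i]], n_common, seed + 10L + i)$pair_id))
  keep_reads <- paste0(rep(keep_ids, each = 2), c("/1", "/2"))
  aln <- reads$aln[reads$aln$read_id %in% keep_reads, , drop = FALSE]
  pile <- pileup(aln, reads$contigs)
  map <- reads$in_target_map
  cov <- coverage_summary(pile, map)$per_target$mean_cov
  div <- target_divergence(
    map, stats::setNames(space$exon_targets$sequence,
                         space$exon_targets$target_id))
  tab <- divergence_coverage(div, cov)
  # fold: pooled mean coverage of targets at <= 5% divergence over the
  # pooled mean of the 8-9% bin (target-weighted, not mean-of-bin-means)
  low <- mean(cov[div <= 0.05])
  hi <- cov[div >= 0.08 & div < 0.09]
  list(table = tab,
       fold = if (length(hi)) low / mean(hi) else NA_real_,
       divergence = div, coverage = cov,
       n_pairs_used = n_common * length(per_lib))
}

#' End-to-end capture evaluation experiment
#'
#' Simulates a small multiplexed capture (close-relative divergence),
#' runs the filtration truth checks, builds the pileup, and returns the
#' headline capture metrics plus the haploid error estimate from planted
#' haploid reads.
#'
#' @param seed RNG seed.
#' @param n_genes gene count.
#' @param n_samples samples in the library.
#' @return list with `sensitivity`, `specificity`, `coverage_fractions`,
#'   `mean_coverage`, `duplicate_fraction`, `contaminant_fraction`,
#'   `fraction_passed`, `planted` (the config), and the objects used.
#' @export
capture_eval_experiment <- function(seed, n_genes = 15L, n_samples = 2L) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    duplicate_fraction = 0.05)
  space <- simulate_gene_space(cfg)
  sp <- evolve_species(space, 0.0058, cfg$heterozygosity, seed + 1L, "close")
  samples <- sim_samples(n_samples, "close")
  reads <- simulate_capture_reads(sp, space, samples, cfg, seed = seed + 2L)
  pile <- pileup(reads$aln, reads$contigs)
  map <- reads$in_target_map
  cs <- coverage_summary(pile, map)
  list(sensitivity = sensitivity(map, pile),
       specificity = specificity(reads$aln, map),
       coverage_fractions = cs$fractions,
       mean_coverage = cs$mean_coverage,
       duplicate_fraction = mean(reads$pairs$is_dup),
       contaminant_fraction = mean(reads$pairs$is_contam),
       config = cfg, reads = reads, pile = pile, map = map)
}
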