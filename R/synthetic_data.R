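# ---- ground-truth capture-experiment simulator ------------------------------

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a multiplexed, transcriptome-based
#' capture experiment: 100-bp paired reads from ~N(250, 50) fragments, a
#' per-base sequencing error around 4e-4 (Phred ~34), duplicate fractions in
#' the percent range, 7-nt sample barcodes, capture efficiency decaying
#' exponentially beyond ~5% probe-target divergence (a 3-4x coverage drop by
#' ~9%), and a mild quadratic GC penalty.
#'
#' @param seed mandatory RNG seed.
#' @param n_genes number of genes in the ancestral gene space.
#' @param exons_per_gene inclusive range of exon counts per gene.
#' @param exon_len,intron_len,utr_len inclusive bp ranges (exon lengths are
#'   rounded to codon multiples).
#' @param divergences species divergences from the ancestor (fractions).
#' @param heterozygosity per-base heterozygosity within a species.
#' @param read_len read length (paired).
#' @param error_rate per-base sequencing error probability.
#' @param duplicate_fraction fraction of final read pairs that are PCR
#'   duplicates.
#' @param contaminant_fraction fraction of final read pairs drawn from the
#'   contaminant sequence.
#' @param frag_mean,frag_sd fragment size distribution (clipped to
#'   \[read_len, 500\]).
#' @param capture_d0 divergence knee below which capture is unimpaired.
#' @param capture_lambda exponential decay rate beyond the knee.
#' @param gc_alpha quadratic GC penalty coefficient:
#'   `p_gc = max(0, 1 - gc_alpha * (gc - 0.5)^2)`.
#' @param x_fraction fraction of genes placed on the X chromosome.
#' @param offtarget_fraction fraction of aligned (non-contaminant) pairs
#'   drawn from off-target (decoy) regions.
#' @param fragments_per_target mean captured-fragment attempts per target per
#'   sample.
#' @param n_decoys,decoy_len decoy (off-target consensus) contigs.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_genes = 30L,
                       exons_per_gene = c(2L, 4L),
                       exon_len = c(120L, 400L),
                       intron_len = c(80L, 300L),
                       utr_len = c(60L, 200L),
                       divergences = c(0.006, 0.015, 0.088),
                       heterozygosity = 0.002,
                       read_len = 100L,
                       error_rate = 4e-4,
                       duplicate_fraction = 0.015,
                       contaminant_fraction = 0.01,
                       frag_mean = 250, frag_sd = 50,
                       capture_d0 = 0.05, capture_lambda = 32,
                       gc_alpha = 2,
                       x_fraction = 0.15,
                       offtarget_fraction = 0.6,
                       fragments_per_target = 20,
                       n_decoys = 15L, decoy_len = 1000L) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(all(divergences >= 0), !is.unsorted(divergences),
            error_rate > 0, error_rate < 1,
            duplicate_fraction >= 0, duplicate_fraction < 1,
            contaminant_fraction >= 0, contaminant_fraction < 1,
            exon_len[1] >= 60)
  structure(as.list(environment()), class = "sim_config")
}

.rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                               collapse = "")

# codons per amino acid, standard code
.aa_codons <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- split(names(Biostrings::GENETIC_CODE),
                                  unname(Biostrings::GENETIC_CODE))
    gc
  }
})

#' Simulate the ancestral gene space
#'
#' Generates genes with exon/intron/UTR structure on one genomic contig per
#' gene, spliced transcripts, translated proteins (no internal stops, by
#' construction from random proteins back-translated with random synonymous
#' codons), and the per-gene reference exon sets used for boundary transfer.
#' Exon lengths are codon multiples so every exonic codon lies within one
#' exon.  Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list of class `"gene_space"`: `config`, `genes` (data.frame
#'   `gene_id`, `chrom`, `n_exons`), `genomes`, `transcripts`, `proteins`,
#'   `ref_exons` (named character vectors), `models` ([gene_model()] rows on
#'   the genomic contigs), `exon_targets` (data.frame of exon spans on the
#'   genomic contigs: `target_id`, `contig_id`, `start`, `end`, `sequence`),
#'   `tx_cds_span` (per transcript), `contaminant` (random contaminant
#'   sequence).
#' @export
simulate_gene_space <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    aa_tab <- .aa_codons()
    aas <- setdiff(names(aa_tab), "*")
    stops <- aa_tab[["*"]]
    genes <- genomes <- transcripts <- proteins <- list()
    ref_exons <- character(0)
    models <- list(); exon_targets <- list(); tx_cds <- list()
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("gene%03d", g)
      n_ex <- config$exons_per_gene[1] +
        sample.int(config$exons_per_gene[2] - config$exons_per_gene[1] + 1L,
                   1) - 1L
      ex_len <- 3L * round(stats::runif(n_ex, config$exon_len[1],
                                        config$exon_len[2]) / 3)
      if (sum(ex_len) %% 3L != 0L) ex_len[1] <- ex_len[1] + (3L - sum(ex_len) %% 3L)
      plen <- sum(ex_len) / 3L - 1L  # last codon is the stop
      protein <- paste(c("M", sample(aas, plen - 1L, replace = TRUE)),
                       collapse = "")
      codons <- vapply(strsplit(protein, "")[[1]], function(a)
        sample(aa_tab[[a]], 1), character(1))
      cds <- paste(c(codons, sample(stops, 1)), collapse = "")
      ex_seq <- substring(cds, cumsum(c(1L, ex_len[-n_ex])),
                          cumsum(ex_len))
      in_len <- if (n_ex > 1)
        round(stats::runif(n_ex - 1L, config$intron_len[1],
                           config$intron_len[2])) else integer(0)
      introns <- vapply(in_len, .rand_dna, character(1))
      u5 <- .rand_dna(round(stats::runif(1, config$utr_len[1], config$utr_len[2])))
      u3 <- .rand_dna(round(stats::runif(1, config$utr_len[1], config$utr_len[2])))
      pieces <- character(0)
      feat <- data.frame(feature = character(0), start = integer(0),
                         end = integer(0), frame = integer(0))
      at <- 0L
      add <- function(f, s, fr = NA_integer_) {
        pieces <<- c(pieces, s)
        feat <<- rbind(feat, data.frame(feature = f, start = at,
                                        end = at + nchar(s), frame = fr))
        at <<- at + nchar(s)
      }
      add("utr5", u5)
      cds_consumed <- 0L
      for (k in seq_len(n_ex)) {
        add("cds", ex_seq[k], (3L - cds_consumed %% 3L) %% 3L)
        cds_consumed <- cds_consumed + ex_len[k]
        if (k < n_ex) add("intron", introns[k])
      }
      add("utr3", u3)
      contig <- paste(pieces, collapse = "")
      chrom <- if (stats::runif(1) < config$x_fraction) "X" else "auto"
      genes[[g]] <- data.frame(gene_id = gid, chrom = chrom, n_exons = n_ex,
                               stringsAsFactors = FALSE)
      genomes[[gid]] <- contig
      transcripts[[gid]] <- paste0(u5, cds, u3)
      tx_cds[[gid]] <- c(nchar(u5), nchar(u5) + nchar(cds))
      proteins[[gid]] <- protein
      names(ex_seq) <- paste0(gid, "|exon_", seq_len(n_ex))
      ref_exons <- c(ref_exons, ex_seq)
      models[[g]] <- gene_model(gid, feat$feature, feat$start, feat$end,
                                feat$frame)
      cdsr <- feat[feat$feature == "cds", , drop = FALSE]
      exon_targets[[g]] <- data.frame(
        target_id = names(ex_seq), contig_id = gid,
        start = cdsr$start, end = cdsr$end, sequence = ex_seq,
        chrom = chrom, stringsAsFactors = FALSE)
    }
    structure(list(
      config = config,
      genes = do.call(rbind, genes),
      genomes = unlist(genomes),
      transcripts = unlist(transcripts),
      proteins = unlist(proteins),
      ref_exons = ref_exons,
      models = do.call(rbind, models),
      exon_targets = {
        et <- do.call(rbind, exon_targets); rownames(et) <- NULL; et
      },
      tx_cds_span = tx_cds,
      contaminant = c(contaminant = .rand_dna(20000L))),
      class = "gene_space")
  })
}

#' Evolve a species genome from the ancestor
#'
#' Point substitutions are placed uniformly at rate `divergence` (no
#' back-mutation correction, adequate at these scales); heterozygous sites
#' are placed at rate `heterozygosity` between the two haplotypes (haplotype
#' 1 is the species consensus).  Indels are omitted by default.
#'
#' @param space a [simulate_gene_space()] result.
#' @param divergence substitution rate from the ancestor: a scalar, or a
#'   named vector over gene contigs (so a subset of loci can carry the
#'   divergence of a distant probe-design source while the rest stay close).
#' @param heterozygosity per-base heterozygosity.
#' @param seed RNG seed.
#' @param species label.
#' @return list of class `"sim_species"`: `species`, `genomes` (haplotype 1),
#'   `hap2`, `mutations` (data.frame `contig_id`, `pos`, `from`, `to`),
#'   `het_sites`, `div_rates` (the planted rate per contig),
#'   `realized_divergence`.
#' @export
evolve_species <- function(space, divergence, heterozygosity = 0.002,
                           seed = 1L, species = "species") {
  stopifnot(inherits(space, "gene_space"),
            all(divergence >= 0), all(divergence <= 0.2))
  with_seed(seed, {
    muts <- list(); hets <- list()
    genomes <- space$genomes; hap2 <- space$genomes
    for (cid in names(genomes)) {
      d_here <- if (length(divergence) > 1) divergence[[cid]] else divergence
      s <- strsplit(genomes[[cid]], "")[[1]]
      L <- length(s)
      mpos <- which(stats::runif(L) < d_here)
      if (length(mpos)) {
        from <- s[mpos]
        to <- vapply(from, function(b) sample(setdiff(DNA_BASES, b), 1),
                     character(1))
        s[mpos] <- to
        muts[[cid]] <- data.frame(contig_id = cid, pos = mpos - 1L,
                                  from = from, to = to,
                                  stringsAsFactors = FALSE)
      }
      h2 <- s
      hpos <- which(stats::runif(L) < heterozygosity)
      if (length(hpos)) {
        h2[hpos] <- vapply(s[hpos], function(b)
          sample(setdiff(DNA_BASES, b), 1), character(1))
        hets[[cid]] <- data.frame(contig_id = cid, pos = hpos - 1L,
                                  allele1 = s[hpos], allele2 = h2[hpos],
                                  stringsAsFactors = FALSE)
      }
      genomes[[cid]] <- paste(s, collapse = "")
      hap2[[cid]] <- paste(h2, collapse = "")
    }
    mutations <- if (length(muts)) do.call(rbind, c(muts, make.row.names = FALSE))
      else data.frame(contig_id = character(0), pos = integer(0),
                      from = character(0), to = character(0))
    het_sites <- if (length(hets)) do.call(rbind, c(hets, make.row.names = FALSE))
      else data.frame(contig_id = character(0), pos = integer(0),
                      allele1 = character(0), allele2 = character(0))
    rates <- if (length(divergence) > 1)
      vapply(names(genomes), function(cid) divergence[[cid]], numeric(1))
    else stats::setNames(rep(divergence, length(genomes)), names(genomes))
    structure(list(species = species, genomes = genomes, hap2 = hap2,
                   mutations = mutations, het_sites = het_sites,
                   div_rates = rates,
                   realized_divergence = nrow(mutations) /
                     sum(nchar(space$genomes))),
              class = "sim_species")
  })
}

#' Default sample sheet
#'
#' @param n number of samples.
#' @param species species label.
#' @param sexes recycled vector of `"F"`/`"M"`.
#' @return data.frame `sample_id`, `species`, `sex`, `barcode` (7-nt,
#'   pairwise Hamming distance >= 3).
#' @export
sim_samples <- function(n, species = "species", sexes = c("F", "M")) {
  data.frame(sample_id = sprintf("%s_s%02d", species, seq_len(n)),
             species = species, sex = rep_len(sexes, n),
             barcode = default_barcodes(n), stringsAsFactors = FALSE)
}

#' Generate well-separated 7-nt barcodes
#'
#' Deterministic greedy construction (internal fixed seed) of barcodes with
#' pairwise Hamming distance >= 3, so single-mismatch demultiplexing is
#' unambiguous.
#'
#' @param n number of barcodes (up to 48).
#' @return character vector of 7-nt barcodes.
#' @export
default_barcodes <- function(n) {
  stopifnot(n <= 48)
  with_seed(20120817, {
    out <- character(0)
    while (length(out) < n) {
      cand <- .rand_dna(7L)
      if (all(vapply(out, function(b) .hamming(b, cand) >= 3L, logical(1))))
        out <- c(out, cand)
    }
    out
  })
}

.gc_penalty <- function(gc, alpha) pmax(0, 1 - alpha * (gc - 0.5)^2)

.apply_errors <- function(seq, error_rate) {
  s <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(s)) < error_rate)
  if (length(hit))
    s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(DNA_BASES, b), 1), character(1))
  paste(s, collapse = "")
}

#' Simulate a capture experiment for one species
#'
#' Fragments ~N(frag_mean, frag_sd) are drawn around each exon target and
#' captured with probability
#' `exp(-lambda * max(0, d_frag - d0)) * p_gc(gc)`, where `d_frag` is the
#' local divergence level of the fragment's locus from the probe-design
#' source (the planted per-contig rate): hybridization affinity is a
#' deterministic function of the locus's divergence, so the calibrated decay
#' (a 3-4x coverage drop near 9% divergence) is reproduced exactly rather
#' than washed out by per-fragment mismatch resampling.
#' Captured fragments yield 100-bp read pairs with per-base errors at the
#' configured rate and Phred-consistent constant qualities.  Off-target
#' pairs come from decoy contigs, duplicates re-emit captured pairs
#' verbatim, contaminant pairs come from the contaminant sequence, and each
#' pair carries its sample's barcode.  Truth labels (`true_sample`,
#' `target_id`, `is_dup`, `is_contam`, `on_target`) and truth alignments are
#' returned alongside.
#'
#' Male X dosage: fragments from X-chromosome genes in male samples are
#' drawn at half rate and from haplotype 1 only (haploid); all other loci
#' draw each fragment from a random haplotype.
#'
#' @param species a [evolve_species()] result.
#' @param space the [simulate_gene_space()] ancestor.
#' @param samples a [sim_samples()] sheet.
#' @param config the [sim_config()].
#' @param seed RNG seed.
#' @return list of class `"sim_reads"`: `pairs` (a [read_pairs()] table with
#'   truth columns), `aln` (truth [alignments()] for all non-contaminant
#'   reads), `contigs` (species gene contigs + decoys), `in_target_map`
#'   (truth spans of targets on the contigs, an `"in_target_map"`),
#'   `target_divergence` (realized per-target divergence), `samples`.
#' @export
simulate_capture_reads <- function(species, space, samples, config,
                                   seed = config$seed + 1L) {
  stopifnot(inherits(species, "sim_species"), inherits(space, "gene_space"),
            inherits(config, "sim_config"))
  et <- space$exon_targets
  if (nrow(et) == 0) stop("simulate_capture_reads: no targets")
  rl <- config$read_len
  with_seed(seed, {
    decoys <- stats::setNames(
      vapply(seq_len(config$n_decoys), function(i) .rand_dna(config$decoy_len),
             character(1)),
      sprintf("decoy%03d", seq_len(config$n_decoys)))
    contigs <- c(species$genomes, decoys)
    pair_rows <- list(); aln_rows <- list()
    serial <- 0L
    new_id <- function() {
      serial <<- serial + 1L
      sprintf("p%06d", serial)
    }
    emit <- function(sample_id, barcode, contig_id, fstart, flen, hap,
                     target_id, on_target) {
      src <- if (hap == 2L) species$hap2[[contig_id]] else
        contigs[[contig_id]]
      frag <- substr(src, fstart + 1L, fstart + flen)
      fwd1 <- .apply_errors(substr(frag, 1L, rl), config$error_rate)
      fwd2 <- .apply_errors(substr(frag, flen - rl + 1L, flen),
                            config$error_rate)
      q <- strrep(qual_encode(round(phred_from_error(config$error_rate))), rl)
      id <- new_id()
      pair_rows[[length(pair_rows) + 1L]] <<- data.frame(
        pair_id = id, bases1 = fwd1, quals1 = q,
        bases2 = revcomp(fwd2), quals2 = q, barcode = barcode,
        sample_id = NA_character_, true_sample = sample_id,
        target_id = if (is.na(target_id)) NA_character_ else target_id,
        is_dup = FALSE, is_contam = FALSE, on_target = on_target,
        stringsAsFactors = FALSE)
      aln_rows[[length(aln_rows) + 1L]] <<- data.frame(
        read_id = c(paste0(id, "/1"), paste0(id, "/2")),
        sample_id = sample_id, contig_id = contig_id,
        pos = c(fstart, fstart + flen - rl), bases = c(fwd1, fwd2),
        quals = q, unique = TRUE, is_dup = FALSE, stringsAsFactors = FALSE)
      id
    }
    mut_by_contig <- split(species$mutations$pos, species$mutations$contig_id)
    for (si in seq_len(nrow(samples))) {
      samp <- samples[si, ]
      for (ti in seq_len(nrow(et))) {
        cid <- et$contig_id[ti]
        haploid <- et$chrom[ti] == "X" && samp$sex == "M"
        rate <- config$fragments_per_target * if (haploid) 0.5 else 1
        n_frag <- stats::rpois(1, rate)
        if (n_frag == 0) next
        L <- nchar(contigs[[cid]])
        for (f in seq_len(n_frag)) {
          flen <- round(stats::rnorm(1, config$frag_mean, config$frag_sd))
          flen <- max(rl, min(500L, flen))
          center <- round(stats::runif(1, et$start[ti], et$end[ti]))
          fstart <- max(0L, min(L - flen, center - flen %/% 2L))
          d_frag <- species$div_rates[[cid]]
          gc <- gc_fraction(substr(contigs[[cid]], fstart + 1L,
                                   fstart + flen))
          p <- exp(-config$capture_lambda * max(0, d_frag - config$capture_d0)) *
            .gc_penalty(gc, config$gc_alpha)
          if (stats::runif(1) > p) next
          hap <- if (haploid) 1L else sample(1:2, 1)
          emit(samp$sample_id, samp$barcode, cid, fstart, flen, hap,
               et$target_id[ti], TRUE)
        }
      }
    }
    n_on <- length(pair_rows)
    # off-target pairs from decoys
    n_off <- round(n_on * config$offtarget_fraction /
                     (1 - config$offtarget_fraction))
    for (k in seq_len(n_off)) {
      samp <- samples[sample.int(nrow(samples), 1), ]
      cid <- sample(names(decoys), 1)
      flen <- max(rl, min(500L, round(stats::rnorm(1, config$frag_mean,
                                                   config$frag_sd))))
      fstart <- sample.int(nchar(contigs[[cid]]) - flen + 1L, 1) - 1L
      emit(samp$sample_id, samp$barcode, cid, fstart, flen, 1L,
           NA_character_, FALSE)
    }
    pairs <- do.call(rbind, pair_rows)
    aln <- do.call(rbind, aln_rows)
    # duplicates: re-emit existing pairs verbatim
    n_dup <- round(nrow(pairs) * config$duplicate_fraction /
                     (1 - config$duplicate_fraction))
    if (n_dup > 0) {
      src <- pairs[sample.int(nrow(pairs), n_dup, replace = TRUE), ,
                   drop = FALSE]
      src$is_dup <- TRUE
      orig <- src$pair_id
      src$pair_id <- vapply(seq_len(n_dup), function(i) new_id(), character(1))
      src$duplicate_of <- orig
      pairs$duplicate_of <- NA_character_
      pairs <- rbind(pairs, src)
    } else {
      pairs$duplicate_of <- NA_character_
    }
    # contaminant pairs
    n_con <- round(nrow(pairs) * config$contaminant_fraction /
                     (1 - config$contaminant_fraction))
    if (n_con > 0) {
      con_rows <- lapply(seq_len(n_con), function(k) {
        samp <- samples[sample.int(nrow(samples), 1), ]
        flen <- max(rl, min(500L, round(stats::rnorm(1, config$frag_mean,
                                                     config$frag_sd))))
        fstart <- sample.int(nchar(space$contaminant[[1]]) - flen + 1L, 1) - 1L
        frag <- substr(space$contaminant[[1]], fstart + 1L, fstart + flen)
        q <- strrep(qual_encode(round(phred_from_error(config$error_rate))), rl)
        data.frame(pair_id = new_id(),
                   bases1 = .apply_errors(substr(frag, 1L, rl),
                                          config$error_rate),
                   quals1 = q,
                   bases2 = revcomp(.apply_errors(
                     substr(frag, flen - rl + 1L, flen), config$error_rate)),
                   quals2 = q, barcode = samp$barcode,
                   sample_id = NA_character_, true_sample = samp$sample_id,
                   target_id = NA_character_, is_dup = FALSE,
                   is_contam = TRUE, on_target = FALSE,
                   duplicate_of = NA_character_, stringsAsFactors = FALSE)
      })
      pairs <- rbind(pairs, do.call(rbind, con_rows))
    }
    rownames(pairs) <- NULL
    # truth in-target map + realized per-target divergence
    div <- vapply(seq_len(nrow(et)), function(ti) {
      mpos <- mut_by_contig[[et$contig_id[ti]]]
      if (is.null(mpos)) 0 else
        sum(mpos >= et$start[ti] & mpos < et$end[ti]) /
          (et$end[ti] - et$start[ti])
    }, numeric(1))
    map <- data.frame(
      target_id = et$target_id, contig_id = et$contig_id,
      c_start = et$start, c_end = et$end,
      identity = 1 - div, divergence = div,
      left_flank = et$start,
      right_flank = nchar(contigs[et$contig_id]) - et$end,
      stringsAsFactors = FALSE)
    rownames(map) <- NULL
    class(map) <- c("in_target_map", "data.frame")
    attr(map, "contigs") <- contigs
    structure(list(pairs = pairs, aln = aln, contigs = contigs,
                   in_target_map = map, target_divergence = div,
                   samples = samples),
              class = "sim_reads")
  })
}

#' Fragment contigs into an overlapping raw "assembly"
#'
#' Cuts each source contig into pieces of ~`piece` bp overlapping by
#' `overlap` bp, emulating redundant raw assemblies for merge testing.
#'
#' @param contigs named character vector.
#' @param piece,overlap piece length and overlap (bp).
#' @param label assembly label used in piece ids.
#' @return named character vector of pieces.
#' @export
fragment_assembly <- function(contigs, piece = 400L, overlap = 80L,
                              label = "raw") {
  out <- character(0)
  for (cid in names(contigs)) {
    L <- nchar(contigs[[cid]])
    starts <- unique(c(seq(0L, max(0L, L - piece), by = piece - overlap),
                       max(0L, L - piece)))
    for (k in seq_along(starts)) {
      out[sprintf("%s_%s_%d", label, cid, k)] <-
        substr(contigs[[cid]], starts[k] + 1L, min(L, starts[k] + piece))
    }
  }
  out
}

#' Simulate a per-target coverage matrix across samples
#'
#' Coverage-level model for X-linkage screening: per-target efficiency is
#' lognormal (median `mean_cov`, `sdlog` spread across targets); per-sample,
#' per-target coverage is the efficiency times multiplicative noise with
#' coefficient of variation `cv` (capture performance is highly reproducible
#' between libraries, so within-target noise is small).  Male samples
#' receive half dosage on X-linked targets.
#'
#' @param n_targets total targets; the first `n_x` are X-linked.
#' @param n_x number of X-linked targets.
#' @param samples a [sim_samples()] sheet (uses `sample_id`, `sex`).
#' @param mean_cov median per-target coverage.
#' @param sdlog between-target lognormal sdlog.
#' @param cv within-target, between-sample coefficient of variation.
#' @param seed RNG seed.
#' @return list with `cov` (matrix targets x samples), `truth` (logical
#'   vector: X-linked).
#' @export
simulate_coverage_matrix <- function(n_targets, n_x, samples, mean_cov = 10,
                                     sdlog = 0.7, cv = 0.07, seed = 1L) {
  stopifnot(n_x <= n_targets)
  with_seed(seed, {
    eff <- stats::rlnorm(n_targets, log(mean_cov), sdlog)
    is_x <- seq_len(n_targets) <= n_x
    noise <- matrix(stats::rnorm(n_targets * nrow(samples), 1, cv),
                    n_targets, nrow(samples))
    noise[noise < 0] <- 0
    cov <- eff * noise
    dosage <- matrix(1, n_targets, nrow(samples))
    dosage[is_x, samples$sex == "M"] <- 0.5
    cov <- cov * dosage
    dimnames(cov) <- list(sprintf("t%04d", seq_len(n_targets)),
                          samples$sample_id)
    list(cov = cov, truth = stats::setNames(is_x, rownames(cov)))
  })
}

#' Simulate haploid-locus alignments at a planted error rate
#'
#' A single haploid contig sequenced to `depth` with per-base errors at
#' `error_rate`; used to verify empirical error-rate estimation at scale
#' (e.g. 10 kb x 100X = 1e6 stacked bases).
#'
#' @param contig_len contig length.
#' @param depth mean read depth.
#' @param error_rate planted per-base error.
#' @param read_len read length.
#' @param seed RNG seed.
#' @return list with `contigs` and `aln` ([alignments()]).
#' @export
simulate_haploid_reads <- function(contig_len = 10000L, depth = 100,
                                   error_rate = 4e-4, read_len = 100L,
                                   seed = 1L) {
  with_seed(seed, {
    contig <- c(haploid = .rand_dna(contig_len))
    n_reads <- round(contig_len * depth / read_len)
    pos <- sample.int(contig_len - read_len + 1L, n_reads, replace = TRUE) - 1L
    q <- strrep(qual_encode(round(phred_from_error(error_rate))), read_len)
    bases <- vapply(pos, function(p)
      .apply_errors(substr(contig[[1]], p + 1L, p + read_len), error_rate),
      character(1))
    list(contigs = contig,
         aln = alignments(read_id = sprintf("r%06d", seq_len(n_reads)),
                          contig_id = "haploid", pos = pos, bases = bases,
                          quals = q, sample_id = "hap", unique = TRUE,
                          is_dup = FALSE))
  })
}
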