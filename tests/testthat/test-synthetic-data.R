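cfg <- sim_config(seed = 11, n_genes = 8)

test_that("gene space construction is deterministic and translatable", {
  s1 <- simulate_gene_space(cfg)
  s2 <- simulate_gene_space(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$transcripts, s2$transcripts)

  # n_genes with fixed exon counts gives the expected exon total
  s3 <- simulate_gene_space(sim_config(seed = 3, n_genes = 10,
                                       exons_per_gene = c(3L, 3L)))
  expect_equal(length(s3$ref_exons), 30L)

  # every CDS translates without internal stops
  for (tid in names(s1$transcripts)) {
    span <- s1$tx_cds_span[[tid]]
    cds <- substr(s1$transcripts[[tid]], span[1] + 1, span[2])
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    # transcript = spliced exons (+ UTRs); exons concatenate to the CDS
    refs <- s1$ref_exons[startsWith(names(s1$ref_exons), paste0(tid, "|"))]
    expect_equal(paste(refs, collapse = ""), cds)
  }

  # gene model features are non-overlapping and tile the contig
  m <- s1$models[s1$models$contig_id == names(s1$genomes)[1], ]
  m <- m[order(m$start), ]
  expect_true(all(m$start[-1] == m$end[-nrow(m)]))
  expect_equal(m$end[nrow(m)], nchar(s1$genomes[[1]]))

  expect_error(sim_config(seed = 1, exon_len = c(30, 50)), "exon_len")
})

test_that("species evolution plants divergence and heterozygosity", {
  space <- simulate_gene_space(cfg)
  L <- sum(nchar(space$genomes))

  sp0 <- evolve_species(space, 0, 0, seed = 5)
  expect_identical(sp0$genomes, space$genomes)

  sp <- evolve_species(space, 0.015, 0.002, seed = 5)
  d <- sp$realized_divergence
  expect_lt(abs(d - 0.015), 3 * sqrt(0.015 * 0.985 / L))
  # mutation list reproduces the species genome from the ancestor
  cid <- names(space$genomes)[1]
  anc <- strsplit(space$genomes[[cid]], "")[[1]]
  mut <- sp$mutations[sp$mutations$contig_id == cid, ]
  expect_equal(anc[mut$pos + 1], mut$from)
  anc[mut$pos + 1] <- mut$to
  expect_equal(paste(anc, collapse = ""), sp$genomes[[cid]])
  # heterozygous sites differ between haplotypes at the planted rate
  n_het <- nrow(sp$het_sites)
  expect_lt(abs(n_het - 0.002 * L), 3 * sqrt(0.002 * L))

  # per-contig divergence vector is honoured
  dv <- stats::setNames(rep(c(0, 0.1), length.out = length(space$genomes)),
                        names(space$genomes))
  spv <- evolve_species(space, dv, 0, seed = 6)
  flat <- names(dv)[dv == 0]
  expect_identical(spv$genomes[flat], space$genomes[flat])
  expect_false(any(spv$mutations$contig_id %in% flat))
})

test_that("read simulation is deterministic with faithful truth labels", {
  space <- simulate_gene_space(cfg)
  sp <- evolve_species(space, 0.006, 0.002, seed = 7)
  samples <- sim_samples(2, "sp")
  r1 <- simulate_capture_reads(sp, space, samples, cfg, seed = 13)
  r2 <- simulate_capture_reads(sp, space, samples, cfg, seed = 13)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$aln, r2$aln)

  # planted duplicate and contaminant fractions are recovered exactly from labels
  n <- nrow(r1$pairs)
  n_dup <- sum(r1$pairs$is_dup)
  n_cont <- sum(r1$pairs$is_contam)
  n_pre_dup <- n - n_dup - n_cont
  expect_equal(n_dup, round(n_pre_dup * cfg$duplicate_fraction /
                              (1 - cfg$duplicate_fraction)))
  expect_equal(n_cont, round((n_pre_dup + n_dup) * cfg$contaminant_fraction /
                               (1 - cfg$contaminant_fraction)))
  # duplicates are byte-identical to their originals
  dups <- r1$pairs[r1$pairs$is_dup, ]
  orig <- r1$pairs[match(dups$duplicate_of, r1$pairs$pair_id), ]
  expect_equal(dups$bases1, orig$bases1)
  expect_equal(dups$bases2, orig$bases2)

  # dedup recovers the planted duplicates
  dd <- remove_exact_duplicates(read_pairs(
    r1$pairs$pair_id, r1$pairs$bases1, r1$pairs$quals1, r1$pairs$bases2,
    r1$pairs$quals2, barcode = r1$pairs$barcode))
  expect_gte(dd$n_duplicates, n_dup)

  # every truth alignment lies within its contig
  spans_ok <- r1$aln$pos >= 0 &
    r1$aln$pos + nchar(r1$aln$bases) <=
      nchar(r1$contigs)[match(r1$aln$contig_id, names(r1$contigs))]
  expect_true(all(spans_ok))

  # truth SAM fed back through capture_eval: full sensitivity for targets
  # with emitted fragments
  pile <- pileup(r1$aln, r1$contigs)
  seen <- unique(r1$pairs$target_id[!is.na(r1$pairs$target_id)])
  map <- r1$in_target_map
  expect_equal(sensitivity(map[map$target_id %in% seen, ], pile), 100)

  # demultiplexing by the attached barcodes recovers the true samples
  dm <- demultiplex(read_pairs(r1$pairs$pair_id, r1$pairs$bases1,
                               r1$pairs$quals1, r1$pairs$bases2,
                               r1$pairs$quals2, barcode = r1$pairs$barcode),
                    samples[, c("sample_id", "barcode")])
  expect_equal(nrow(dm$unassigned), 0L)
  expect_equal(dm$assigned$sample_id, r1$pairs$true_sample)
})

test_that("barcode sets are mutually distant", {
  bcs <- default_barcodes(20)
  expect_equal(length(unique(bcs)), 20L)
  expect_true(all(nchar(bcs) == 7L))
  d <- outer(bcs, bcs, Vectorize(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])))
  expect_true(all(d[upper.tri(d)] >= 3))
})

test_that("coverage matrix simulation plants X dosage", {
  samples <- sim_samples(10, "sp")
  m <- simulate_coverage_matrix(100, 20, samples, seed = 3)
  expect_equal(dim(m$cov), c(100L, 10L))
  f <- samples$sex == "F"
  ratio <- rowMeans(m$cov[, f]) / rowMeans(m$cov[, !f])
  expect_gt(mean(ratio[m$truth]), 1.7)
  expect_lt(mean(abs(ratio[!m$truth] - 1)), 0.2)
})
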