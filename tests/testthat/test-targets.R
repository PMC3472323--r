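# fixtures built from the simulator's ground-truth gene space
space <- simulate_gene_space(sim_config(seed = 101, n_genes = 6))

test_that("transcript annotation finds the right protein and completeness", {
  tid <- names(space$transcripts)[1]
  ann <- annotate_transcript(space$transcripts[tid], space$proteins)
  expect_false(is.null(ann))
  expect_equal(ann$best_protein_id, tid)  # proteins share gene ids
  expect_equal(ann$completeness, "full_cds")
  expect_equal(ann$strand, "+")
  # annotated CDS span matches the construction
  expect_equal(ann$cds_span[1], space$tx_cds_span[[tid]][1], tolerance = 0)

  # truncation before the protein start, 3' flank kept
  tx <- space$transcripts[[tid]]
  cds <- space$tx_cds_span[[tid]]
  cut <- substr(tx, cds[1] + floor((cds[2] - cds[1]) / 2), nchar(tx))
  names(cut) <- "trunc"
  ann2 <- annotate_transcript(c(trunc = cut), space$proteins)
  expect_equal(ann2$completeness, "partial_cds_3utr")

  # reverse-complemented contig annotates on the minus strand
  rc <- revcomp(space$transcripts[tid])
  ann3 <- annotate_transcript(c(rc = unname(rc)), space$proteins)
  expect_equal(ann3$strand, "-")
  expect_equal(ann3$best_protein_id, tid)

  # random sequence: no hit
  set.seed(1)
  expect_null(annotate_transcript(c(r = random_dna(400)), space$proteins))
})

test_that("premature stop detection distinguishes terminal stops", {
  # terminal stop only
  ann <- structure(list(strand = "+", cds_span = c(0L, 6L)),
                   class = "transcript_annotation")
  expect_false(detect_premature_stop(c(x = "ATGTAA"), ann))
  ann2 <- structure(list(strand = "+", cds_span = c(0L, 12L)),
                    class = "transcript_annotation")
  expect_true(detect_premature_stop(c(x = "ATGTAATTTTAA"), ann2))
  expect_error(detect_premature_stop(
    c(x = "AT"), structure(list(strand = "+", cds_span = c(0L, 2L)),
                           class = "transcript_annotation")), "shorter")

  # simulator transcripts carry no internal stop by construction
  for (tid in names(space$transcripts)[1:3]) {
    ann <- annotate_transcript(space$transcripts[tid], space$proteins)
    expect_false(detect_premature_stop(space$transcripts[tid], ann))
  }

  # injecting an internal stop flips the flag
  tid <- names(space$transcripts)[1]
  tx <- space$transcripts[[tid]]
  cds <- space$tx_cds_span[[tid]]
  mid_codon <- cds[1] + 3 * floor((cds[2] - cds[1]) / 6)
  substr(tx, mid_codon + 1, mid_codon + 3) <- "TAA"
  ann <- annotate_transcript(c(mut = tx), space$proteins)
  expect_true(detect_premature_stop(c(mut = tx), ann))
})

test_that("chimera detection requires two genes on disjoint spans", {
  t1 <- names(space$transcripts)[1]; t2 <- names(space$transcripts)[2]
  expect_false(detect_chimeric_contig(space$transcripts[t1], space$proteins))
  chim <- paste0(space$transcripts[[t1]], space$transcripts[[t2]])
  expect_true(detect_chimeric_contig(c(chim = chim), space$proteins))
  # tandem repeat of one gene is not chimeric
  tand <- paste0(space$transcripts[[t1]], space$transcripts[[t1]])
  expect_false(detect_chimeric_contig(c(tand = tand), space$proteins))
})

test_that("exon boundary transfer recovers construction coordinates", {
  set.seed(21)
  ex <- stats::setNames(vapply(c(150, 150, 150), random_dna, character(1)),
                        c("g|exon_1", "g|exon_2", "g|exon_3"))
  tx <- c(tx1 = paste(ex, collapse = ""))
  got <- transfer_exon_boundaries(tx, ex)
  expect_equal(got$start, c(0L, 150L, 300L))
  expect_equal(got$end, c(150L, 300L, 450L))

  # 1% point mutations leave the projected boundaries unchanged
  mut <- c(tx1 = mutate_seq(tx[[1]], 0.01))
  got2 <- transfer_exon_boundaries(mut, ex)
  expect_equal(got2$start, c(0L, 150L, 300L))
  expect_equal(got2$end, c(150L, 300L, 450L))

  # missing first exon: two placements, first exon unplaced
  part <- c(tx1 = substr(tx[[1]], 151, 450))
  got3 <- transfer_exon_boundaries(part, ex)
  expect_equal(got3$exon_index, c(2L, 3L))
  expect_equal(got3$start, c(0L, 150L))
})

test_that("boundary transfer on simulated genes is near-exact at 1% divergence", {
  sp <- simulate_gene_space(sim_config(seed = 303, n_genes = 50,
                                       exons_per_gene = c(2L, 4L)))
  set.seed(303)
  n_bound <- 0L; n_exact <- 0L
  for (tid in names(sp$transcripts)) {
    cds <- sp$tx_cds_span[[tid]]
    refs <- sp$ref_exons[startsWith(names(sp$ref_exons), paste0(tid, "|"))]
    truth_start <- cds[1] + cumsum(c(0L, nchar(refs)[-length(refs)]))
    truth_end <- cds[1] + cumsum(nchar(refs))
    mut <- c(mutate_seq(sp$transcripts[[tid]], 0.01))
    names(mut) <- tid
    got <- transfer_exon_boundaries(mut, refs)
    m <- match(got$exon_index, seq_along(refs))
    n_bound <- n_bound + 2L * length(refs)
    n_exact <- n_exact + sum(got$start == truth_start[m]) +
      sum(got$end == truth_end[m])
  }
  expect_gte(n_exact / n_bound, 0.95)
})

test_that("target set building filters, dedupes and counts", {
  set.seed(31)
  mk <- function(id, len) data.frame(
    target_id = id, source_seq_id = "src", start = 0L, end = len,
    sequence = random_dna(len), target_class = "nuclear_exon",
    stringsAsFactors = FALSE)
  exons <- rbind(mk("e150", 150), mk("e200", 200), mk("e250", 250))
  ts <- build_target_set(exon_targets = exons, min_length = 200)
  expect_equal(nrow(ts$targets), 2L)  # >= threshold retained
  expect_equal(ts$n_dropped_short, 1L)

  # extra classes pass unfiltered; duplicates by sequence collapse
  dup <- mk("e200b", 200); dup$sequence <- exons$sequence[2]
  mito <- data.frame(target_id = "mt", sequence = random_dna(100),
                     target_class = "mito", stringsAsFactors = FALSE)
  ts2 <- build_target_set(exon_targets = rbind(exons, dup),
                          extra_targets = mito)
  expect_equal(ts2$n_dropped_dup, 1L)
  expect_true("mt" %in% ts2$targets$target_id)  # 100 bp mito kept
  expect_equal(nrow(ts2$targets),
               nrow(rbind(exons, dup)) + 1L - ts2$n_dropped_short -
                 ts2$n_dropped_dup)

  # duplicate ids are an input error
  expect_error(build_target_set(exon_targets = rbind(exons, exons[2, ])),
               "duplicate target_id")

  # mito-only set works
  ts3 <- build_target_set(extra_targets = mito)
  expect_equal(nrow(ts3$targets), 1L)
})

test_that("completeness classes partition annotated transcripts", {
  qc <- transcriptome_qc(space$transcripts, space$proteins)
  ann <- qc[qc$annotated, ]
  expect_equal(nrow(ann), nrow(qc))  # all simulator transcripts annotate
  expect_true(all(ann$completeness %in%
                    c("full_cds", "partial_cds_3utr", "partial_cds_5utr",
                      "partial_cds_only")))
  expect_false(any(ann$premature_stop))
  expect_false(any(ann$chimeric))
})
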