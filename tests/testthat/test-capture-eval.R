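stack_fixture <- function() {
  # 3 reads hand-stacked on a 10-bp contig, one staggered
  contigs <- c(c1 = "ACGTACGTAC")
  aln <- alignments(read_id = c("r1", "r2", "r3"), contig_id = "c1",
                    pos = c(0L, 0L, 4L),
                    bases = c("ACGTACGTAC", "ACGTACGTAC", "ACGTAC"),
                    quals = c(strrep("I", 10), strrep("I", 10), strrep("I", 6)),
                    sample_id = "s1")
  list(contigs = contigs, aln = aln)
}

test_that("pileup stacks base counts and emits zero-depth positions", {
  f <- stack_fixture()
  p <- pileup(f$aln, f$contigs)
  expect_equal(nrow(p), 10L)
  expect_equal(p$depth, c(2, 2, 2, 2, 3, 3, 3, 3, 3, 3))
  expect_equal(p$A[1], 2L)
  expect_equal(p$A[5], 3L)  # all three reads agree at position 4

  # a disagreeing read shows up in the base counts
  aln2 <- f$aln
  aln2$bases[3] <- "TCGTAC"
  p2 <- pileup(aln2, f$contigs)
  expect_equal(p2$T[5], 1L)
  expect_equal(p2$A[5], 2L)

  # duplicates and non-unique reads are excluded
  aln3 <- rbind(f$aln, alignments("d1", "c1", 0L, "ACGTACGTAC",
                                  strrep("I", 10), is_dup = TRUE))
  expect_equal(pileup(aln3, f$contigs)$depth[1], 2)

  # no reads: all zeros
  p0 <- pileup(f$aln[0, ], f$contigs)
  expect_true(all(p0$depth == 0))

  # out-of-bounds alignment is malformed input
  bad <- alignments("x", "c1", 8L, "ACGTA", strrep("I", 5))
  expect_error(pileup(bad, f$contigs), "beyond contig end")
})

test_that("SAM round-trips through the minimal reader/writer", {
  f <- stack_fixture()
  aln <- f$aln
  aln$unique[2] <- FALSE
  aln$is_dup[3] <- TRUE
  tmp <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, f$contigs, tmp)
  back <- read_sam(tmp)
  expect_equal(back$read_id, aln$read_id)
  expect_equal(back$pos, aln$pos)
  expect_equal(back$bases, aln$bases)
  expect_equal(back$unique, aln$unique)
  expect_equal(back$is_dup, aln$is_dup)
  expect_equal(back$sample_id, aln$sample_id)
  # soft-clipped CIGAR reduces to the aligned span
  lines <- readLines(tmp)
  lines <- c(lines, "sc\t0\tc1\t3\t60\t2S4M\t*\t0\t0\tGGACGT\tIIIIII")
  writeLines(lines, tmp)
  back2 <- read_sam(tmp)
  expect_equal(back2$bases[back2$read_id == "sc"], "ACGT")
  expect_equal(back2$pos[back2$read_id == "sc"], 2L)
})

test_that("sensitivity and specificity follow their definitions", {
  f <- stack_fixture()
  p <- pileup(f$aln, f$contigs)
  map <- data.frame(target_id = "t1", contig_id = "c1", c_start = 0L,
                    c_end = 10L, stringsAsFactors = FALSE)
  expect_equal(sensitivity(map, p), 100)
  # 5 designed targets, one covered
  expect_equal(sensitivity(map, p, all_targets = paste0("t", 1:5)), 20)
  expect_error(sensitivity(map, p, all_targets = character(0)), "zero targets")

  # specificity: 25 of 100 reads on target
  contigs <- c(on = strrep("A", 200), off = strrep("A", 200))
  aln <- alignments(read_id = sprintf("r%03d", 1:100),
                    contig_id = rep(c("on", "off"), c(25, 75)),
                    pos = 0L, bases = strrep("A", 50), quals = strrep("I", 50))
  map2 <- data.frame(target_id = "t1", contig_id = "on", c_start = 0L,
                     c_end = 200L, stringsAsFactors = FALSE)
  expect_equal(specificity(aln, map2), 25)
  expect_true(is.na(specificity(aln[0, ], map2)))
  # invariant under read order permutation
  set.seed(2)
  expect_equal(specificity(aln[sample(100), ], map2), 25)
})

test_that("coverage summary applies the mixed threshold convention", {
  # per-target mean depths 0.5, 6, 12 -> >=1X: 2/3, >5X: 2/3, >10X: 1/3
  contigs <- c(a = strrep("A", 100), b = strrep("A", 100),
               c = strrep("A", 100))
  mk <- function(contig, n) if (n == 0) NULL else
    alignments(sprintf("%s_%d", contig, 1:n), contig, 0L,
               strrep("A", 50), strrep("I", 50))
  aln <- rbind(mk("a", 1), mk("b", 12), mk("c", 24))
  p <- pileup(aln, contigs)
  map <- data.frame(target_id = c("ta", "tb", "tc"),
                    contig_id = c("a", "b", "c"), c_start = 0L, c_end = 100L,
                    stringsAsFactors = FALSE)
  cs <- coverage_summary(p, map)
  expect_equal(unname(cs$per_target$mean_cov), c(0.5, 6, 12))
  expect_equal(unname(cs$fractions), c(2 / 3, 2 / 3, 1 / 3))
  # threshold fractions are non-increasing in the threshold
  expect_true(all(diff(cs$fractions) <= 0))
})

test_that("edge profile exposes coverage decay toward target ends", {
  # uniform coverage: flat profile
  contigs <- c(c1 = strrep("A", 300))
  aln <- alignments(sprintf("r%d", 1:10), "c1", 0L, strrep("A", 300),
                    strrep("I", 300))
  map <- data.frame(target_id = "t", contig_id = "c1", c_start = 0L,
                    c_end = 300L, stringsAsFactors = FALSE)
  ep <- edge_profile(pileup(aln, contigs), map)
  expect_true(all(ep$mean_cov == 10))
  expect_equal(ep$bin, 0:7)  # distances up to the 150-bp midpoint

  # simulated fragments without edge densification: first bin < centre bin
  ex <- capture_eval_experiment(seed = 5, n_genes = 10, n_samples = 1)
  ep2 <- edge_profile(ex$pile, ex$map, min_len = 201, max_len = 600)
  expect_lt(ep2$mean_cov[1], ep2$mean_cov[nrow(ep2)])

  # a single 201-bp target populates bins 0-5 (centre included)
  map201 <- data.frame(target_id = "t", contig_id = "c1", c_start = 0L,
                       c_end = 201L, stringsAsFactors = FALSE)
  ep3 <- edge_profile(pileup(aln, contigs), map201)
  expect_equal(max(ep3$bin), 5L)
})

test_that("GC-coverage binning reflects a planted quadratic penalty", {
  gc <- seq(0.1, 0.9, by = 0.02)
  cov <- 10 * pmax(0, 1 - 2 * (gc - 0.5)^2)
  tab <- gc_coverage_relation(gc, cov)
  mid <- tab$mean_cov[tab$gc_lo == 0.50]
  expect_gt(mid, tab$mean_cov[1])
  expect_gt(mid, tab$mean_cov[nrow(tab)])
  # single-bin degenerate case
  tab1 <- gc_coverage_relation(rep(0.52, 5), rep(10, 5))
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$mean_cov, 10)
})

test_that("reproducibility correlates shared-target log coverage", {
  set.seed(8)
  expect_equal(reproducibility(c(1, 5, 20, 100), c(1, 5, 20, 100)), 1.0)
  a <- rlnorm(1000, 2, 1); b <- rlnorm(1000, 2, 1)
  expect_lt(abs(reproducibility(a, b)), 0.1)
  eff <- rlnorm(500, 2, 1)
  r <- reproducibility(eff * rlnorm(500, 0, 0.2), eff * rlnorm(500, 0, 0.2))
  expect_gt(r, 0.8)
  expect_true(is.na(reproducibility(c(2, 2, 2), c(1, 5, 9))))
})

test_that("divergence-coverage binning flags weak bins", {
  div <- c(0, 0.001, 0.002, 0.085)
  cov <- c(10, 11, 9, 3)
  tab <- divergence_coverage(div, cov)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$mean_cov[1], 10)
  expect_true(tab$low_support[2])  # single target in the 8-9% bin
})

test_that("haploid error rate recovers planted rates within binomial noise", {
  # error-free reads: rate 0
  f <- stack_fixture()
  aln <- rbind(f$aln, f$aln, f$aln, f$aln)  # depth >= 10 floor
  aln$read_id <- sprintf("r%d", seq_len(nrow(aln)))
  er0 <- haploid_error_rate(pileup(aln, f$contigs), min_depth = 8)
  expect_equal(er0$rate, 0)

  # planted rates over >= 10 seeds stay within 3 binomial SDs
  for (seed in 1:10) {
    e <- 2e-3  # higher rate so a small fixture has power
    sim <- simulate_haploid_reads(contig_len = 2000, depth = 50,
                                  error_rate = e, seed = seed)
    er <- haploid_error_rate(pileup(sim$aln, sim$contigs))
    sd3 <- 3 * sqrt(e * (1 - e) / er$aligned_bases)
    expect_lt(abs(er$rate - e), sd3 + e * 0.15)
  }
  expect_error(haploid_error_rate(pileup(f$aln[0, ], f$contigs)),
               "zero aligned")
})

test_that("X-linkage screening selects half-dosage targets", {
  cov <- matrix(c(20, 10, 10, 10), 2, 2,
                dimnames = list(c("t1", "t2"), c("f1", "m1")))
  sexes <- c(f1 = "F", m1 = "M")
  got <- identify_x_linked(cov, sexes)
  expect_true(got$x_linked[got$target_id == "t1"])   # ratio 2.0
  expect_false(got$x_linked[got$target_id == "t2"])  # ratio 1.0
  cov2 <- rbind(cov, t3 = c(5, 0))
  got2 <- identify_x_linked(cov2, sexes)
  expect_true(got2$skipped[got2$target_id == "t3"])
  expect_error(identify_x_linked(cov[, 1, drop = FALSE], sexes), "male")
})

test_that("SRY check flags contaminated females and failed males", {
  sexes <- c(f1 = "F", f2 = "F", m1 = "M", m2 = "M")
  got <- sry_check(c(f1 = 0L, f2 = 6L, m1 = 40L, m2 = 0L), sexes)
  expect_equal(got$status,
               c("pass", "possible_contamination", "pass",
                 "possible_capture_failure"))
})
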