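test_that("site quality follows the binomial error model", {
  # 50/50 split at depth 100, Q30: overwhelming evidence of a variant
  expect_gt(site_quality(100, 50, 30), 30)
  # one discordant base at depth 30, Q20: P(X>=1) = 1-0.99^30 ~ 0.26
  q <- site_quality(30, 29, 20)
  expect_lt(q, 30)
  expect_equal(q, -10 * log10(1 - pbinom(0, 30, 0.01)), tolerance = 1e-10)
  # no discordant bases: quality 0; cap at 2000
  expect_equal(site_quality(100, 100, 30), 0)
  expect_lte(site_quality(5000, 2500, 40), 2000)
})

test_that("candidate calling enforces the depth window and quality floor", {
  mk_pile <- function(depth, a, c_) {
    structure(data.frame(contig_id = "c", pos = 0L, depth = depth, A = a,
                         C = c_, G = 0L, T = 0L, N = 0L,
                         qual_sum = depth * 30, stringsAsFactors = FALSE),
              class = c("pileup", "data.frame"))
  }
  expect_equal(nrow(call_sites(mk_pile(19, 10, 9))), 0L)    # below floor
  expect_equal(nrow(call_sites(mk_pile(100, 50, 50))), 1L)
  expect_equal(nrow(call_sites(mk_pile(30, 29, 1))), 0L)    # weak singleton
  expect_equal(nrow(call_sites(mk_pile(6000, 3000, 3000))), 0L)  # above ceiling
  # raising min_depth never increases the number of called sites
  p <- mk_pile(c(25, 40, 100), c(12, 20, 60), c(13, 20, 40))
  n20 <- nrow(call_sites(p, min_depth = 20))
  n30 <- nrow(call_sites(p, min_depth = 30))
  n50 <- nrow(call_sites(p, min_depth = 50))
  expect_true(n20 >= n30 && n30 >= n50)
})

test_that("zygosity classification separates fixed from polymorphic", {
  # all reads carry the alternate allele: fixed difference
  z <- classify_zygosity(c(A = 0, C = 40, G = 0, T = 0), "A")
  expect_equal(z$status, "fixed")
  expect_equal(z$alt, "C")
  # 50/50: polymorphic
  z2 <- classify_zygosity(c(A = 20, C = 20, G = 0, T = 0), "A")
  expect_equal(z2$status, "polymorphic")
  expect_equal(z2$alt, "C")
  # 95% ref / 5% alt at depth 40: below the 20% minor fraction -> invariant
  z3 <- classify_zygosity(c(A = 38, C = 2, G = 0, T = 0), "A")
  expect_equal(z3$status, "invariant")
})

test_that("functional classification matches the exhaustive codon oracle", {
  expect_equal(classify_function("GAT", 2L, "T", "C",
                                 gene_model("c", "cds", 0L, 3L, 0L)),
               "synonymous")    # GAT -> GAC, Asp -> Asp
  expect_equal(classify_function("GAT", 1L, "A", "C",
                                 gene_model("c", "cds", 0L, 3L, 0L)),
               "non_synonymous")  # GAT -> GCT, Asp -> Ala

  # every single-base change of every codon (576 cases) vs direct translation
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  model <- gene_model("c", "cds", 0L, 3L, 0L)
  for (codon in codons) {
    for (pos in 1:3) {
      for (alt in setdiff(bases, substr(codon, pos, pos))) {
        got <- classify_function(codon, pos - 1L, substr(codon, pos, pos),
                                 alt, model)
        alt_codon <- codon
        substr(alt_codon, pos, pos) <- alt
        want <- oracle_codon_effect(codon, pos, alt)
        expect_equal(got, want, info = sprintf("%s pos %d -> %s", codon, pos,
                                               alt))
      }
    }
  }

  # intron / UTR / unannotated positions
  m <- gene_model("c", c("utr5", "cds", "intron"), c(0L, 10L, 22L),
                  c(10L, 22L, 40L), c(NA, 0L, NA))
  seqc <- strrep("GAT", 14)
  expect_equal(classify_function(seqc, 3L, "G", "A", m), "utr")
  expect_equal(classify_function(seqc, 25L, "G", "A", m), "intron")
  expect_equal(classify_function(seqc, 41L, "G", "A", m), "unclassified")

  # minus-strand CDS classifies through the reverse complement
  m2 <- gene_model("c", "cds", 0L, 3L, 0L, strand = "-")
  # contig ATC; minus strand reads GAT; third codon position is contig pos 0
  expect_equal(classify_function("ATC", 0L, "A", "G", m2), "synonymous")
})

test_that("SNP summaries cross-tabulate with conserved totals", {
  s <- snp_summary_counts(
    fixed = c(synonymous = 10, non_synonymous = 4, intron = 5, utr = 1),
    polymorphic = c(synonymous = 6, non_synonymous = 2, intron = 1, utr = 1))
  expect_equal(unname(s$fixed[["total"]]), 20)
  expect_equal(unname(s$polymorphic[["total"]]), 10)
  expect_equal(unname(s$total_difference[["total"]]), 30)
  classes <- c("synonymous", "non_synonymous", "intron", "utr")
  expect_equal(sum(s$total_difference[classes]), 30)
  expect_equal(unname(s$percent[["synonymous"]]), round(100 * 16 / 30, 1))

  # record-level summary matches the counts route
  rec <- data.frame(
    species = "sp",
    status = c("fixed", "fixed", "polymorphic"),
    func_class = c("synonymous", "intron", "non_synonymous"),
    stringsAsFactors = FALSE)
  ss <- summarize_snps(rec)[["sp"]]
  expect_equal(unname(ss$fixed[["synonymous"]]), 1)
  expect_equal(unname(ss$total_difference[["total"]]), 3)

  empty <- snp_summary_counts()
  expect_equal(unname(empty$total_difference[["total"]]), 0)
})

test_that("end-to-end calling recovers planted fixed and polymorphic sites", {
  set.seed(90)
  ref <- c(ctg = random_dna(3000))
  model <- gene_model("ctg", "cds", 0L, 3000L, 0L)
  seq_sp <- ref[["ctg"]]
  # plant 20 fixed differences at distinct codon positions
  fixed_pos <- sort(sample(seq(3, 2997, by = 3), 20))
  for (p in fixed_pos) {
    b <- substr(seq_sp, p + 1, p + 1)
    substr(seq_sp, p + 1, p + 1) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  # plant 10 polymorphic sites: half the reads carry the alternate
  poly_pos <- sort(sample(setdiff(seq(4, 2998, by = 3), fixed_pos + 1), 10))
  seq_alt <- seq_sp
  for (p in poly_pos) {
    b <- substr(seq_alt, p + 1, p + 1)
    substr(seq_alt, p + 1, p + 1) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  reads <- list()
  for (i in 1:300) {
    st <- sample(2900, 1) - 1L
    src <- if (i %% 2 == 0) seq_sp else seq_alt
    reads[[i]] <- data.frame(read_id = paste0("r", i), contig_id = "ctg",
                             pos = st, bases = substr(src, st + 1, st + 100),
                             stringsAsFactors = FALSE)
  }
  aln <- do.call(rbind, reads)
  aln$quals <- strrep(qual_encode(34L), 100)
  aln$sample_id <- "sp"; aln$unique <- TRUE; aln$is_dup <- FALSE
  pile <- pileup(aln, ref)
  snps <- call_snps(pile, ref, model, species = "sp", min_depth = 5L)
  called_fixed <- snps$pos[snps$status == "fixed"]
  called_poly <- snps$pos[snps$status == "polymorphic"]
  # positions covered at depth >= 5 should be recovered
  expect_gte(length(intersect(called_fixed, fixed_pos)), 17)
  expect_gte(length(intersect(called_poly, poly_pos)), 8)
  expect_true(all(snps$func_class %in% c("synonymous", "non_synonymous")))
})

test_that("shared orthologs intersect in-target maps", {
  m1 <- data.frame(target_id = c("a", "b", "c"))
  m2 <- data.frame(target_id = c("b", "c", "d"))
  m3 <- data.frame(target_id = c("c", "b"))
  expect_setequal(shared_orthologs(list(m1, m2, m3)), c("b", "c"))
  expect_error(shared_orthologs(list(m1)), ">= 2")
})

test_that("VCF output carries status and class in INFO", {
  rec <- data.frame(contig_id = "c1", pos = 9L, ref = "A", alt = "G",
                    species = "sp", status = "fixed",
                    func_class = "synonymous", depth = 44L,
                    site_quality = 120.3, stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(rec, tmp)
  lines <- readLines(tmp)
  body <- lines[!startsWith(lines, "#")]
  expect_match(body, "^c1\t10\t\\.\tA\tG\t120\\.3\tPASS\tSTATUS=fixed;CLASS=synonymous;DP=44$")
})
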