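# ---- capture performance evaluation -----------------------------------------
#
# Alignments are a data.frame: read_id, sample_id, contig_id, pos (0-based),
# bases, quals, unique (logical; MAPQ > 0), is_dup (logical).  Reads are
# assumed gapless on the reference (CIGAR <n>M), which is what the simulator
# emits; gapped records from external mappers are reduced to their aligned
# span on read-in.

#' Construct an alignment table
#' @param read_id,sample_id,contig_id,pos,bases,quals,unique,is_dup columns;
#'   `pos` is 0-based.
#' @return data.frame of alignment records.
#' @export
alignments <- function(read_id, contig_id, pos, bases, quals = NULL,
                       sample_id = NA_character_, unique = TRUE,
                       is_dup = FALSE) {
  n <- length(read_id)
  if (is.null(quals)) quals <- strrep(qual_encode(30L), nchar(bases))
  data.frame(read_id = read_id, sample_id = rep_len(sample_id, n),
             contig_id = contig_id, pos = as.integer(pos), bases = bases,
             quals = quals, unique = rep_len(unique, n),
             is_dup = rep_len(is_dup, n), stringsAsFactors = FALSE)
}

#' Write / read minimal SAM
#'
#' Eleven mandatory columns; MAPQ 60 for uniquely mapped records, 0 for
#' non-unique; CIGAR `<n>M`. `read_sam` accepts gapped CIGARs (M/=/X consumed
#' into the span; I/S clipped from the read; D/N gap the reference, splitting
#' is not attempted for these simple records) but the package's own writer
#' only emits `<n>M`.  Sample ids travel in the RG:Z tag.
#'
#' @param aln an [alignments()] table.
#' @param contigs named character vector (for @SQ header lengths).
#' @param path file path.
#' @return `read_sam`: an [alignments()] table.
#' @export
write_sam <- function(aln, contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)), con)
  if (nrow(aln) > 0) {
    writeLines(sprintf(
      "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tRG:Z:%s",
      aln$read_id, ifelse(aln$is_dup, 1024L, 0L), aln$contig_id,
      aln$pos + 1L, ifelse(aln$unique, 60L, 0L), nchar(aln$bases),
      aln$bases, aln$quals,
      ifelse(is.na(aln$sample_id), "none", aln$sample_id)), con)
  }
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(alignments(character(0), character(0), integer(0), character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  rg <- vapply(f, function(x) {
    tag <- grep("^RG:Z:", x[-(1:11)], value = TRUE)
    if (length(tag)) sub("^RG:Z:", "", tag[1]) else NA_character_
  }, character(1))
  # reduce CIGAR to read bases actually aligned to the reference (drop S/I)
  cig <- get(6); seqs <- get(10); quals <- get(11)
  parse_one <- function(cg, sq, ql) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]", "", ops)); op <- sub("[0-9]+", "", ops)
    b <- character(0); q <- character(0); at <- 1L
    for (k in seq_along(op)) {
      if (op[k] %in% c("M", "=", "X")) {
        b <- c(b, substr(sq, at, at + n[k] - 1L))
        q <- c(q, substr(ql, at, at + n[k] - 1L))
        at <- at + n[k]
      } else if (op[k] %in% c("I", "S")) {
        at <- at + n[k]
      } # D/N consume reference only; not represented in the gapless model
    }
    c(paste(b, collapse = ""), paste(q, collapse = ""))
  }
  simple <- grepl("^[0-9]+M$", cig)
  bq <- matrix(c(seqs, quals), ncol = 2)
  if (any(!simple)) {
    for (i in which(!simple)) bq[i, ] <- parse_one(cig[i], seqs[i], quals[i])
  }
  alignments(read_id = get(1), contig_id = get(3),
             pos = as.integer(get(4)) - 1L, bases = bq[, 1], quals = bq[, 2],
             sample_id = rg, unique = as.integer(get(5)) > 0L,
             is_dup = bitwAnd(flag, 1024L) > 0L)
}

#' Per-base pileup
#'
#' Stacks base counts per reference position from uniquely mapped,
#' non-duplicate reads.  Every position of every referenced contig is
#' emitted, including zero-depth positions.
#'
#' @param aln an [alignments()] table.
#' @param contigs named character vector of reference contigs.
#' @return data.frame of class `"pileup"`: `contig_id`, `pos` (0-based),
#'   `depth`, `A`, `C`, `G`, `T`, `N`, `qual_sum` (sum of Phred qualities of
#'   stacked bases; mean = qual_sum/depth).
#' @export
pileup <- function(aln, contigs) {
  use <- aln[aln$unique & !aln$is_dup, , drop = FALSE]
  if (nrow(use) > 0 &&
      any(use$pos + nchar(use$bases) > nchar(contigs)[match(use$contig_id, names(contigs))]))
    stop("pileup: alignment extends beyond contig end")
  out <- vector("list", length(contigs))
  base_codes <- utf8ToInt("ACGTN")
  for (ci in seq_along(contigs)) {
    cid <- names(contigs)[ci]
    L <- nchar(contigs[ci])
    cnt <- matrix(0L, nrow = 5L, ncol = L)
    qsum <- numeric(L)
    rows <- which(use$contig_id == cid)
    for (r in rows) {
      b <- utf8ToInt(use$bases[r])
      q <- utf8ToInt(use$quals[r]) - 33L
      p <- use$pos[r] + seq_along(b)  # 1-based columns
      bi <- match(b, base_codes); bi[is.na(bi)] <- 5L
      cnt[cbind(bi, p)] <- cnt[cbind(bi, p)] + 1L
      qsum[p] <- qsum[p] + q
    }
    out[[ci]] <- data.frame(
      contig_id = cid, pos = 0:(L - 1L), depth = colSums(cnt),
      A = cnt[1, ], C = cnt[2, ], G = cnt[3, ], T = cnt[4, ], N = cnt[5, ],
      qual_sum = qsum, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pileup", "data.frame")
  res
}

# depth vector for one in-target span
.span_depth <- function(pile, contig_id, c_start, c_end) {
  rows <- pile$contig_id == contig_id & pile$pos >= c_start & pile$pos < c_end
  pile$depth[rows]
}

#' Capture sensitivity
#'
#' Percentage of intended targets covered by at least one read (at least one
#' base of the target span has depth >= 1).
#'
#' @param map an [identify_in_target()] map (targets absent from the map
#'   count as uncovered if `all_targets` supplies the full design).
#' @param pile a [pileup()].
#' @param all_targets optional character vector of all designed target ids;
#'   defaults to the targets in `map`.
#' @return percentage in \[0, 100\].
#' @export
sensitivity <- function(map, pile, all_targets = NULL) {
  if (is.null(all_targets)) all_targets <- map$target_id
  if (length(all_targets) == 0) stop("sensitivity: zero targets")
  covered <- vapply(seq_len(nrow(map)), function(i) {
    any(.span_depth(pile, map$contig_id[i], map$c_start[i], map$c_end[i]) >= 1)
  }, logical(1))
  100 * sum(map$target_id[covered] %in% all_targets) / length(all_targets)
}

#' Capture specificity (on-target rate)
#'
#' Percentage of uniquely mapped, non-duplicate reads whose aligned span
#' overlaps a target span by at least one base, over all such reads aligned
#' anywhere in the consensus assemblies.
#'
#' @param aln an [alignments()] table.
#' @param map an [identify_in_target()] map.
#' @return percentage, or NA if no reads are aligned.
#' @export
specificity <- function(aln, map) {
  use <- aln[aln$unique & !aln$is_dup, , drop = FALSE]
  if (nrow(use) == 0) return(NA_real_)
  ends <- use$pos + nchar(use$bases)
  on_target <- logical(nrow(use))
  for (i in seq_len(nrow(map))) {
    hit <- use$contig_id == map$contig_id[i] &
      use$pos < map$c_end[i] & ends > map$c_start[i]
    on_target <- on_target | hit
  }
  100 * mean(on_target)
}

#' Per-target coverage and threshold summary
#'
#' Mean base coverage over each target span, plus the fraction of targets
#' with mean coverage of at least 1X and strictly greater than the higher
#' thresholds (mirroring the conventional "at least 1X" / "greater than 5X"
#' reporting).
#'
#' @param pile a [pileup()].
#' @param map an [identify_in_target()] map.
#' @param thresholds coverage thresholds; the first uses `>=`, the rest `>`.
#' @return list with `per_target` (data.frame `target_id`, `mean_cov`),
#'   `fractions` (named numeric), and `mean_coverage` (grand mean over
#'   targets).
#' @export
coverage_summary <- function(pile, map, thresholds = c(1, 5, 10)) {
  mc <- vapply(seq_len(nrow(map)), function(i) {
    d <- .span_depth(pile, map$contig_id[i], map$c_start[i], map$c_end[i])
    if (length(d) == 0) 0 else mean(d)
  }, numeric(1))
  per <- data.frame(target_id = map$target_id, mean_cov = mc,
                    stringsAsFactors = FALSE)
  fr <- vapply(seq_along(thresholds), function(k) {
    if (k == 1) mean(mc >= thresholds[k]) else mean(mc > thresholds[k])
  }, numeric(1))
  names(fr) <- paste0(ifelse(seq_along(thresholds) == 1, "ge", "gt"),
                      thresholds, "X")
  list(per_target = per, fractions = fr, mean_coverage = mean(mc))
}

#' Edge coverage profile
#'
#' For targets of length in `[min_len, max_len]`, each position is assigned
#' to a `bin`-bp bin by its distance to the nearer target end; the mean
#' coverage per bin (across all positions of all qualifying targets)
#' quantifies the edge effect.
#'
#' @param pile a [pileup()].
#' @param map an [identify_in_target()] map.
#' @param min_len,max_len target length window (201-600 by default).
#' @param bin bin width in bp.
#' @return data.frame `bin`, `dist_lo`, `dist_hi`, `mean_cov`, `n_positions`.
#' @export
edge_profile <- function(pile, map, min_len = 201L, max_len = 600L,
                         bin = 20L) {
  len <- map$c_end - map$c_start
  sel <- which(len >= min_len & len <= max_len)
  if (length(sel) == 0) stop("edge_profile: no qualifying targets")
  dist <- integer(0); dep <- numeric(0)
  for (i in sel) {
    d <- .span_depth(pile, map$contig_id[i], map$c_start[i], map$c_end[i])
    L <- length(d)
    pos <- 0:(L - 1L)
    dist <- c(dist, pmin(pos, L - 1L - pos))
    dep <- c(dep, d)
  }
  b <- dist %/% bin
  agg <- stats::aggregate(dep, list(bin = b), mean)
  out <- data.frame(bin = agg$bin, dist_lo = agg$bin * bin,
                    dist_hi = (agg$bin + 1L) * bin, mean_cov = agg$x,
                    n_positions = as.integer(table(b)[as.character(agg$bin)]))
  rownames(out) <- NULL
  out
}

#' GC content vs coverage
#'
#' Bins targets by GC fraction (5% bins) and reports mean coverage per bin;
#' empty bins are omitted.
#'
#' @param gc numeric vector of per-target GC fractions.
#' @param cov numeric vector of per-target mean coverage (same order).
#' @param bin_width GC bin width (default 0.05).
#' @return data.frame `gc_lo`, `gc_hi`, `gc_mid`, `mean_cov`, `n`.
#' @export
gc_coverage_relation <- function(gc, cov, bin_width = 0.05) {
  stopifnot(length(gc) == length(cov))
  b <- pmin(floor(gc / bin_width), floor(1 / bin_width) - 1)
  agg <- stats::aggregate(cov, list(bin = b), mean)
  n <- as.integer(table(b)[as.character(agg$bin)])
  data.frame(gc_lo = agg$bin * bin_width, gc_hi = (agg$bin + 1) * bin_width,
             gc_mid = (agg$bin + 0.5) * bin_width, mean_cov = agg$x, n = n)
}

#' Reproducibility of capture between libraries
#'
#' Pearson correlation of log10(coverage + 1) across shared targets for a
#' pair of libraries.  Undefined (NA) when either vector has zero variance.
#'
#' @param cov_a,cov_b per-target mean coverage for the two libraries, in the
#'   same target order (>= 3 shared targets required).
#' @return correlation coefficient or NA.
#' @export
reproducibility <- function(cov_a, cov_b) {
  stopifnot(length(cov_a) == length(cov_b), length(cov_a) >= 3)
  la <- log10(cov_a + 1); lb <- log10(cov_b + 1)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) return(NA_real_)
  stats::cor(la, lb)
}

#' Coverage vs target divergence
#'
#' Bins targets by their divergence from the in-target assembly (1% bins)
#' and reports mean normalized coverage per bin; bins supported by fewer
#' than `min_support` targets are flagged.
#'
#' @param divergence per-target divergence fractions.
#' @param cov per-target normalized coverage (same order).
#' @param bin_width divergence bin width (default 0.01).
#' @param min_support minimum targets per bin before the bin is flagged
#'   low-support.
#' @return data.frame `div_lo`, `div_hi`, `mean_cov`, `n`, `low_support`.
#' @export
divergence_coverage <- function(divergence, cov, bin_width = 0.01,
                                min_support = 3L) {
  stopifnot(length(divergence) == length(cov))
  b <- floor(divergence / bin_width)
  agg <- stats::aggregate(cov, list(bin = b), mean)
  n <- as.integer(table(b)[as.character(agg$bin)])
  data.frame(div_lo = agg$bin * bin_width, div_hi = (agg$bin + 1) * bin_width,
             mean_cov = agg$x, n = n, low_support = n < min_support)
}

#' Empirical sequencing error from haploid loci
#'
#' On haploid loci (mitochondrial contigs, X-linked targets in males, SRY)
#' every within-sample mismatch is error.  The per-column consensus
#' (majority) base is taken as truth; the rate is the total count of
#' non-consensus stacked bases divided by the total stacked bases, over
#' columns with depth at least `min_depth`.
#'
#' @param pile a [pileup()] restricted to haploid loci (subset rows before
#'   calling, or pass `contig_ids`).
#' @param contig_ids optional contig ids to restrict to.
#' @param min_depth minimum column depth for consensus calling (default 10).
#' @return list with `mismatches`, `aligned_bases`, `rate`, `phred`.
#' @export
haploid_error_rate <- function(pile, contig_ids = NULL, min_depth = 10L) {
  p <- if (is.null(contig_ids)) pile else
    pile[pile$contig_id %in% contig_ids, , drop = FALSE]
  p <- p[p$depth >= min_depth, , drop = FALSE]
  if (nrow(p) == 0 || sum(p$depth) == 0)
    stop("haploid_error_rate: zero aligned bases")
  maj <- pmax(p$A, p$C, p$G, p$T)
  mism <- sum(p$depth - maj)
  bases <- sum(p$depth)
  rate <- mism / bases
  list(mismatches = mism, aligned_bases = bases, rate = rate,
       phred = if (rate > 0) phred_from_error(rate) else Inf)
}

#' Identify putatively X-linked targets by coverage dosage
#'
#' Targets whose female-to-male average coverage ratio falls in
#' `ratio_window` (1.9-2.1 by default, the diploid/haploid dosage) are
#' returned as putatively X-linked.  Targets with zero male mean coverage
#' are skipped and flagged.
#'
#' @param cov matrix of per-target mean coverage (rows = targets, columns =
#'   samples; rownames/colnames required).
#' @param sexes named character vector (`"F"`/`"M"`) per sample.
#' @param ratio_window acceptance window on the F/M ratio.
#' @return data.frame `target_id`, `ratio`, `x_linked`, `skipped`.
#' @export
identify_x_linked <- function(cov, sexes, ratio_window = c(1.9, 2.1)) {
  stopifnot(!is.null(rownames(cov)), !is.null(colnames(cov)))
  sexes <- sexes[colnames(cov)]
  if (!any(sexes == "F") || !any(sexes == "M"))
    stop("identify_x_linked: need at least one male and one female sample")
  fmean <- rowMeans(cov[, sexes == "F", drop = FALSE])
  mmean <- rowMeans(cov[, sexes == "M", drop = FALSE])
  skipped <- mmean == 0
  ratio <- ifelse(skipped, NA_real_, fmean / mmean)
  data.frame(target_id = rownames(cov), ratio = ratio,
             x_linked = !skipped & ratio >= ratio_window[1] &
               ratio <= ratio_window[2],
             skipped = skipped, stringsAsFactors = FALSE)
}

#' Per-sample SRY read check
#'
#' Females with any SRY-mapped read are flagged as possible cross-sample
#' contamination; males with none are flagged as possible capture failure.
#'
#' @param sry_reads named integer vector of SRY-mapped read counts per
#'   sample.
#' @param sexes named character vector (`"F"`/`"M"`).
#' @return data.frame `sample_id`, `sex`, `sry_reads`, `status` (one of
#'   `pass`, `possible_contamination`, `possible_capture_failure`).
#' @export
sry_check <- function(sry_reads, sexes) {
  ids <- names(sry_reads)
  sex <- sexes[ids]
  status <- ifelse(sex == "F" & sry_reads > 0, "possible_contamination",
            ifelse(sex == "M" & sry_reads == 0, "possible_capture_failure",
                   "pass"))
  data.frame(sample_id = ids, sex = unname(sex),
             sry_reads = unname(sry_reads), status = unname(status),
             stringsAsFactors = FALSE)
}
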