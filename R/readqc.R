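# ---- pre-analysis read filtration -------------------------------------------
#
# Read pairs are a data.frame with columns pair_id, bases1, quals1, bases2,
# quals2 (Phred+33 strings), barcode (7-nt or NA), sample_id (NA until
# demultiplexed).  Optional provenance columns from the simulator (is_dup,
# is_contam, ...) ride along untouched.

#' Construct a read-pair table
#'
#' @param pair_id character vector of pair ids.
#' @param bases1,quals1,bases2,quals2 character vectors (quals Phred+33).
#' @param barcode optional 7-nt barcodes.
#' @param sample_id optional sample assignment.
#' @return data.frame of read pairs.
#' @export
read_pairs <- function(pair_id, bases1, quals1, bases2, quals2,
                       barcode = NA_character_, sample_id = NA_character_) {
  stopifnot(all(nchar(bases1) == nchar(quals1)),
            all(nchar(bases2) == nchar(quals2)))
  bc <- rep_len(barcode, length(pair_id))
  stopifnot(all(is.na(bc) | nchar(bc) == 7L))
  data.frame(pair_id = pair_id, bases1 = bases1, quals1 = quals1,
             bases2 = bases2, quals2 = quals2, barcode = bc,
             sample_id = rep_len(sample_id, length(pair_id)),
             stringsAsFactors = FALSE)
}

.hamming <- function(a, b) {
  x <- charToRaw(a); y <- charToRaw(b)
  n <- charToRaw("N")
  sum(x != y | x == n | y == n)
}

#' Demultiplex read pairs by barcode
#'
#' Assigns each pair to the unique sample whose barcode matches within
#' `max_mismatch`; ambiguous or non-matching pairs go to `unassigned`.
#' The barcode map is validated up front: barcodes must be mutually more
#' than `2 * max_mismatch` mismatches apart, otherwise assignment would be
#' ambiguous by construction.
#'
#' @param pairs a [read_pairs()] table with a `barcode` column.
#' @param barcode_map data.frame with columns `sample_id` and `barcode`.
#' @param max_mismatch maximum barcode mismatches tolerated (default 0).
#' @return list with `assigned` (pairs with `sample_id` filled) and
#'   `unassigned`.
#' @export
demultiplex <- function(pairs, barcode_map, max_mismatch = 0L) {
  stopifnot(all(c("sample_id", "barcode") %in% names(barcode_map)))
  bcs <- barcode_map$barcode
  if (length(bcs) > 1) {
    for (i in seq_len(length(bcs) - 1)) for (j in (i + 1):length(bcs))
      if (.hamming(bcs[i], bcs[j]) <= 2L * max_mismatch)
        stop(sprintf("demultiplex: barcodes %s and %s collide at max_mismatch=%d",
                     bcs[i], bcs[j], max_mismatch))
  }
  assign_one <- function(bc) {
    if (is.na(bc)) return(NA_character_)
    d <- vapply(bcs, .hamming, integer(1), a = bc)
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1) barcode_map$sample_id[hit] else NA_character_
  }
  pairs$sample_id <- vapply(pairs$barcode, assign_one, character(1),
                            USE.NAMES = FALSE)
  list(assigned = pairs[!is.na(pairs$sample_id), , drop = FALSE],
       unassigned = pairs[is.na(pairs$sample_id), , drop = FALSE])
}

#' Remove exact duplicate pairs
#'
#' Pairs whose forward and reverse read sequences are both identical to an
#' earlier pair are removed; the first occurrence (input order) is kept.
#'
#' @param pairs a [read_pairs()] table.
#' @return list with `unique` (pairs kept, input order) and `n_duplicates`.
#' @export
remove_exact_duplicates <- function(pairs) {
  key <- paste(pairs$bases1, pairs$bases2, sep = "\r")
  dup <- duplicated(key)
  list(unique = pairs[!dup, , drop = FALSE], n_duplicates = sum(dup))
}

# leftmost 3' adapter occurrence with >= min_overlap bp and <= 10% mismatch
.find_adapter <- function(read, adapter, min_overlap = 10L,
                          max_mismatch_frac = 0.1) {
  n <- nchar(read); m <- nchar(adapter)
  if (n < min_overlap) return(NA_integer_)
  for (p in 1:(n - min_overlap + 1L)) {
    o <- min(m, n - p + 1L)
    mism <- .hamming(substr(read, p, p + o - 1L), substr(adapter, 1, o))
    if (mism <= max_mismatch_frac * o) return(p)
  }
  NA_integer_
}

# BWA-style 3' quality trimming: remove the suffix maximising the running sum
# of (min_q - q) from the 3' end; returns number of kept bases
.qual_trim_keep <- function(quals, min_q = 20L) {
  q <- qual_decode(quals)
  s <- cumsum(min_q - rev(q))
  if (max(s) <= 0) length(q) else length(q) - which.max(s)
}

# dust-style low-complexity score: triplet collision count per 64-bp window
.dust_score <- function(read, window = 64L) {
  n <- nchar(read)
  starts <- unique(c(seq.int(1L, max(1L, n - window + 1L), by = 32L),
                     max(1L, n - window + 1L)))
  max(vapply(starts, function(st) {
    w <- substr(read, st, min(n, st + window - 1L))
    wl <- nchar(w)
    if (wl < 4L) return(0)
    tri <- substring(w, 1:(wl - 2L), 3:wl)
    cnt <- table(tri)
    sum(cnt * (cnt - 1) / 2) / (wl - 3L)
  }, numeric(1)))
}

.mono_frac <- function(read) {
  b <- strsplit(read, "", fixed = TRUE)[[1]]
  max(table(b)) / length(b)
}

#' Clean one read pair
#'
#' Per mate: (a) a 3' adapter occurrence (>= 10 bp overlap, <= 10% mismatch)
#' truncates the read at the leftmost hit; (b) the longest low-quality 3'
#' suffix is removed by a running-sum rule (maximising \eqn{\sum (Q_{min} -
#' q_i)} from the 3' end); (c) the pair is rejected as low-complexity if any
#' 64-bp window has a dust-style triplet score above `dust_threshold` or a
#' single nucleotide makes up `mono_frac` or more of a mate.  The pair is
#' rejected if either mate is shorter than `min_len` after trimming.
#'
#' @param pair one-row [read_pairs()] data.frame.
#' @param adapters character vector of adapter sequences.
#' @param min_q quality-trimming threshold (Q20).
#' @param min_len minimum surviving mate length.
#' @param dust_threshold dust score threshold per 64-bp window.
#' @param mono_frac mononucleotide fraction threshold.
#' @return the cleaned one-row pair, or `NULL` with attribute-free rejection
#'   (use [clean_pairs()] for bookkeeping).
#' @export
clean_read_pair <- function(pair, adapters, min_q = 20L, min_len = 36L,
                            dust_threshold = 7, mono_frac = 0.9) {
  stopifnot(length(adapters) >= 1)
  for (mate in 1:2) {
    b <- pair[[paste0("bases", mate)]]
    q <- pair[[paste0("quals", mate)]]
    cut <- NA_integer_
    for (ad in adapters) {
      p <- .find_adapter(b, ad)
      if (!is.na(p)) cut <- min(cut, p, na.rm = TRUE)
    }
    if (!is.na(cut)) {
      b <- substr(b, 1, cut - 1L); q <- substr(q, 1, cut - 1L)
    }
    if (nchar(b) > 0) {
      keep <- .qual_trim_keep(q, min_q)
      b <- substr(b, 1, keep); q <- substr(q, 1, keep)
    }
    if (nchar(b) < min_len) return(NULL)
    if (.mono_frac(b) >= mono_frac || .dust_score(b) > dust_threshold)
      return(NULL)
    pair[[paste0("bases", mate)]] <- b
    pair[[paste0("quals", mate)]] <- q
  }
  pair
}

#' Clean many pairs
#'
#' Applies [clean_read_pair()] to every row and reports how many pairs were
#' rejected.
#'
#' @inheritParams clean_read_pair
#' @param pairs a [read_pairs()] table.
#' @return list with `passed` (cleaned pairs) and `n_rejected`.
#' @export
clean_pairs <- function(pairs, adapters, min_q = 20L, min_len = 36L,
                        dust_threshold = 7, mono_frac = 0.9) {
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs)))
    out[[i]] <- clean_read_pair(pairs[i, , drop = FALSE], adapters, min_q,
                                min_len, dust_threshold, mono_frac)
  keep <- !vapply(out, is.null, logical(1))
  passed <- if (any(keep)) do.call(rbind, out[keep]) else pairs[0, , drop = FALSE]
  rownames(passed) <- NULL
  list(passed = passed, n_rejected = sum(!keep))
}

#' Screen read pairs against a contaminant k-mer table
#'
#' A pair is flagged as contaminant iff at least `frac` of either mate's
#' 21-mers occur in the contaminant table (built from e.g. human and
#' E. coli reference sequence with [count_kmers()], k = 21).
#'
#' @param pairs a [read_pairs()] table.
#' @param contaminant_table a [count_kmers()] table (k = 21 by convention).
#' @param frac fraction of matching k-mers that triggers the flag.
#' @return logical vector, TRUE = contaminant.
#' @export
contaminant_screen <- function(pairs, contaminant_table, frac = 0.8) {
  flag_mate <- function(b) {
    f <- kmer_frequencies(b, contaminant_table)
    f <- f[!is.na(f)]
    length(f) > 0 && mean(f > 0) >= frac
  }
  vapply(seq_len(nrow(pairs)), function(i) {
    flag_mate(pairs$bases1[i]) || flag_mate(pairs$bases2[i])
  }, logical(1))
}

#' Base-quality summary
#'
#' Mean Phred quality and the fraction of bases with Q >= 30 over all bases
#' of all mates.
#'
#' @param pairs a [read_pairs()] table (quality strings required).
#' @return list with `mean_q` and `frac_q30`.
#' @export
quality_summary <- function(pairs) {
  qs <- c(pairs$quals1, pairs$quals2)
  if (any(!nzchar(qs)) || length(qs) == 0)
    stop("quality_summary: missing quality strings")
  q <- unlist(lapply(qs, qual_decode), use.names = FALSE)
  list(mean_q = mean(q), frac_q30 = mean(q >= 30))
}

#' Subsample read pairs
#'
#' Uniform sampling without replacement, reproducible given `seed`; output
#' preserves input order.
#'
#' @param pairs a [read_pairs()] table.
#' @param n number of pairs to keep.
#' @param seed RNG seed.
#' @return subsampled pairs.
#' @export
subsample_pairs <- function(pairs, n, seed) {
  if (n > nrow(pairs)) stop("subsample_pairs: n exceeds number of pairs")
  idx <- with_seed(seed, sort(sample.int(nrow(pairs), n)))
  pairs[idx, , drop = FALSE]
}

#' Run the full filtration pipeline
#'
#' Duplicate removal, adapter/quality/complexity cleaning and contaminant
#' screening, with telescoping stage counts (the output count of each stage
#' is the input count of the next).
#'
#' @param pairs a [read_pairs()] table.
#' @param adapters adapter sequences.
#' @param contaminant_table optional contaminant [count_kmers()] table.
#' @inheritParams clean_read_pair
#' @param contaminant_frac k-mer fraction for the contaminant flag.
#' @return list with `passed` (pairs) and `report` (data.frame `stage`,
#'   `n_in`, `n_removed`, `n_out`) plus `fraction_passed`.
#' @export
filter_reads <- function(pairs, adapters, contaminant_table = NULL,
                         min_q = 20L, min_len = 36L, dust_threshold = 7,
                         mono_frac = 0.9, contaminant_frac = 0.8) {
  n0 <- nrow(pairs)
  dd <- remove_exact_duplicates(pairs)
  cl <- clean_pairs(dd$unique, adapters, min_q, min_len, dust_threshold,
                    mono_frac)
  if (!is.null(contaminant_table) && nrow(cl$passed) > 0) {
    contam <- contaminant_screen(cl$passed, contaminant_table,
                                 contaminant_frac)
  } else contam <- rep(FALSE, nrow(cl$passed))
  passed <- cl$passed[!contam, , drop = FALSE]
  report <- data.frame(
    stage = c("duplicates", "clean", "contaminant"),
    n_in = c(n0, nrow(dd$unique), nrow(cl$passed)),
    n_removed = c(dd$n_duplicates, cl$n_rejected, sum(contam)),
    stringsAsFactors = FALSE)
  report$n_out <- report$n_in - report$n_removed
  list(passed = passed, report = report,
       fraction_passed = if (n0 > 0) nrow(passed) / n0 else NA_real_)
}
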