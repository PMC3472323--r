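# ---- assembly merging, statistics, and in-target identification ------------

#' Merge multi-parameter assemblies into a low-redundancy consensus
#'
#' Contigs from all input assemblies are pooled and greedily clustered in
#' decreasing length order: a contig joins an existing consensus when a local
#' alignment (either strand) reaches `id_threshold` identity over at least
#' `min_overlap` alignable bases.  Contained contigs collapse into the
#' container; contigs overhanging a consensus end extend it.  At mismatching
#' columns the consensus keeps the base of the longer (earlier-processed)
#' member.
#'
#' @param assemblies a list of named character vectors (or a single one).
#' @param id_threshold minimum alignment identity to merge (0.99: redundancy
#'   removal within one individual/species).
#' @param min_overlap minimum alignable bases to merge.
#' @param scoring DNA alignment scoring.
#' @return named character vector of merged contigs (ids of cluster
#'   representatives = longest members).
#' @export
merge_assemblies <- function(assemblies, id_threshold = 0.99,
                             min_overlap = 40L, scoring = align_scoring()) {
  if (!is.list(assemblies)) assemblies <- list(assemblies)
  pool <- do.call(c, lapply(assemblies, function(a) a))
  stopifnot(length(pool) >= 1, !is.null(names(pool)))
  pool <- pool[order(-nchar(pool))]
  cons <- character(0)  # named consensus sequences
  for (i in seq_along(pool)) {
    s <- unname(pool[i]); id <- names(pool)[i]
    merged <- FALSE
    for (j in seq_along(cons)) {
      hit <- NULL
      for (cand in c(s, revcomp(s))) {
        a <- local_align(cand, cons[j], scoring,
                         query_id = id, ref_id = names(cons)[j])
        if (a$hit && a$alignable >= min_overlap &&
            !is.na(a$identity) && a$identity >= id_threshold) {
          hit <- list(aln = a, seq = cand); break
        }
      }
      if (!is.null(hit)) {
        a <- hit$aln; cs <- unname(cons[j]); sq <- hit$seq
        left <- if (a$q_span[1] > 0 && a$r_span[1] == 0)
          substr(sq, 1, a$q_span[1]) else ""
        right <- if (a$q_span[2] < nchar(sq) && a$r_span[2] == nchar(cs))
          substr(sq, a$q_span[2] + 1L, nchar(sq)) else ""
        cons[j] <- paste0(left, cs, right)
        merged <- TRUE
        break
      }
    }
    if (!merged) cons[id] <- s
  }
  cons
}

#' Assembly statistics
#'
#' @param contigs named character vector.
#' @return list with `n`, `total_length`, `mean_length`, `median_length`,
#'   `n50` (the contig length at which the cumulative length of contigs at
#'   least that long first reaches half the total).
#' @export
assembly_stats <- function(contigs) {
  if (length(contigs) == 0) stop("assembly_stats: empty assembly")
  len <- sort(nchar(contigs), decreasing = TRUE)
  total <- sum(len)
  n50 <- unname(len[which(cumsum(len) >= total / 2)[1]])
  list(n = length(contigs), total_length = total, mean_length = mean(len),
       median_length = stats::median(len), n50 = n50)
}

# candidate subject indices per query that share at least one k-mer
.kmer_candidates <- function(A, B, k) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_along(B)) {
    s <- B[[j]]
    n <- nchar(s)
    if (n < k) next
    for (w in unique(substring(s, 1:(n - k + 1), k:n))) {
      idx[[w]] <- c(idx[[w]], j)
    }
  }
  lapply(seq_along(A), function(i) {
    s <- A[[i]]
    n <- nchar(s)
    if (n < k) return(integer(0))
    w <- unique(substring(s, 1:(n - k + 1), k:n))
    sort(unique(unlist(lapply(w, function(x) idx[[x]]))))
  })
}

# all-vs-all best hits of queries against subjects; large problems are
# prescreened by shared 12-mers (a pair with no shared 12-mer cannot reach
# the RBH identity floor), small ones stay exhaustively exact
.best_hits <- function(A, B, scoring, prefilter_k = 12L) {
  if (!is.null(prefilter_k) && length(A) * length(B) > 100) {
    cand <- .kmer_candidates(A, B, prefilter_k)
  } else {
    cand <- rep(list(seq_along(B)), length(A))
  }
  rows <- lapply(seq_along(B), function(j) {
    qs <- which(vapply(cand, function(x) j %in% x, logical(1)))
    if (length(qs) == 0) return(NULL)
    df <- local_align_many(A[qs], B[j], scoring)
    df$ref_id <- names(B)[j]
    df
  })
  all <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(all)) {
    all <- local_align_many(A[1], B[1], scoring)[0, ]
    all$ref_id <- character(0)
  }
  all <- all[all$hit, , drop = FALSE]
  if (nrow(all) == 0) return(all)
  all$aln_len <- all$alignable
  # best per query: score, then alignment length, then lexicographic subject id
  all <- all[order(all$query_id, -all$score, -all$aln_len, all$ref_id), ,
             drop = FALSE]
  all[!duplicated(all$query_id), , drop = FALSE]
}

#' Reciprocal best hits between two sequence sets
#'
#' A pair `(a, b)` is reported iff `b` is `a`'s best-scoring hit in B and `a`
#' is `b`'s best-scoring hit in A, with at least `min_len` alignable bases at
#' identity at least `min_identity`.  Ties are broken by score, then
#' alignment length, then lexicographic id.
#'
#' @param setA,setB named character vectors.
#' @param min_identity,min_len acceptance thresholds on the pairing
#'   alignment.
#' @param scoring DNA alignment scoring.
#' @return data.frame `a_id`, `b_id`, `score`, `aln_len`, `identity`,
#'   `a_start`, `a_end`, `b_start`, `b_end` (0-based half-open spans of the
#'   a-vs-b alignment).
#' @export
reciprocal_best_hit <- function(setA, setB, min_identity = 0.8,
                                min_len = 60L, scoring = align_scoring()) {
  stopifnot(length(setA) >= 1, length(setB) >= 1)
  ab <- .best_hits(setA, setB, scoring)
  ba <- .best_hits(setB, setA, scoring)
  empty <- data.frame(a_id = character(0), b_id = character(0),
                      score = numeric(0), aln_len = integer(0),
                      identity = numeric(0), a_start = integer(0),
                      a_end = integer(0), b_start = integer(0),
                      b_end = integer(0), stringsAsFactors = FALSE)
  if (nrow(ab) == 0 || nrow(ba) == 0) return(empty)
  back <- ba$ref_id[match(ab$ref_id, ba$query_id)]
  mutual <- !is.na(back) & back == ab$query_id
  ok <- mutual & ab$aln_len >= min_len & !is.na(ab$identity) &
    ab$identity >= min_identity
  ab <- ab[ok, , drop = FALSE]
  if (nrow(ab) == 0) return(empty)
  out <- data.frame(a_id = ab$query_id, b_id = ab$ref_id, score = ab$score,
                    aln_len = ab$aln_len, identity = ab$identity,
                    a_start = ab$q_start, a_end = ab$q_end,
                    b_start = ab$r_start, b_end = ab$r_end,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$a_id), , drop = FALSE]
}

#' Identify in-target assemblies
#'
#' Associates each capture target with the consensus contig that is its
#' reciprocal best hit; the resulting "in-target assemblies" serve as the
#' mapping reference in place of a genome.  Flanking spans beyond the exon
#' boundaries (captured intron/UTR sequence) are recorded.
#'
#' @param contigs named character vector of consensus contigs.
#' @param target_set a [build_target_set()] result (or a data.frame with
#'   `target_id` and `sequence`).
#' @param min_identity,min_len RBH acceptance thresholds.
#' @param scoring DNA alignment scoring.
#' @return object of class `"in_target_map"`: data.frame `target_id`,
#'   `contig_id`, `c_start`, `c_end` (target span on the contig, 0-based
#'   half-open), `identity`, `divergence`, `left_flank`, `right_flank`, with
#'   the contig sequences as attribute `contigs`.
#' @export
identify_in_target <- function(contigs, target_set, min_identity = 0.8,
                               min_len = 60L, scoring = align_scoring()) {
  t <- if (inherits(target_set, "target_set")) target_set$targets else target_set
  targets <- stats::setNames(t$sequence, t$target_id)
  rbh <- reciprocal_best_hit(targets, contigs, min_identity, min_len, scoring)
  clen <- nchar(contigs)[match(rbh$b_id, names(contigs))]
  out <- data.frame(
    target_id = rbh$a_id, contig_id = rbh$b_id,
    c_start = rbh$b_start, c_end = rbh$b_end,
    identity = rbh$identity, divergence = 1 - rbh$identity,
    left_flank = rbh$b_start, right_flank = clen - rbh$b_end,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, contigs = contigs, class = c("in_target_map", "data.frame"))
}

#' Write an in-target map as TSV
#' @param map an [identify_in_target()] result.
#' @param path output path.
#' @export
write_in_target_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(map)
}
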