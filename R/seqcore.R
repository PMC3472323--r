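# ---- shared sequence primitives ---------------------------------------------
#
# Sequences travel through the package as plain uppercase character strings over
# {A,C,G,T,N}; collections are named character vectors (names = ids).  All
# coordinates are 0-based half-open; conversion to 1-based happens only at the
# SAM/VCF boundary.

DNA_BASES <- c("A", "C", "G", "T")

#' Default alignment scoring
#'
#' BLAST-like defaults for local DNA alignment: match +1, mismatch -2,
#' gap opening -4, gap extension -1.  A gap of length L costs
#' `gap_open + L * gap_ext`.  `N` never matches anything (scored as a
#' mismatch), which keeps divergence estimates conservative.
#'
#' @param match positive match score.
#' @param mismatch negative mismatch score.
#' @param gap_open negative gap-opening score.
#' @param gap_ext negative per-base gap-extension score.
#' @return A list with the four scores, class `"align_scoring"`.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = -4, gap_ext = -1) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_ext < 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "align_scoring")
}

# substitution matrix where N (DNA) or X/* (protein) never match
.subst_matrix <- function(scoring, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  letters <- if (alphabet == "dna") c(DNA_BASES, "N") else
    c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T",
      "W","Y","V","X","*")
  m <- matrix(scoring$mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- scoring$match
  never <- if (alphabet == "dna") "N" else c("X", "*")
  m[never, ] <- scoring$mismatch
  m[, never] <- scoring$mismatch
  m
}

.aln_stats <- function(qs, rs) {
  # qs, rs: aligned strings of equal length with "-" gaps
  q <- charToRaw(qs); r <- charToRaw(rs)
  gap <- charToRaw("-")
  ngap <- q != gap & r != gap
  nn <- charToRaw("N")
  mism <- ngap & (q != r | q == nn | r == nn)
  c(alignable = sum(ngap), mismatches = sum(mism))
}

#' Local pairwise alignment
#'
#' Affine-gap local (Smith-Waterman) alignment of two sequences.  When no
#' positive-scoring alignment exists the result is flagged as a no-hit
#' (`hit = FALSE`).
#'
#' @param a,b sequences (character scalars); `a` is the query, `b` the
#'   reference.  Optionally named; names become `query_id` / `ref_id`.
#' @param scoring an [align_scoring()] list.
#' @param alphabet `"dna"` (default) or `"protein"`.
#' @param query_id,ref_id identifiers recorded on the result.
#' @return An object of class `"pw_align"`: a list with `query_id`, `ref_id`,
#'   `score`, `hit`, aligned strings `q_aligned` / `r_aligned`, counts
#'   `alignable` and `mismatches`, `identity`, and 0-based half-open spans
#'   `q_span`, `r_span`.
#' @export
local_align <- function(a, b, scoring = align_scoring(), alphabet = "dna",
                        query_id = NULL, ref_id = NULL) {
  if (is.null(query_id)) query_id <- if (!is.null(names(a))) names(a)[1] else "query"
  if (is.null(ref_id)) ref_id <- if (!is.null(names(b))) names(b)[1] else "ref"
  a <- unname(a); b <- unname(b)
  if (!nzchar(a) || !nzchar(b)) stop("local_align: empty sequence")
  mat <- .subst_matrix(scoring, alphabet)
  str <- if (alphabet == "dna") Biostrings::DNAString else Biostrings::AAString
  aln <- Biostrings::pairwiseAlignment(
    str(a), str(b), type = "local", substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_ext)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(structure(list(query_id = query_id, ref_id = ref_id, score = 0,
                          hit = FALSE, q_aligned = "", r_aligned = "",
                          alignable = 0L, mismatches = 0L, identity = NA_real_,
                          q_span = c(0L, 0L), r_span = c(0L, 0L)),
                     class = "pw_align"))
  }
  qs <- as.character(Biostrings::alignedPattern(aln))
  rs <- as.character(Biostrings::alignedSubject(aln))
  st <- .aln_stats(qs, rs)
  structure(list(
    query_id = query_id, ref_id = ref_id, score = sc, hit = TRUE,
    q_aligned = qs, r_aligned = rs,
    alignable = unname(st["alignable"]), mismatches = unname(st["mismatches"]),
    identity = 1 - unname(st["mismatches"]) / max(1L, unname(st["alignable"])),
    q_span = c(Biostrings::start(Biostrings::pattern(aln)) - 1L,
               Biostrings::end(Biostrings::pattern(aln))),
    r_span = c(Biostrings::start(Biostrings::subject(aln)) - 1L,
               Biostrings::end(Biostrings::subject(aln)))),
    class = "pw_align")
}

#' @export
print.pw_align <- function(x, ...) {
  if (!x$hit) {
    cat(sprintf("<pw_align> %s vs %s: no hit\n", x$query_id, x$ref_id))
  } else {
    cat(sprintf(
      "<pw_align> %s[%d,%d) vs %s[%d,%d) score=%g mismatches=%d/%d (%.1f%% id)\n",
      x$query_id, x$q_span[1], x$q_span[2], x$ref_id, x$r_span[1], x$r_span[2],
      x$score, x$mismatches, x$alignable, 100 * x$identity))
  }
  invisible(x)
}

#' Align many queries against one reference
#'
#' Vectorised local alignment of a set of queries against a single reference,
#' returning one row per query.  Used by the reciprocal-best-hit search and
#' exon boundary transfer, where one subject is scanned by many patterns.
#'
#' @param queries named character vector of query sequences.
#' @param ref reference sequence (character scalar, optionally named).
#' @inheritParams local_align
#' @return data.frame with columns `query_id`, `ref_id`, `score`, `hit`,
#'   `q_start`, `q_end`, `r_start`, `r_end` (0-based half-open), `alignable`,
#'   `mismatches`, `identity`.
#' @export
local_align_many <- function(queries, ref, scoring = align_scoring(),
                             alphabet = "dna") {
  stopifnot(length(queries) >= 1, !is.null(names(queries)))
  ref_id <- if (!is.null(names(ref))) names(ref)[1] else "ref"
  mat <- .subst_matrix(scoring, alphabet)
  if (alphabet == "dna") {
    qset <- Biostrings::DNAStringSet(unname(queries))
    subj <- Biostrings::DNAString(unname(ref))
  } else {
    qset <- Biostrings::AAStringSet(unname(queries))
    subj <- Biostrings::AAString(unname(ref))
  }
  aln <- Biostrings::pairwiseAlignment(
    qset, subj, type = "local", substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_ext)
  sc <- Biostrings::score(aln)
  qs <- as.character(Biostrings::alignedPattern(aln))
  rs <- as.character(Biostrings::alignedSubject(aln))
  st <- vapply(seq_along(qs), function(i) .aln_stats(qs[i], rs[i]), numeric(2))
  hit <- sc > 0
  out <- data.frame(
    query_id = names(queries), ref_id = ref_id, score = ifelse(hit, sc, 0),
    hit = hit,
    q_start = Biostrings::start(Biostrings::pattern(aln)) - 1L,
    q_end = Biostrings::end(Biostrings::pattern(aln)),
    r_start = Biostrings::start(Biostrings::subject(aln)) - 1L,
    r_end = Biostrings::end(Biostrings::subject(aln)),
    alignable = as.integer(st[1, ]), mismatches = as.integer(st[2, ]),
    stringsAsFactors = FALSE)
  out$identity <- ifelse(out$alignable > 0, 1 - out$mismatches / out$alignable, NA)
  out[!hit, c("q_start", "q_end", "r_start", "r_end", "alignable", "mismatches")] <- 0L
  out$identity[!hit] <- NA
  out
}

#' Percent divergence of an alignment
#'
#' Divergence is the number of observed mismatches divided by the number of
#' alignable bases (columns where neither side is a gap); gap columns are
#' excluded from both numerator and denominator.
#'
#' @param aln a `"pw_align"` object from [local_align()].
#' @return fraction in \[0, 1\].
#' @export
percent_divergence <- function(aln) {
  stopifnot(inherits(aln, "pw_align"))
  if (aln$alignable == 0)
    stop("percent_divergence: undefined, alignment has no alignable bases")
  aln$mismatches / aln$alignable
}

#' Reverse complement
#' @param x character vector of DNA sequences.
#' @return reverse-complemented character vector (names preserved).
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Count k-mers on both strands
#'
#' Counts every k-length window of every sequence on both the forward and
#' reverse-complement strand (no canonicalisation: each literal k-mer is a
#' separate key).  Windows containing `N` are skipped and tallied.
#'
#' @param seqs character vector of sequences.
#' @param k k-mer length (default 15, the repeat soft-masking length).
#' @return object of class `"kmer_table"`: list with `k`, `counts` (named
#'   integer vector) and `skipped` (number of N-containing windows).
#' @export
count_kmers <- function(seqs, k = 15) {
  stopifnot(k >= 1)
  all_k <- character(0)
  skipped <- 0L
  for (s in c(unname(seqs), unname(revcomp(seqs)))) {
    n <- nchar(s)
    if (n < k) next
    w <- substring(s, 1:(n - k + 1), k:n)
    has_n <- grepl("N", w, fixed = TRUE)
    skipped <- skipped + sum(has_n)
    all_k <- c(all_k, w[!has_n])
  }
  counts <- if (length(all_k)) table(all_k) else table(character(0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(k = as.integer(k), counts = counts, skipped = skipped),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> k=%d, %d distinct k-mers, %d N-windows skipped\n",
              x$k, length(x$counts), x$skipped))
  invisible(x)
}

#' Look up k-mer frequencies of a sequence
#'
#' Returns the table frequency of each forward k-mer of `seq` (0 for absent
#' k-mers, NA for windows containing N).
#'
#' @param seq character scalar.
#' @param table a [count_kmers()] table.
#' @return integer vector of length `nchar(seq) - k + 1` (empty if shorter).
#' @export
kmer_frequencies <- function(seq, table) {
  stopifnot(inherits(table, "kmer_table"))
  n <- nchar(seq); k <- table$k
  if (n < k) return(integer(0))
  w <- substring(seq, 1:(n - k + 1), k:n)
  f <- unname(table$counts[w])
  f[is.na(f) & !grepl("N", w, fixed = TRUE)] <- 0L
  f
}

#' GC fraction of a sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); `N` is excluded from the denominator.
#'
#' @param seq character scalar (or vector; vectorised).
#' @return numeric in \[0, 1\] (NA impossible: all-N input is an error).
#' @export
gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    if (!nzchar(s)) stop("gc_fraction: empty sequence")
    b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    gc <- sum(b == "G" | b == "C")
    acgt <- sum(b %in% DNA_BASES)
    if (acgt == 0) stop("gc_fraction: undefined for all-N sequence")
    gc / acgt
  }, numeric(1), USE.NAMES = FALSE)
}

#' Phred quality / error probability conversions
#'
#' `phred_from_error(e)` returns \eqn{-10 \log_{10} e}; `error_from_phred(q)`
#' is its exact inverse \eqn{10^{-q/10}}.
#'
#' @param e error probability in (0, 1].
#' @param q Phred-scaled quality, `q >= 0`.
#' @return numeric vector.
#' @export
phred_from_error <- function(e) {
  if (any(e <= 0 | e > 1)) stop("phred_from_error: e must be in (0, 1]")
  -10 * log10(e)
}

#' @rdname phred_from_error
#' @export
error_from_phred <- function(q) {
  if (any(q < 0)) stop("error_from_phred: q must be >= 0")
  10^(-q / 10)
}

# ---- FASTA / FASTQ I/O ------------------------------------------------------

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings; sequences are returned as an uppercase
#' named character vector and written wrapped at 60 columns.
#'
#' @param path file path.
#' @param x named character vector of sequences.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  stopifnot(!is.null(names(x)))
  set <- Biostrings::BStringSet(unname(x))
  names(set) <- names(x)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read / write FASTQ (Phred+33)
#'
#' @param path file path.
#' @param bases,quals named character vectors (equal lengths); `quals` are
#'   Phred+33 encoded strings.
#' @return `read_fastq`: list with `bases` and `quals` named character vectors.
#' @export
read_fastq <- function(path) {
  # metadata-column drop notice from QualityScaledDNAStringSet is irrelevant
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  ids <- sub("\\s.*$", "", names(x))
  bases <- stats::setNames(as.character(x), ids)
  quals <- stats::setNames(as.character(Biostrings::quality(x)), ids)
  list(bases = bases, quals = quals)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(bases, quals, path) {
  stopifnot(length(bases) == length(quals), !is.null(names(bases)),
            all(nchar(bases) == nchar(quals)))
  lines <- character(4L * length(bases))
  lines[seq(1, by = 4, length.out = length(bases))] <- paste0("@", names(bases))
  lines[seq(2, by = 4, length.out = length(bases))] <- unname(bases)
  lines[seq(3, by = 4, length.out = length(bases))] <- "+"
  lines[seq(4, by = 4, length.out = length(bases))] <- unname(quals)
  writeLines(lines, path)
  invisible(path)
}

#' Encode/decode Phred+33 quality strings
#' @param q integer vector of qualities, or a Phred+33 string.
#' @return `qual_encode`: character scalar; `qual_decode`: integer vector.
#' @export
qual_encode <- function(q) intToUtf8(as.integer(q) + 33L)

#' @rdname qual_encode
#' @export
qual_decode <- function(q) utf8ToInt(q) - 33L

# run a block with a private, seeded RNG stream, restoring global state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}
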