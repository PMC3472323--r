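# ---- capture target definition from annotated transcripts ------------------

# default tiling step per target class (bp between probe starts)
CLASS_TILING_STEP <- c(nuclear_exon = 4L, mito = 20L, genomic_interval = 2L,
                       sry = 1L, control_gene = 4L)

TARGET_CLASSES <- names(CLASS_TILING_STEP)

# gene id convention: everything before the first "|" of a sequence id
gene_of <- function(id) sub("\\|.*$", "", id)

.six_frames <- function(seq) {
  # list of translated frames; each element carries strand and nt offset
  n <- nchar(seq)
  frames <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      len <- 3L * ((n - f) %/% 3L)
      if (len < 3L) next
      nt <- substr(s, f + 1L, f + len)
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(nt), if.fuzzy.codon = "X")))
      frames[[length(frames) + 1L]] <- list(strand = strand, offset = f, aa = aa)
    }
  }
  frames
}

#' Annotate a transcript contig against a protein set
#'
#' Six-frame translated local alignment of the contig against every protein;
#' the best hit above `min_score` wins (ties: first protein in input order,
#' forward strand before reverse, lower frame first).  CDS completeness is
#' classified from whether the protein's ends are reached by the alignment:
#' both ends -> `full_cds`; only the protein 3' end -> `partial_cds_3utr`;
#' only the 5' end -> `partial_cds_5utr`; neither -> `partial_cds_only`.
#' Terminal-residue slack of 2 aa tolerates end mismatches trimmed by local
#' alignment.
#'
#' @param contig named character scalar (transcript contig).
#' @param proteins named character vector of amino-acid sequences.  Ids before
#'   the first `|` are taken as gene ids.
#' @param min_score minimum alignment score to accept a hit (identity scoring,
#'   match = 1).
#' @param scoring protein alignment scoring ([align_scoring()]).
#' @param end_slack residues of slack when testing whether a protein end is
#'   covered.
#' @return A `"transcript_annotation"` list (`transcript_id`,
#'   `best_protein_id`, `gene_id`, `strand`, `frame`, `score`, `identity`,
#'   `cds_span` on the transcript in transcript orientation, 0-based
#'   half-open; `protein_span`; `completeness`), or `NULL` if no hit.
#' @export
annotate_transcript <- function(contig, proteins,
                                min_score = 50,
                                scoring = align_scoring(),
                                end_slack = 2L) {
  stopifnot(length(proteins) >= 1)
  hits <- annotate_all_hits(contig, proteins, min_score, scoring, end_slack)
  if (nrow(hits) == 0) return(NULL)
  best <- hits[order(-hits$score, match(hits$protein_id, names(proteins)),
                     hits$strand != "+", hits$frame), , drop = FALSE][1, ]
  structure(list(
    transcript_id = if (!is.null(names(contig))) names(contig)[1] else "contig",
    best_protein_id = best$protein_id,
    gene_id = gene_of(best$protein_id),
    strand = best$strand, frame = best$frame,
    score = best$score, identity = best$identity,
    cds_span = c(best$cds_start, best$cds_end),
    protein_span = c(best$p_start, best$p_end),
    completeness = best$completeness),
    class = "transcript_annotation")
}

#' All protein hits on a contig
#'
#' Like [annotate_transcript()] but returns every protein whose best frame
#' scores at or above the threshold; used for chimera detection.
#'
#' @inheritParams annotate_transcript
#' @return data.frame with one row per hit protein: `protein_id`, `gene_id`,
#'   `strand`, `frame`, `score`, `identity`, `cds_start`, `cds_end` (contig
#'   coordinates in transcript orientation), `p_start`, `p_end` (0-based
#'   half-open on the protein), `completeness`.
#' @export
annotate_all_hits <- function(contig, proteins, min_score = 50,
                              scoring = align_scoring(), end_slack = 2L) {
  seq <- unname(contig[1])
  n <- nchar(seq)
  frames <- .six_frames(seq)
  rows <- list()
  for (fr in frames) {
    res <- local_align_many(proteins, fr$aa, scoring, alphabet = "protein")
    res <- res[res$hit & res$score >= min_score, , drop = FALSE]
    if (nrow(res) == 0) next
    # aa span on frame -> nt span on the oriented contig
    nt_start <- fr$offset + 3L * res$r_start
    nt_end <- fr$offset + 3L * res$r_end
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = res$query_id, gene_id = gene_of(res$query_id),
      strand = fr$strand, frame = fr$offset, score = res$score,
      identity = res$identity,
      cds_start = nt_start, cds_end = nt_end,
      p_start = res$q_start, p_end = res$q_end,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(protein_id = character(0), gene_id = character(0),
                      strand = character(0), frame = integer(0),
                      score = numeric(0), identity = numeric(0),
                      cds_start = integer(0), cds_end = integer(0),
                      p_start = integer(0), p_end = integer(0),
                      completeness = character(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  # keep each protein's best frame only
  hits <- hits[order(-hits$score, hits$strand != "+", hits$frame), , drop = FALSE]
  hits <- hits[!duplicated(hits$protein_id), , drop = FALSE]
  plen <- nchar(proteins)[match(hits$protein_id, names(proteins))]
  start_cov <- hits$p_start <= end_slack
  end_cov <- hits$p_end >= plen - end_slack
  hits$completeness <- ifelse(start_cov & end_cov, "full_cds",
                       ifelse(end_cov, "partial_cds_3utr",
                       ifelse(start_cov, "partial_cds_5utr", "partial_cds_only")))
  rownames(hits) <- NULL
  hits
}

#' Detect a premature stop codon in an annotated CDS
#'
#' Translates the annotated CDS span (in transcript orientation) and reports
#' whether an in-frame stop occurs strictly before the final codon.
#'
#' @param transcript named character scalar.
#' @param annotation a `"transcript_annotation"`.
#' @return logical scalar.
#' @export
detect_premature_stop <- function(transcript, annotation) {
  stopifnot(inherits(annotation, "transcript_annotation"))
  seq <- unname(transcript[1])
  if (annotation$strand == "-") seq <- revcomp(seq)
  span <- annotation$cds_span
  cds <- substr(seq, span[1] + 1L, span[2])
  if (nchar(cds) < 3) stop("detect_premature_stop: cds_span shorter than 3")
  len <- 3L * (nchar(cds) %/% 3L)
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, len)), if.fuzzy.codon = "X")))
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  any(stops > 0 & stops < nchar(aa))
}

#' Detect a chimeric contig
#'
#' A contig is flagged chimeric when accepted protein hits from two different
#' genes occupy essentially non-overlapping spans of the contig (overlap
#' < 10% of the shorter span), i.e. two distinct transcripts were spuriously
#' joined during assembly.
#'
#' @inheritParams annotate_transcript
#' @param max_overlap_frac maximum span overlap (fraction of the shorter
#'   span) for two hits to count as distinct.
#' @return logical scalar.
#' @export
detect_chimeric_contig <- function(contig, proteins, min_score = 50,
                                   scoring = align_scoring(),
                                   max_overlap_frac = 0.1) {
  hits <- annotate_all_hits(contig, proteins, min_score, scoring)
  if (nrow(hits) < 2) return(FALSE)
  for (i in seq_len(nrow(hits) - 1)) {
    for (j in (i + 1):nrow(hits)) {
      if (hits$gene_id[i] == hits$gene_id[j]) next
      ov <- min(hits$cds_end[i], hits$cds_end[j]) -
        max(hits$cds_start[i], hits$cds_start[j])
      shorter <- min(hits$cds_end[i] - hits$cds_start[i],
                     hits$cds_end[j] - hits$cds_start[j])
      if (ov < max_overlap_frac * shorter) return(TRUE)
    }
  }
  FALSE
}

#' Transfer reference exon boundaries onto a transcript
#'
#' Each reference exon (given in gene order) is locally aligned to the
#' transcript; a placement is accepted when the alignment covers at least
#' `min_cov` of the reference exon at identity at least `min_identity`.
#' Accepted placements must be non-overlapping and colinear with exon order;
#' conflicts are resolved by greedily keeping higher-scoring exons.
#'
#' @param transcript named character scalar.
#' @param reference_exons named character vector, in gene order (ids
#'   conventionally `gene|exon_k`).
#' @param min_cov minimum fraction of the reference exon covered.
#' @param min_identity minimum alignment identity.
#' @param scoring DNA alignment scoring.
#' @return data.frame of exon placements: `target_id`, `source_seq_id`,
#'   `start`, `end` (0-based half-open on the transcript), `exon_index`,
#'   `score`, `identity`, `sequence`, `target_class = "nuclear_exon"`.
#' @export
transfer_exon_boundaries <- function(transcript, reference_exons,
                                     min_cov = 0.8, min_identity = 0.7,
                                     scoring = align_scoring()) {
  tid <- if (!is.null(names(transcript))) names(transcript)[1] else "transcript"
  seq <- unname(transcript[1])
  res <- local_align_many(reference_exons, seq, scoring)
  res$exon_index <- seq_len(nrow(res))
  exlen <- nchar(reference_exons)
  cov <- (res$q_end - res$q_start) / exlen
  ok <- res$hit & cov >= min_cov & !is.na(res$identity) &
    res$identity >= min_identity
  # project the exon ends through the alignment: terminal mismatches trimmed
  # by local alignment are restored so boundaries land on the true exon extent
  res$r_start <- pmax(0L, res$r_start - res$q_start)
  res$r_end <- pmin(nchar(seq), res$r_end + (exlen - res$q_end))
  cand <- res[ok, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(target_id = character(0), source_seq_id = character(0),
                      start = integer(0), end = integer(0),
                      exon_index = integer(0), score = numeric(0),
                      identity = numeric(0), sequence = character(0),
                      target_class = character(0), stringsAsFactors = FALSE))
  }
  # greedy by score: keep a candidate only if it neither overlaps a kept span
  # nor breaks colinearity (span order must follow exon order)
  cand <- cand[order(-cand$score, cand$exon_index), , drop = FALSE]
  kept <- cand[0, , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    x <- cand[i, ]
    conflict <- FALSE
    if (nrow(kept) > 0) {
      ov <- pmin(kept$r_end, x$r_end) - pmax(kept$r_start, x$r_start)
      order_bad <- (kept$exon_index < x$exon_index & kept$r_start >= x$r_start) |
        (kept$exon_index > x$exon_index & kept$r_start <= x$r_start)
      conflict <- any(ov > 0) || any(order_bad)
    }
    if (!conflict) kept <- rbind(kept, x)
  }
  kept <- kept[order(kept$exon_index), , drop = FALSE]
  n <- nrow(kept)
  if (n > 1 && any(kept$r_start[-1] < kept$r_end[-n]))
    stop("transfer_exon_boundaries: overlapping spans after resolution")
  data.frame(
    target_id = paste0(tid, "|", kept$query_id),
    source_seq_id = tid,
    start = kept$r_start, end = kept$r_end,
    exon_index = kept$exon_index, score = kept$score,
    identity = kept$identity,
    sequence = substring(seq, kept$r_start + 1L, kept$r_end),
    target_class = "nuclear_exon", stringsAsFactors = FALSE)
}

#' Build the multi-class capture target set
#'
#' Combines nuclear exon targets with extra target classes (mitochondrial,
#' anonymous genomic intervals, SRY, control genes).  Nuclear exons shorter
#' than `min_length` are dropped (the count is reported); extra classes pass
#' unfiltered.  Targets with exactly identical sequences are deduplicated
#' (first occurrence wins).
#'
#' @param exon_targets data.frame(s) as returned by
#'   [transfer_exon_boundaries()] (a list is rbind-ed).
#' @param extra_targets optional data.frame with columns `target_id`,
#'   `sequence`, `target_class` (one of `mito`, `genomic_interval`, `sry`,
#'   `control_gene`) and optionally `source_seq_id`.
#' @param min_length minimum nuclear exon length (default 200).
#' @return object of class `"target_set"`: list with `targets` (data.frame:
#'   `target_id`, `source_seq_id`, `start`, `end`, `length`, `gc`,
#'   `target_class`, `tiling_step`, `sequence`), `n_dropped_short`,
#'   `n_dropped_dup`, and `class_counts`.
#' @export
build_target_set <- function(exon_targets = NULL, extra_targets = NULL,
                             min_length = 200) {
  cols <- c("target_id", "source_seq_id", "start", "end", "sequence",
            "target_class")
  pieces <- list()
  if (!is.null(exon_targets)) {
    if (is.data.frame(exon_targets)) exon_targets <- list(exon_targets)
    for (df in exon_targets) {
      if (nrow(df) == 0) next
      pieces[[length(pieces) + 1L]] <- df[, intersect(cols, names(df))]
    }
  }
  if (!is.null(extra_targets) && nrow(extra_targets) > 0) {
    ex <- extra_targets
    if (is.null(ex$source_seq_id)) ex$source_seq_id <- ex$target_id
    if (is.null(ex$start)) ex$start <- 0L
    if (is.null(ex$end)) ex$end <- nchar(ex$sequence)
    stopifnot(all(ex$target_class %in% setdiff(TARGET_CLASSES, "nuclear_exon")))
    pieces[[length(pieces) + 1L]] <- ex[, cols]
  }
  if (length(pieces) == 0) stop("build_target_set: no targets supplied")
  all <- do.call(rbind, lapply(pieces, function(p) {
    for (m in setdiff(cols, names(p))) p[[m]] <- NA
    p[, cols]
  }))
  if (anyDuplicated(all$target_id))
    stop("build_target_set: duplicate target_id: ",
         paste(unique(all$target_id[duplicated(all$target_id)]), collapse = ", "))
  all$length <- nchar(all$sequence)
  short <- all$target_class == "nuclear_exon" & all$length < min_length
  n_short <- sum(short)
  all <- all[!short, , drop = FALSE]
  dup <- duplicated(all$sequence)
  n_dup <- sum(dup)
  all <- all[!dup, , drop = FALSE]
  if (nrow(all) == 0) stop("build_target_set: no targets retained")
  all$gc <- gc_fraction(all$sequence)
  all$tiling_step <- unname(CLASS_TILING_STEP[all$target_class])
  rownames(all) <- NULL
  structure(list(
    targets = all[, c("target_id", "source_seq_id", "start", "end", "length",
                      "gc", "target_class", "tiling_step", "sequence")],
    min_length = min_length,
    n_dropped_short = n_short, n_dropped_dup = n_dup,
    class_counts = table(all$target_class)),
    class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> %d targets (%d short exons dropped, %d duplicates)\n",
              nrow(x$targets), x$n_dropped_short, x$n_dropped_dup))
  print(x$class_counts)
  invisible(x)
}

#' Write targets as BED and FASTA
#'
#' BED is 0-based half-open with `name = target_id` and `score` = integer
#' class code (position of the class in the canonical class order).
#'
#' @param target_set a [build_target_set()] result.
#' @param bed_path,fasta_path output paths (either may be NULL).
#' @export
write_targets <- function(target_set, bed_path = NULL, fasta_path = NULL) {
  t <- target_set$targets
  if (!is.null(bed_path)) {
    bed <- data.frame(t$source_seq_id, t$start, t$end, t$target_id,
                      match(t$target_class, TARGET_CLASSES), "+")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(fasta_path))
    write_fasta(stats::setNames(t$sequence, t$target_id), fasta_path)
  invisible(target_set)
}

#' Transcriptome QC table
#'
#' Per-transcript annotation status, completeness class, premature-stop and
#' chimera flags for a set of contigs against a protein database.
#'
#' @param transcripts named character vector.
#' @param proteins named character vector of proteins.
#' @param min_score annotation score threshold.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `annotated`, `best_protein_id`, `completeness`, `premature_stop`,
#'   `chimeric`.
#' @export
transcriptome_qc <- function(transcripts, proteins, min_score = 50) {
  rows <- lapply(names(transcripts), function(id) {
    tr <- transcripts[id]
    ann <- annotate_transcript(tr, proteins, min_score)
    if (is.null(ann)) {
      data.frame(transcript_id = id, annotated = FALSE,
                 best_protein_id = NA_character_, completeness = NA_character_,
                 premature_stop = NA, chimeric = NA, stringsAsFactors = FALSE)
    } else {
      data.frame(transcript_id = id, annotated = TRUE,
                 best_protein_id = ann$best_protein_id,
                 completeness = ann$completeness,
                 premature_stop = detect_premature_stop(tr, ann),
                 chimeric = detect_chimeric_contig(tr, proteins, min_score),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
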