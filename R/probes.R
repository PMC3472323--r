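# ---- tiling probe design and repeat soft-masking ----------------------------

#' Array design configuration
#'
#' @param probe_len probe length in bp (60 for 1M-feature arrays).
#' @param steps named integer vector of tiling steps per target class.
#' @param edge_step tiling step inside the edge windows of nuclear exons.
#' @param edge_window width (bp) of the densified window at each exon end.
#' @param mask_k k-mer length for repeat soft-masking.
#' @param mask_threshold k-mer frequency at or above which a probe is masked.
#' @param capacity maximum number of retained probes the array can hold.
#' @return list of class `"design_config"`.
#' @export
design_config <- function(probe_len = 60L, steps = CLASS_TILING_STEP,
                          edge_step = 1L, edge_window = 30L,
                          mask_k = 15L, mask_threshold = 50L,
                          capacity = 1000000L) {
  stopifnot(probe_len > 0, capacity > 0, mask_k <= probe_len)
  structure(list(probe_len = as.integer(probe_len), steps = steps,
                 edge_step = as.integer(edge_step),
                 edge_window = as.integer(edge_window),
                 mask_k = as.integer(mask_k),
                 mask_threshold = as.integer(mask_threshold),
                 capacity = as.integer(capacity)),
            class = "design_config")
}

#' Tile probes across one target
#'
#' Interior probes start at offsets `0, step, 2*step, ...`; a terminal probe
#' flush with the target end is always included.  For nuclear exon targets
#' every offset in `[0, edge_window)` and `(L - probe_len - edge_window,
#' L - probe_len]` is additionally emitted at `edge_step = 1` (edge
#' densification, compensating for the impossibility of tiling into unknown
#' introns).  Duplicate offsets are removed and output is sorted by offset.
#'
#' @param sequence target sequence (character scalar).
#' @param target_id id recorded on the probes.
#' @param target_class one of the canonical classes; determines the default
#'   step and whether edges are densified.
#' @param probe_len,step,edge_step,edge_window see [design_config()];
#'   `step = NULL` uses the class default.
#' @return data.frame with `probe_id` (`target_id|offset`), `target_id`,
#'   `offset` (0-based), `length`, `sequence`, `gc`, `tiling_origin`
#'   (`interior`/`edge`), or NULL (with a warning) for targets shorter than
#'   `probe_len`.
#' @export
tile_target <- function(sequence, target_id = "target",
                        target_class = "nuclear_exon",
                        probe_len = 60L, step = NULL,
                        edge_step = 1L, edge_window = 30L) {
  L <- nchar(sequence)
  if (L < probe_len) {
    warning(sprintf("target %s (%d bp) shorter than probe length %d: skipped",
                    target_id, L, probe_len))
    return(NULL)
  }
  if (is.null(step)) step <- unname(CLASS_TILING_STEP[target_class])
  last <- L - probe_len
  offsets <- unique(c(seq.int(0L, last, by = step), last))
  origin <- rep("interior", length(offsets))
  if (target_class == "nuclear_exon" && edge_window > 0) {
    lo <- seq.int(0L, min(edge_window - 1L, last), by = edge_step)
    hi <- seq.int(max(0L, last - edge_window + 1L), last, by = edge_step)
    edge <- setdiff(unique(c(lo, hi)), offsets)
    offsets <- c(offsets, edge)
    origin <- c(origin, rep("edge", length(edge)))
  }
  ord <- order(offsets)
  offsets <- as.integer(offsets[ord]); origin <- origin[ord]
  seqs <- substring(sequence, offsets + 1L, offsets + probe_len)
  data.frame(probe_id = paste0(target_id, "|", offsets),
             target_id = target_id, offset = offsets,
             length = probe_len, sequence = seqs, gc = gc_fraction(seqs),
             tiling_origin = origin, stringsAsFactors = FALSE)
}

#' Soft-mask probes by k-mer frequency
#'
#' A probe is masked iff any of its `length - k + 1` k-mers occurs in the
#' reference k-mer table at a frequency of `threshold` or greater (the table
#' itself counts both strands of the reference, so forward probe k-mers
#' suffice).
#'
#' @param probes data.frame from [tile_target()] (rbind-able).
#' @param table a [count_kmers()] table built on the masking reference.
#' @param threshold masking frequency cutoff (default 50).
#' @return list with `retained` and `masked` data.frames (each the input rows
#'   plus a `masked` column) and `counts = c(designed, masked, retained)`.
#' @export
soft_mask_probes <- function(probes, table, threshold = 50L) {
  stopifnot(inherits(table, "kmer_table"))
  masked <- vapply(probes$sequence, function(s) {
    f <- kmer_frequencies(s, table)
    any(!is.na(f) & f >= threshold)
  }, logical(1), USE.NAMES = FALSE)
  probes$masked <- masked
  list(retained = probes[!masked, , drop = FALSE],
       masked = probes[masked, , drop = FALSE],
       counts = c(designed = nrow(probes), masked = sum(masked),
                  retained = sum(!masked)))
}

#' Design the full capture array
#'
#' Tiles every target with its class-specific step (edge densification for
#' nuclear exons), soft-masks probes against a 15-mer frequency table built
#' from the masking reference (design transcriptome plus any auxiliary
#' genome), and enforces the array's probe capacity.
#'
#' @param target_set a [build_target_set()] result.
#' @param masking_reference named character vector of reference sequences for
#'   k-mer counting (NULL disables masking).
#' @param config a [design_config()].
#' @return object of class `"probe_set"`: list with `probes` (retained,
#'   with `masked = FALSE`), `masked_probes`, `config`, `counts`, and
#'   `per_class` count table.
#' @export
design_array <- function(target_set, masking_reference = NULL,
                         config = design_config()) {
  stopifnot(inherits(target_set, "target_set"))
  t <- target_set$targets
  if (nrow(t) == 0) stop("design_array: empty target set")
  tiles <- vector("list", nrow(t))
  for (i in seq_len(nrow(t))) {
    tiles[[i]] <- tile_target(
      t$sequence[i], t$target_id[i], t$target_class[i],
      probe_len = config$probe_len,
      step = unname(config$steps[t$target_class[i]]),
      edge_step = config$edge_step, edge_window = config$edge_window)
  }
  probes <- do.call(rbind, tiles[!vapply(tiles, is.null, logical(1))])
  if (is.null(probes) || nrow(probes) == 0)
    stop("design_array: no probes could be tiled")
  probes$target_class <- t$target_class[match(probes$target_id, t$target_id)]
  if (!is.null(masking_reference)) {
    tab <- count_kmers(masking_reference, k = config$mask_k)
    part <- soft_mask_probes(probes, tab, config$mask_threshold)
  } else {
    probes$masked <- FALSE
    part <- list(retained = probes, masked = probes[0, , drop = FALSE],
                 counts = c(designed = nrow(probes), masked = 0L,
                            retained = nrow(probes)))
  }
  if (part$counts[["retained"]] > config$capacity)
    stop(sprintf(
      "design_array: %d retained probes exceed array capacity %d (overflow %d)",
      part$counts[["retained"]], config$capacity,
      part$counts[["retained"]] - config$capacity))
  per_class <- table(part$retained$target_class)
  structure(list(probes = part$retained, masked_probes = part$masked,
                 config = config, counts = part$counts,
                 per_class = per_class),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> %d designed, %d masked, %d retained (capacity %d)\n",
              x$counts[["designed"]], x$counts[["masked"]],
              x$counts[["retained"]], x$config$capacity))
  print(x$per_class)
  invisible(x)
}

#' Write a probe set as FASTA and TSV
#'
#' FASTA headers are `target_id|offset`; the TSV lists probe id, target,
#' offset, GC and mask status for all designed probes, and the report TSV
#' per-class designed/masked/retained counts.
#'
#' @param probe_set a [design_array()] result.
#' @param fasta_path,tsv_path,report_path output paths (any may be NULL).
#' @export
write_probes <- function(probe_set, fasta_path = NULL, tsv_path = NULL,
                         report_path = NULL) {
  all <- rbind(probe_set$probes, probe_set$masked_probes)
  all <- all[order(all$target_id, all$offset), , drop = FALSE]
  if (!is.null(fasta_path)) {
    keep <- probe_set$probes
    write_fasta(stats::setNames(keep$sequence, keep$probe_id), fasta_path)
  }
  if (!is.null(tsv_path))
    utils::write.table(
      all[, c("probe_id", "target_id", "offset", "gc", "masked")],
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report_path)) {
    rep <- as.data.frame(table(all$target_class, all$masked))
    names(rep) <- c("target_class", "masked", "n")
    utils::write.table(rep, report_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(probe_set)
}
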