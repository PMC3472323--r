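# ---- SNP detection, zygosity, functional classification --------------------

FUNC_CLASSES <- c("synonymous", "non_synonymous", "intron", "utr")

#' Binomial site quality
#'
#' Phred-scaled confidence that the discordant bases of a pileup column are
#' not all sequencing error: \eqn{-10\log_{10} P(X \ge k)} for
#' \eqn{X \sim Binom(n, e)} with `n` the depth, `k` the discordant count
#' (`depth - concordant`) and `e` the column's mean base-quality error rate.
#' Capped at 2000.
#'
#' @param depth column depth.
#' @param concordant count of bases agreeing with the reference (or, absent
#'   a reference, with the within-stack majority).
#' @param mean_qual mean Phred base quality of the column.
#' @return numeric quality (0 when `k = 0`).
#' @export
site_quality <- function(depth, concordant, mean_qual) {
  k <- depth - concordant
  e <- error_from_phred(mean_qual)
  p <- stats::pbinom(k - 1, depth, e, lower.tail = FALSE)
  q <- -10 * log10(pmax(p, 1e-300))
  pmin(q, 2000)
}

#' Call candidate variant sites from a pileup
#'
#' A column is a candidate iff `min_depth <= depth <= max_depth`, it carries
#' at least one discordant base, and its [site_quality()] reaches
#' `min_site_quality`.  When reference contigs are supplied, "discordant"
#' means differing from the reference base — so homozygous fixed differences
#' (all reads carrying the alternate allele) score as strong candidates;
#' without a reference the within-stack non-majority count is used (which
#' can only surface polymorphic columns).  Pileups must be built from
#' uniquely mapped, non-duplicate reads ([pileup()] enforces this).
#'
#' @param pile a [pileup()].
#' @param ref_contigs optional named character vector of reference contigs.
#' @param min_depth,max_depth depth window (20 / 5000).
#' @param min_site_quality Phred site-quality floor (30).
#' @return data.frame `contig_id`, `pos`, `depth`, `A`, `C`, `G`, `T`, `N`,
#'   `mean_qual`, `site_quality`.
#' @export
call_sites <- function(pile, ref_contigs = NULL, min_depth = 20L,
                       max_depth = 5000L, min_site_quality = 30) {
  p <- pile[pile$depth >= min_depth & pile$depth <= max_depth, , drop = FALSE]
  if (nrow(p) == 0) {
    out <- cbind(p[, c("contig_id", "pos", "depth", "A", "C", "G", "T", "N")],
                 mean_qual = numeric(0), site_quality = numeric(0))
    return(out)
  }
  if (is.null(ref_contigs)) {
    concordant <- pmax(p$A, p$C, p$G, p$T)
  } else {
    ref <- substr(ref_contigs[p$contig_id], p$pos + 1L, p$pos + 1L)
    cnt <- as.matrix(p[, c("A", "C", "G", "T")])
    idx <- match(ref, c("A", "C", "G", "T"))
    concordant <- ifelse(is.na(idx), 0L, cnt[cbind(seq_len(nrow(p)), idx)])
  }
  p$mean_qual <- p$qual_sum / p$depth
  p$site_quality <- site_quality(p$depth, concordant, p$mean_qual)
  keep <- (p$depth - concordant) > 0 & p$site_quality >= min_site_quality
  out <- p[keep, c("contig_id", "pos", "depth", "A", "C", "G", "T", "N",
                   "mean_qual", "site_quality")]
  rownames(out) <- NULL
  out
}

#' Classify the zygosity of a candidate column
#'
#' Within a pooled species pileup: the site is `polymorphic` iff the second
#' most frequent allele has at least `min_alt_reads` reads and a fraction of
#' at least `alt_frac_poly`; otherwise it is `fixed` iff the species
#' consensus allele (fraction >= `consensus_frac`) differs from the reference
#' base; otherwise `invariant`.
#'
#' @param counts named numeric vector of base counts (`A`,`C`,`G`,`T`).
#' @param ref_base reference base at the column.
#' @param alt_frac_poly minor-allele fraction for polymorphism.
#' @param consensus_frac consensus fraction for a fixed difference.
#' @param min_alt_reads minimum minor-allele reads for polymorphism.
#' @return list with `status` (`polymorphic`/`fixed`/`invariant`) and `alt`
#'   (the non-reference allele, or NA for invariant sites).
#' @export
classify_zygosity <- function(counts, ref_base, alt_frac_poly = 0.2,
                              consensus_frac = 0.9, min_alt_reads = 2L) {
  counts <- counts[c("A", "C", "G", "T")]
  depth <- sum(counts)
  ord <- order(-counts, names(counts))
  top <- names(counts)[ord[1]]; second <- names(counts)[ord[2]]
  if (depth > 0 && counts[second] >= min_alt_reads &&
      counts[second] / depth >= alt_frac_poly) {
    alt <- if (top != ref_base) top else second
    return(list(status = "polymorphic", alt = alt))
  }
  if (depth > 0 && counts[top] / depth >= consensus_frac && top != ref_base)
    return(list(status = "fixed", alt = top))
  list(status = "invariant", alt = NA_character_)
}

#' Build a gene model table
#'
#' @param contig_id contig the features live on.
#' @param feature one of `cds`, `intron`, `utr5`, `utr3`.
#' @param start,end 0-based half-open spans (non-overlapping).
#' @param frame for `cds` rows: offset from `start` to the first complete
#'   codon (0/1/2, GFF convention); NA otherwise.
#' @param strand `"+"` or `"-"`.
#' @return data.frame gene model.
#' @export
gene_model <- function(contig_id, feature, start, end, frame = NA_integer_,
                       strand = "+") {
  stopifnot(all(feature %in% c("cds", "intron", "utr5", "utr3")))
  n <- length(feature)
  data.frame(contig_id = rep_len(contig_id, n), feature = feature,
             start = as.integer(start), end = as.integer(end),
             frame = rep_len(as.integer(frame), n),
             strand = rep_len(strand, n), stringsAsFactors = FALSE)
}

.codon_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify the functional effect of a substitution
#'
#' Positions inside a CDS feature are translated with the standard genetic
#' code in the annotated frame: same amino acid = `synonymous`, otherwise
#' `non_synonymous`.  Intron and UTR positions are labelled by their
#' containing feature (both UTRs collapse to `utr`).  Positions in no
#' feature, or whose codon is not fully contained in one CDS feature, return
#' `unclassified`.
#'
#' @param contig_seq sequence of the contig (plus strand).
#' @param pos 0-based position of the substitution.
#' @param ref,alt reference and alternate base (plus strand).
#' @param model a [gene_model()] for the contig.
#' @return character scalar.
#' @export
classify_function <- function(contig_seq, pos, ref, alt, model) {
  row <- model[model$start <= pos & pos < model$end, , drop = FALSE]
  if (nrow(row) == 0) return("unclassified")
  row <- row[1, ]
  if (row$feature == "intron") return("intron")
  if (row$feature %in% c("utr5", "utr3")) return("utr")
  # cds: locate the codon in the annotated frame
  if (row$strand == "-") {
    # work on the reverse complement coordinate system
    L <- nchar(contig_seq)
    rc <- revcomp(contig_seq)
    comp <- function(b) chartr("ACGTN", "TGCAN", b)
    m2 <- row
    m2$start <- L - row$end; m2$end <- L - row$start; m2$strand <- "+"
    return(classify_function(rc, L - 1L - pos, comp(ref), comp(alt), m2))
  }
  first_codon <- row$start + row$frame
  phase <- (pos - first_codon) %% 3L
  codon_start <- pos - phase
  if (codon_start < row$start || codon_start + 3L > row$end)
    return("unclassified")
  codon <- substr(contig_seq, codon_start + 1L, codon_start + 3L)
  if (substr(codon, phase + 1L, phase + 1L) != ref)
    warning("classify_function: reference base does not match contig")
  alt_codon <- codon
  substr(alt_codon, phase + 1L, phase + 1L) <- alt
  aa_ref <- .codon_translate(codon); aa_alt <- .codon_translate(alt_codon)
  if (is.na(aa_ref) || is.na(aa_alt)) return("unclassified")
  if (aa_ref == aa_alt) "synonymous" else "non_synonymous"
}

#' Call and classify SNPs for one species
#'
#' Runs [call_sites()] on the species pileup against the shared reference,
#' classifies zygosity against the reference base and functional class
#' against the gene models, and returns the filtered SNP records.
#'
#' @param pile species [pileup()] on the reference in-target assemblies.
#' @param ref_contigs named character vector: the reference contigs.
#' @param models a [gene_model()] table covering the reference contigs.
#' @param species species label recorded on the records.
#' @param min_depth,max_depth,min_site_quality see [call_sites()].
#' @param ... passed to [classify_zygosity()].
#' @return data.frame of SNP records: `contig_id`, `pos`, `ref`, `alt`,
#'   `species`, `status`, `func_class`, `depth`, `site_quality`.
#' @export
call_snps <- function(pile, ref_contigs, models, species = "species",
                      min_depth = 20L, max_depth = 5000L,
                      min_site_quality = 30, ...) {
  cand <- call_sites(pile, ref_contigs, min_depth, max_depth,
                     min_site_quality)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    cid <- cand$contig_id[i]; pos <- cand$pos[i]
    ref <- substr(ref_contigs[[cid]], pos + 1L, pos + 1L)
    zyg <- classify_zygosity(
      c(A = cand$A[i], C = cand$C[i], G = cand$G[i], T = cand$T[i]), ref, ...)
    if (zyg$status == "invariant" || is.na(zyg$alt) || zyg$alt == ref) next
    fc <- classify_function(ref_contigs[[cid]], pos, ref, zyg$alt,
                            models[models$contig_id == cid, , drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = cid, pos = pos, ref = ref, alt = zyg$alt,
      species = species, status = zyg$status, func_class = fc,
      depth = cand$depth[i], site_quality = cand$site_quality[i],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(contig_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      species = character(0), status = character(0),
                      func_class = character(0), depth = integer(0),
                      site_quality = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Summarise SNP counts for one species
#'
#' Cross-tabulates fixed and polymorphic SNPs by functional class, with the
#' "total difference" row block (fixed + polymorphic per class) and
#' percentages of the grand total rounded to 1 decimal place.
#'
#' @param fixed,polymorphic named numeric vectors of counts with names among
#'   `synonymous`, `non_synonymous`, `intron`, `utr` (missing classes are 0).
#' @return list of class `"snp_summary"`: `fixed`, `polymorphic`,
#'   `total_difference` (each a named vector with a `total` element) and
#'   `percent` (per-class share of the grand total, 1 d.p.).
#' @export
snp_summary_counts <- function(fixed = numeric(0), polymorphic = numeric(0)) {
  fill <- function(x) {
    out <- stats::setNames(numeric(length(FUNC_CLASSES)), FUNC_CLASSES)
    out[names(x)] <- x
    out
  }
  f <- fill(fixed); p <- fill(polymorphic)
  td <- f + p
  grand <- sum(td)
  pct <- if (grand > 0) round(100 * td / grand, 1) else td * NA
  structure(list(fixed = c(f, total = sum(f)),
                 polymorphic = c(p, total = sum(p)),
                 total_difference = c(td, total = grand),
                 percent = pct),
            class = "snp_summary")
}

#' Summarise SNP records (one or more species)
#'
#' @param records SNP record data.frame from [call_snps()] (rows with
#'   `func_class = "unclassified"` are excluded).
#' @return named list of `"snp_summary"` objects, one per species.
#' @export
summarize_snps <- function(records) {
  records <- records[records$func_class %in% FUNC_CLASSES, , drop = FALSE]
  split_by <- split(records, records$species)
  lapply(split_by, function(r) {
    tab <- function(st) {
      x <- table(factor(r$func_class[r$status == st], levels = FUNC_CLASSES))
      stats::setNames(as.numeric(x), FUNC_CLASSES)
    }
    snp_summary_counts(fixed = tab("fixed"), polymorphic = tab("polymorphic"))
  })
}

#' @export
print.snp_summary <- function(x, ...) {
  m <- rbind(fixed = x$fixed, polymorphic = x$polymorphic,
             total_difference = x$total_difference)
  print(m)
  cat("percent of total difference:\n")
  print(x$percent)
  invisible(x)
}

#' Orthologous loci shared across species
#'
#' Loci (targets) present in every species' in-target map.
#'
#' @param maps list of [identify_in_target()] maps (>= 2).
#' @return character vector of shared target ids.
#' @export
shared_orthologs <- function(maps) {
  stopifnot(length(maps) >= 2)
  Reduce(intersect, lapply(maps, function(m) m$target_id))
}

#' Write SNP records as a minimal VCF
#'
#' One file per species is conventional; INFO carries `STATUS` and `CLASS`.
#'
#' @param records SNP records ([call_snps()]).
#' @param path output path.
#' @param sample_name value for the optional sample column header comment.
#' @export
write_snp_vcf <- function(records, path, sample_name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"fixed or polymorphic\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"functional class\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(records) > 0)
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t%.1f\tPASS\tSTATUS=%s;CLASS=%s;DP=%d",
      records$contig_id, records$pos + 1L, records$ref, records$alt,
      records$site_quality, records$status, records$func_class,
      records$depth), con)
  invisible(path)
}
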