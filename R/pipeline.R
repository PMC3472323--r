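# ---- stage orchestration ----------------------------------------------------

STAGES <- c("simulate", "design", "readqc", "assemble-merge", "intarget",
            "eval", "errors", "variants")

.log_line <- function(con, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  json <- paste0("{", paste(sprintf(
    '"%s":%s', names(rec),
    vapply(rec, function(v) {
      if (is.character(v)) sprintf('"%s"', v) else format(v, digits = 12)
    }, character(1))), collapse = ","), "}")
  writeLines(json, con)
}

.cfg_get <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

.need_path <- function(config, key) {
  p <- config[[key]]
  if (is.null(p) || !file.exists(p))
    stop(sprintf("config error: required input '%s' missing or not found", key),
         call. = FALSE)
  p
}

#' Run one pipeline stage
#'
#' Thin orchestration over the package's functions: each stage reads its
#' inputs from `config` paths/values, writes its artifacts under `out_dir`,
#' and appends JSON-lines progress records to `log.jsonl`.  Stages:
#'
#' * `simulate`: write a full simulated experiment (FASTA/FASTQ/SAM/TSV).
#' * `design`: targets FASTA in, probe FASTA/TSV + design report out.
#' * `readqc`: FASTQ pair + barcode map in, filtered FASTQ + report out.
#' * `assemble-merge`: raw assembly FASTAs in, merged FASTA + stats out.
#' * `intarget`: contigs + targets FASTA in, in-target map TSV out.
#' * `eval`: SAM + in-target map in, capture metrics TSV out.
#' * `errors`: SAM + haploid contig list in, error-rate TSV out.
#' * `variants`: SAM + reference FASTA + gene model TSV in, VCF + summary out.
#'
#' @param stage one of the stage names above.
#' @param config named list of paths and parameters (unknown keys rejected).
#' @param out_dir output directory (created).
#' @return invisible list of produced artifact paths.
#' @export
run_stage <- function(stage, config = list(), out_dir = ".") {
  stage <- match.arg(stage, STAGES)
  known <- c("seed", "targets_fasta", "mask_fasta", "capacity",
             "mask_threshold", "edge_window", "fastq1", "fastq2",
             "barcodes_tsv", "adapters", "contaminant_fasta", "min_q",
             "min_len", "assemblies", "contigs_fasta", "sam", "map_tsv",
             "min_depth", "max_depth", "min_site_quality", "haploid_contigs",
             "gene_model_tsv", "reference_fasta", "species", "subsample_n",
             "n_genes", "divergence", "n_samples")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("config error: unknown keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file(file.path(out_dir, "log.jsonl"), "a")
  on.exit(close(log))
  seed <- .cfg_get(config, "seed", 1L)
  arts <- character(0)
  art <- function(name) {
    p <- file.path(out_dir, name)
    arts <<- c(arts, p)
    p
  }
  if (stage == "simulate") {
    cfg <- sim_config(seed = seed,
                      n_genes = .cfg_get(config, "n_genes", 20L))
    space <- simulate_gene_space(cfg)
    sp <- evolve_species(space, .cfg_get(config, "divergence", 0.006),
                         cfg$heterozygosity, seed + 1L, "sim")
    samples <- sim_samples(.cfg_get(config, "n_samples", 2L), "sim")
    reads <- simulate_capture_reads(sp, space, samples, cfg)
    write_fasta(space$transcripts, art("transcripts.fasta"))
    write_fasta(space$proteins, art("proteins.fasta"))
    write_fasta(space$ref_exons, art("ref_exons.fasta"))
    write_fasta(reads$contigs, art("contigs.fasta"))
    p <- reads$pairs
    ids <- paste0(p$pair_id, "#", p$barcode)  # barcode travels in the id
    write_fastq(stats::setNames(p$bases1, ids),
                stats::setNames(p$quals1, ids), art("reads_1.fastq"))
    write_fastq(stats::setNames(p$bases2, ids),
                stats::setNames(p$quals2, ids), art("reads_2.fastq"))
    utils::write.table(samples[, c("sample_id", "barcode")],
                       art("barcodes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_sam(reads$aln, reads$contigs, art("truth.sam"))
    write_in_target_map(reads$in_target_map, art("in_target_map.tsv"))
    utils::write.table(samples, art("samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(space$models, art("gene_models.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .log_line(log, stage, n_pairs = nrow(p), n_contigs = length(reads$contigs))
  } else if (stage == "design") {
    targets <- read_fasta(.need_path(config, "targets_fasta"))
    tdf <- data.frame(target_id = names(targets), sequence = unname(targets),
                      target_class = "nuclear_exon", stringsAsFactors = FALSE)
    tset <- build_target_set(exon_targets = list(
      data.frame(tdf, source_seq_id = tdf$target_id, start = 0L,
                 end = nchar(tdf$sequence))))
    mask <- if (!is.null(config$mask_fasta))
      read_fasta(config$mask_fasta) else NULL
    dc <- design_config(
      capacity = .cfg_get(config, "capacity", 1000000L),
      mask_threshold = .cfg_get(config, "mask_threshold", 50L),
      edge_window = .cfg_get(config, "edge_window", 30L))
    ps <- design_array(tset, mask, dc)
    write_probes(ps, art("probes.fasta"), art("probes.tsv"),
                 art("design_report.tsv"))
    .log_line(log, stage, designed = ps$counts[["designed"]],
              retained = ps$counts[["retained"]])
  } else if (stage == "readqc") {
    f1 <- read_fastq(.need_path(config, "fastq1"))
    f2 <- read_fastq(.need_path(config, "fastq2"))
    pairs <- read_pairs(names(f1$bases), unname(f1$bases), unname(f1$quals),
                        unname(f2$bases), unname(f2$quals))
    if (!is.null(config$barcodes_tsv)) {
      bmap <- utils::read.table(.need_path(config, "barcodes_tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
      # barcodes ride in the read id suffix "<id>#<barcode>" when present
      bc <- sub("^[^#]*#", "", pairs$pair_id)
      pairs$barcode <- ifelse(nchar(bc) == 7L & bc != pairs$pair_id, bc, NA)
      dm <- demultiplex(pairs, bmap)
      utils::write.table(
        as.data.frame(table(sample = dm$assigned$sample_id)),
        art("demultiplex_report.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      pairs <- rbind(dm$assigned, dm$unassigned)
    }
    adapters <- .cfg_get(config, "adapters",
                         "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC")
    ctab <- if (!is.null(config$contaminant_fasta))
      count_kmers(read_fasta(config$contaminant_fasta), k = 21) else NULL
    res <- filter_reads(pairs, adapters, ctab,
                        min_q = .cfg_get(config, "min_q", 20L),
                        min_len = .cfg_get(config, "min_len", 36L))
    pp <- res$passed
    write_fastq(stats::setNames(pp$bases1, pp$pair_id),
                stats::setNames(pp$quals1, pp$pair_id),
                art("filtered_1.fastq"))
    write_fastq(stats::setNames(pp$bases2, pp$pair_id),
                stats::setNames(pp$quals2, pp$pair_id),
                art("filtered_2.fastq"))
    utils::write.table(res$report, art("filter_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .log_line(log, stage, n_in = nrow(pairs), n_out = nrow(pp),
              fraction_passed = res$fraction_passed)
  } else if (stage == "assemble-merge") {
    paths <- strsplit(.cfg_get(config, "assemblies", ""), ",")[[1]]
    if (length(paths) == 0 || !all(file.exists(paths)))
      stop("config error: 'assemblies' must list existing FASTA paths",
           call. = FALSE)
    merged <- merge_assemblies(lapply(paths, read_fasta))
    st <- assembly_stats(merged)
    write_fasta(merged, art("merged.fasta"))
    utils::write.table(as.data.frame(st), art("assembly_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .log_line(log, stage, n_contigs = st$n, n50 = st$n50)
  } else if (stage == "intarget") {
    contigs <- read_fasta(.need_path(config, "contigs_fasta"))
    targets <- read_fasta(.need_path(config, "targets_fasta"))
    tdf <- data.frame(target_id = names(targets), sequence = unname(targets),
                      stringsAsFactors = FALSE)
    map <- identify_in_target(contigs, tdf)
    write_in_target_map(map, art("in_target_map.tsv"))
    .log_line(log, stage, n_paired = nrow(map))
  } else if (stage == "eval") {
    aln <- read_sam(.need_path(config, "sam"))
    contigs <- read_fasta(.need_path(config, "contigs_fasta"))
    map <- utils::read.table(.need_path(config, "map_tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    pile <- pileup(aln, contigs)
    cs <- coverage_summary(pile, map)
    metrics <- data.frame(
      metric = c("sensitivity", "specificity", "mean_coverage",
                 names(cs$fractions)),
      value = c(sensitivity(map, pile), specificity(aln, map),
                cs$mean_coverage, unname(cs$fractions)))
    utils::write.table(metrics, art("capture_metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cs$per_target, art("per_target_coverage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .log_line(log, stage, n_reads = nrow(aln), n_targets = nrow(map))
  } else if (stage == "errors") {
    aln <- read_sam(.need_path(config, "sam"))
    contigs <- read_fasta(.need_path(config, "contigs_fasta"))
    hap <- strsplit(.cfg_get(config, "haploid_contigs", ""), ",")[[1]]
    if (length(hap) == 0) stop("config error: 'haploid_contigs' required",
                               call. = FALSE)
    pile <- pileup(aln[aln$contig_id %in% hap, , drop = FALSE],
                   contigs[hap])
    er <- haploid_error_rate(pile)
    utils::write.table(as.data.frame(er), art("error_rate.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .log_line(log, stage, rate = er$rate, phred = er$phred)
  } else if (stage == "variants") {
    aln <- read_sam(.need_path(config, "sam"))
    contigs <- read_fasta(.need_path(config, "reference_fasta"))
    models <- utils::read.table(.need_path(config, "gene_model_tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    pile <- pileup(aln, contigs)
    snps <- call_snps(pile, contigs, models,
                      species = .cfg_get(config, "species", "species"),
                      min_depth = .cfg_get(config, "min_depth", 20L),
                      max_depth = .cfg_get(config, "max_depth", 5000L),
                      min_site_quality = .cfg_get(config, "min_site_quality",
                                                  30))
    write_snp_vcf(snps, art("snps.vcf"))
    summ <- summarize_snps(snps)
    if (length(summ)) {
      s <- summ[[1]]
      out <- data.frame(class = names(s$total_difference),
                        fixed = unname(s$fixed),
                        polymorphic = unname(s$polymorphic),
                        total = unname(s$total_difference))
      utils::write.table(out, art("snp_summary.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    .log_line(log, stage, n_snps = nrow(snps))
  }
  invisible(arts)
}
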