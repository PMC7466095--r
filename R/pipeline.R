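#' Assemble a pipeline run configuration
#'
#' Collects input paths and thresholds for [run_all()]. Required: the two
#' VCFs (line called against each parental reference), the two parental
#' GFF3 annotations and the ortholog pairing. Optional inputs switch on
#' optional stages: parental FASTAs enable reconstruction + lift-over, a
#' hit table enables orthology typing and the segment-order check, DEG
#' tables enable the expression summaries, a marker assay table plus the
#' line FASTA enables marker resolution of unknown calls, and a target
#' region enables the purity scan.
#'
#' @param vcf_background,vcf_donor variant calls against each reference.
#' @param genes_background,genes_donor GFF3 gene models.
#' @param gene_pairing TSV with `background_gene_id`, `donor_gene_id`.
#' @param genome_background,genome_donor,genome_line optional FASTAs.
#' @param hits optional 12-column similarity hit table.
#' @param deg_br,deg_mr optional DEG tables (gene_id, logFC, fdr, ...).
#' @param assays optional marker table (marker_id, gene_id, fwd, rev,
#'   enzyme).
#' @param target_region optional `"chrom:start-end"` for the purity scan.
#' @param deg_region optional region overriding the inferred replaced
#'   segment for the DEG intersection.
#' @param min_mean_depth,min_informative,fdr_threshold,evalue_threshold,min_run,max_bridge
#'   stage thresholds (depth filter, ancestry evidence, DEG significance,
#'   hit significance, chimera runs, unknown-bridging).
#' @param strict error on more than one donor block.
#' @param cut cut placement inside uncertainty intervals (see
#'   [merge_genomes()]).
#' @param out_dir output directory.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(vcf_background, vcf_donor, genes_background,
                       genes_donor, gene_pairing,
                       genome_background = NULL, genome_donor = NULL,
                       genome_line = NULL, hits = NULL,
                       deg_br = NULL, deg_mr = NULL, assays = NULL,
                       target_region = NULL, deg_region = NULL,
                       min_mean_depth = 5, min_informative = 2,
                       fdr_threshold = 0.05, evalue_threshold = 1e-10,
                       min_run = 3, max_bridge = 3, strict = TRUE,
                       cut = "midpoint", out_dir = tempfile("introdissect_run")) {
  cfg <- as.list(environment())
  if (min_mean_depth < 0) stop("run_config: negative min_mean_depth")
  if (min_informative < 1) stop("run_config: min_informative < 1")
  if (fdr_threshold <= 0 || fdr_threshold > 1) stop("run_config: fdr_threshold outside (0,1]")
  for (f in c("vcf_background", "vcf_donor", "genes_background",
              "genes_donor", "gene_pairing", "genome_background",
              "genome_donor", "genome_line", "hits", "deg_br", "deg_mr",
              "assays")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p)) stop("run_config: missing input ", f, ": ", p)
  }
  class(cfg) <- "run_config"
  cfg
}

genotype_assay_table <- function(assays, genome_background, genome_donor,
                                 genome_line, enzymes = restriction_enzymes()) {
  calls <- character(nrow(assays))
  for (i in seq_len(nrow(assays))) {
    a <- assays[i, ]
    amp <- lapply(list(bg = genome_background, dn = genome_donor, ln = genome_line),
                  function(gg) find_amplicon(gg, a$fwd, a$rev))
    if (is.null(amp$bg) || is.null(amp$dn)) { calls[i] <- "uninformative"; next }
    if (is.null(amp$ln)) { calls[i] <- "uninformative"; next }
    ez <- enzymes[enzymes$enzyme == a$enzyme, , drop = FALSE]
    if (!nrow(ez)) { calls[i] <- "uninformative"; next }
    calls[i] <- caps_genotype(
      digest(amp$ln$sequence, ez$site, ez$cut_offset),
      digest(amp$bg$sequence, ez$site, ez$cut_offset),
      digest(amp$dn$sequence, ez$site, ez$cut_offset))
  }
  data.frame(gene_id = assays$gene_id, call = calls, stringsAsFactors = FALSE)
}

#' Run the full introgression-dissection pipeline
#'
#' Executes, in order: depth/zygosity filtering of both callsets, the
#' optional purity scan, per-gene variant counting and dual-reference
#' ancestry classification, optional marker resolution of unknown calls,
#' breakpoint inference, optional genome reconstruction with lift-over,
#' optional orthology typing with the segment-order check, and optional DEG
#' summarization against the replaced segment. Every stage's record counts
#' go to `run_log.txt`; the effective configuration is serialized next to
#' the outputs; all outputs are plain tables/FASTA/GFF3 with no timestamps,
#' so identical configurations give identical report bundles.
#'
#' @param config a [run_config()].
#' @return the report bundle (named list of stage results), invisibly;
#'   side effect: files under `config$out_dir`.
#' @export
run_all <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))
  bundle <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # serialized effective config (paths + thresholds, fixed key order)
  keys <- sort(setdiff(names(cfg), "out_dir"))
  writeLines(vapply(keys, function(k) {
    v <- cfg[[k]]
    paste0(k, "=", if (is.null(v)) "" else paste(v, collapse = ","))
  }, ""), file.path(cfg$out_dir, "config_used.txt"))

  vb <- stage("read_variants", read_variants(cfg$vcf_background))
  vd <- stage("read_variants", read_variants(cfg$vcf_donor))
  logf("read_variants: %d vs background, %d vs donor", nrow(vb), nrow(vd))
  fb <- stage("filter_variants", filter_variants(vb, cfg$min_mean_depth))
  fd <- stage("filter_variants", filter_variants(vd, cfg$min_mean_depth))
  logf("filter_variants: kept %d vs background, %d vs donor", nrow(fb), nrow(fd))
  bundle$variants <- list(background = fb, donor = fd)

  if (!is.null(cfg$target_region)) {
    pur <- stage("purity_scan", purity_scan(fb, cfg$target_region))
    bundle$purity <- pur
    pp <- purity_percentages(pur)
    utils::write.table(
      data.frame(n_total = pur$n_total, n_inside = pur$n_inside,
                 n_outside = pur$n_outside, outside_pct = pp["outside_pct"],
                 n_snp = pur$n_snp, n_indel = pur$n_indel,
                 snp_pct = pp["snp_pct"], indel_pct = pp["indel_pct"]),
      file.path(cfg$out_dir, "purity.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    logf("purity_scan: %d/%d inside target region", pur$n_inside, pur$n_total)
  }

  ann_b <- stage("read_annotation", read_annotation(cfg$genes_background))
  ann_d <- stage("read_annotation", read_annotation(cfg$genes_donor))
  pairing <- utils::read.delim(cfg$gene_pairing, stringsAsFactors = FALSE)
  cb <- stage("count_variants", count_variants_per_gene(fb, ann_b))
  cd <- stage("count_variants", count_variants_per_gene(fd, ann_d))
  merged <- stage("merge_counts", merge_gene_counts(cb, cd, pairing))
  calls <- stage("classify_ancestry", classify_ancestry(merged, cfg$min_informative))
  logf("classify_ancestry: %d donor, %d background, %d unknown",
       sum(calls$call == "donor"), sum(calls$call == "background"),
       sum(calls$call == "unknown"))

  if (!is.null(cfg$assays) && !is.null(cfg$genome_line)) {
    assays <- utils::read.delim(cfg$assays, stringsAsFactors = FALSE)
    gb <- read_genome(cfg$genome_background)
    gd <- read_genome(cfg$genome_donor)
    gl <- read_genome(cfg$genome_line)
    marker_calls <- stage("markers", genotype_assay_table(assays, gb, gd, gl))
    calls <- stage("resolve_unknowns", resolve_unknowns(calls, marker_calls))
    bundle$marker_calls <- marker_calls
    logf("markers: %d assays, %d informative", nrow(marker_calls),
         sum(marker_calls$call %in% c("background", "donor")))
  }
  g <- ann_b$genes
  m <- match(calls$gene_id, g$gene_id)
  calls$chrom <- g$chrom[m]; calls$start <- g$start[m]; calls$end <- g$end[m]
  bundle$calls <- calls
  utils::write.table(calls, file.path(cfg$out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  bp <- stage("infer_breakpoints",
              infer_breakpoints(calls, fb, cfg$max_bridge, cfg$strict))
  bundle$breakpoints <- bp
  utils::write.table(as.data.frame(bp), file.path(cfg$out_dir, "breakpoints.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("infer_breakpoints: %d block(s), %d gene(s) in block 1", nrow(bp), bp$n_genes[1])

  # donor-side source span from the donor partners of the block's donor calls
  block_calls <- calls[calls$call == "donor" & calls$chrom == bp$chrom[1], ]
  dg <- ann_d$genes[match(block_calls$donor_gene_id, ann_d$genes$gene_id), ]
  dg <- dg[!is.na(dg$gene_id), , drop = FALSE]
  donor_span <- list(chrom = dg$chrom[1], start = min(dg$start), end = max(dg$end))
  bundle$donor_span <- donor_span

  if (!is.null(cfg$genome_background) && !is.null(cfg$genome_donor)) {
    gb <- read_genome(cfg$genome_background)
    gd <- read_genome(cfg$genome_donor)
    rec <- stage("merge_genomes",
                 merge_genomes(gb, gd, donor_span, bp, cut = cfg$cut))
    bundle$reconstruction <- rec
    write_genome(rec$genome, file.path(cfg$out_dir, "reconstructed.fa"))
    utils::write.table(as.data.frame(rec$map), file.path(cfg$out_dir, "map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lift_b <- stage("liftover", liftover(rec$map, ann_b, "background"))
    lift_d <- stage("liftover", liftover(rec$map, ann_d, "donor"))
    bundle$liftover <- list(background = lift_b, donor = lift_d)
    write_annotation(lift_b$lifted, file.path(cfg$out_dir, "lifted_background.gff3"))
    if (nrow(lift_d$lifted$genes)) {
      write_annotation(lift_d$lifted, file.path(cfg$out_dir, "lifted_donor.gff3"))
    }
    logf("liftover: %d + %d genes lifted, %d chimeric candidate(s)",
         nrow(lift_b$lifted$genes), nrow(lift_d$lifted$genes),
         nrow(lift_b$chimeric_candidates) + nrow(lift_d$chimeric_candidates))
  }

  if (!is.null(cfg$hits)) {
    hits <- stage("read_hits", read_hits(cfg$hits))
    bbh <- stage("bbh", best_bidirectional_hits(hits, cfg$evalue_threshold))
    rel <- stage("classify_relationships",
                 classify_relationships(hits, ann_d$genes$gene_id,
                                        ann_b$genes$gene_id,
                                        cfg$evalue_threshold))
    bundle$bbh <- bbh
    bundle$relations <- rel
    utils::write.table(rel, file.path(cfg$out_dir, "relations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ordc <- stage("segment_order",
                  segment_order_check(rel,
                                      ann_d$genes$gene_id[order(ann_d$genes$chrom,
                                                                ann_d$genes$start)],
                                      ann_b$genes$gene_id[order(ann_b$genes$chrom,
                                                                ann_b$genes$start)]))
    bundle$segment_order <- ordc
    logf("orthology: %d BBH, %d relations, %d translocated block(s)",
         nrow(bbh), nrow(rel), length(ordc$translocated_blocks))
  }

  if (!is.null(cfg$deg_br) && !is.null(cfg$deg_mr)) {
    br <- stage("read_deg", read_deg_table(cfg$deg_br, "BR"))
    mr <- stage("read_deg", read_deg_table(cfg$deg_mr, "MR"))
    sig_br <- significant(br, cfg$fdr_threshold)
    sig_mr <- significant(mr, cfg$fdr_threshold)
    counts <- per_chromosome_counts(rbind(sig_br, sig_mr))
    common <- common_degs(sig_br, sig_mr)
    region <- if (!is.null(cfg$deg_region)) cfg$deg_region else {
      list(chrom = bp$chrom[1],
           start = floor((max(bp$lower_last_background[1], 0) + bp$lower_first_donor[1]) / 2),
           end = ceiling((bp$upper_last_donor[1] +
                            min(bp$upper_first_background[1], .Machine$integer.max)) / 2))
    }
    common_genes <- sig_br[sig_br$gene_id %in% c(common$common_up, common$common_down), ]
    in_region <- intersect_region(common_genes, region)
    bundle$degsum <- list(counts = counts, common = common,
                          in_region = in_region$gene_id, region = region)
    utils::write.table(counts, file.path(cfg$out_dir, "deg_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("degsum: %d BR / %d MR significant, %d common up, %d common down, %d in region",
         nrow(sig_br), nrow(sig_mr), length(common$common_up),
         length(common$common_down), nrow(in_region))
  }

  # gene accounting: donor genes inserted vs background genes replaced
  n_donor <- sum(ann_d$genes$chrom == donor_span$chrom &
                   ann_d$genes$start >= donor_span$start &
                   ann_d$genes$end <= donor_span$end)
  replaced_lo <- max(bp$lower_last_background[1], 0)
  replaced_hi <- min(bp$upper_first_background[1], Inf)
  n_background <- sum(ann_b$genes$chrom == bp$chrom[1] &
                        ann_b$genes$start > replaced_lo &
                        ann_b$genes$end < replaced_hi)
  bundle$accounting <- list(n_donor_genes = n_donor,
                            n_background_genes = n_background)
  logf("accounting: %d donor genes replaced %d background genes", n_donor, n_background)

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  writeLines(c(sprintf("Donor genes introgressed: %d", n_donor),
               sprintf("Background genes replaced: %d", n_background),
               log_lines),
             file.path(cfg$out_dir, "summary.txt"))
  invisible(bundle)
}

#' Gene accounting from a relationship table
#'
#' Counts the distinct donor and background genes of an introgressed-region
#' relationship table (such as the packaged fixture) and splits the donor
#' genes into segments by clustering their coordinates: a gap above
#' `max_gap` bp between consecutive donor genes starts a new segment.
#'
#' @param tbl3 a table as returned by [load_relationship_table()].
#' @param max_gap minimum inter-gene gap (bp) separating two donor
#'   segments.
#' @return list with `n_donor`, `n_background`, `donor_segments` (gene
#'   counts per segment, in donor-coordinate order) and `segment_spans`
#'   (bp extents).
#' @export
gene_accounting <- function(tbl3 = load_relationship_table(), max_gap = 3e5) {
  d <- tbl3[!is.na(tbl3$donor_gene), c("donor_gene", "donor_start", "donor_end")]
  d <- d[order(d$donor_start), ]
  d <- d[!duplicated(d$donor_gene), , drop = FALSE]
  b <- unique(tbl3$background_gene[!is.na(tbl3$background_gene)])
  gap_before <- c(0, d$donor_start[-1L] - d$donor_end[-nrow(d)])
  seg <- cumsum(gap_before > max_gap) + 1L
  spans <- vapply(unique(seg), function(s) {
    max(d$donor_end[seg == s]) - min(d$donor_start[seg == s]) + 1
  }, 0)
  list(n_donor = nrow(d), n_background = length(b),
       donor_segments = as.integer(table(seg)),
       segment_spans = spans)
}
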