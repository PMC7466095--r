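#' Filter variant calls on depth and zygosity
#'
#' Keeps variants with mean depth of coverage at or above `min_mean_depth`
#' (threshold inclusive, default 5) and, by default, homozygous genotype -
#' the filtering regime used before ancestry assignment, where heterozygous
#' and low-coverage calls are discarded. Input order is preserved.
#'
#' @param variants a [variant_table()].
#' @param min_mean_depth minimum mean depth (reads), inclusive.
#' @param require_homozygous drop heterozygous calls.
#' @return filtered [variant_table()].
#' @export
filter_variants <- function(variants, min_mean_depth = 5,
                            require_homozygous = TRUE) {
  if (min_mean_depth < 0) stop("min_mean_depth must be non-negative")
  keep <- !is.na(variants$mean_depth) & variants$mean_depth >= min_mean_depth
  if (require_homozygous) keep <- keep & variants$genotype_class == "homozygous"
  variants[keep, , drop = FALSE]
}

#' Count variants per gene against one reference
#'
#' A variant is assigned to gene *g* iff the chromosome matches and
#' `gene.start <= pos <= gene.end` (full gene span, UTRs included, since
#' transcriptome-derived variants fall anywhere in the transcribed region).
#' Intergenic variants are assigned to no gene. A variant overlapping two
#' genes is assigned to both, with a warning.
#'
#' @param variants a [variant_table()] called against this reference.
#' @param ann the reference's [annotation()].
#' @return data.frame with `gene_id`, `n_variants`, `expressed`
#'   (`TRUE` iff the gene carries any variant evidence in this callset).
#' @export
count_variants_per_gene <- function(variants, ann) {
  g <- ann$genes
  n <- integer(nrow(g))
  multi <- 0L
  if (nrow(variants)) {
    hits_per_variant <- integer(nrow(variants))
    for (i in seq_len(nrow(g))) {
      in_gene <- variants$chrom == g$chrom[i] &
        variants$pos >= g$start[i] & variants$pos <= g$end[i]
      n[i] <- sum(in_gene)
      hits_per_variant <- hits_per_variant + in_gene
    }
    multi <- sum(hits_per_variant > 1L)
  }
  if (multi > 0L) {
    warning(multi, " variant(s) overlap more than one gene; assigned to all")
  }
  data.frame(gene_id = g$gene_id, n_variants = n, expressed = n > 0L,
             stringsAsFactors = FALSE)
}

#' Merge per-reference variant counts over an ortholog pairing
#'
#' @param counts_background output of [count_variants_per_gene()] against the
#'   background reference.
#' @param counts_donor same against the donor reference.
#' @param pairing data.frame with `background_gene_id`, `donor_gene_id`
#'   linking orthologous gene models of the two references.
#' @return data.frame with `gene_id` (background id), `donor_gene_id`,
#'   `n_vs_background`, `n_vs_donor`, `expressed`.
#' @export
merge_gene_counts <- function(counts_background, counts_donor, pairing) {
  ib <- match(pairing$background_gene_id, counts_background$gene_id)
  id <- match(pairing$donor_gene_id, counts_donor$gene_id)
  if (anyNA(ib) || anyNA(id)) {
    stop("pairing names a gene absent from the per-reference counts")
  }
  nb <- counts_background$n_variants[ib]
  nd <- counts_donor$n_variants[id]
  data.frame(gene_id = pairing$background_gene_id,
             donor_gene_id = pairing$donor_gene_id,
             n_vs_background = nb, n_vs_donor = nd,
             expressed = nb > 0L | nd > 0L,
             stringsAsFactors = FALSE)
}

#' Classify per-gene ancestry from dual-reference variant counts
#'
#' A gene is called `donor` (wild) iff it harbors more variants against the
#' background reference than against the donor reference - the introgressed
#' allele diverges from the background but matches the donor - and
#' symmetrically for `background`. The winning count must reach
#' `min_informative` so a single stray variant cannot flip a call. Ties,
#' unexpressed genes, and sub-threshold evidence yield `unknown`.
#'
#' @param counts merged counts from [merge_gene_counts()].
#' @param min_informative minimum winning variant count (default 2).
#' @return `counts` with added `call` (`donor`/`background`/`unknown`) and
#'   `provenance` (`"variants"`) columns.
#' @export
classify_ancestry <- function(counts, min_informative = 2) {
  nb <- counts$n_vs_background
  nd <- counts$n_vs_donor
  call <- rep("unknown", nrow(counts))
  call[nb > nd & nb >= min_informative] <- "donor"
  call[nd > nb & nd >= min_informative] <- "background"
  counts$call <- call
  counts$provenance <- "variants"
  counts
}

#' Genome-wide purity scan for spurious introgressions
#'
#' Partitions a variant set by membership in a target region (the intended
#' introgression) and classifies the inside variants by class. A pure line
#' shows essentially all its diagnostic variants inside the target region;
#' variants elsewhere point at spurious wild fragments.
#'
#' @param variants a [variant_table()] (typically already filtered).
#' @param region target region: a `"chrom:start-end"` string or a list with
#'   `chrom`, `start`, `end`.
#' @return object of class `purity_report`: counts, full-precision fractions,
#'   and the positions of the outside variants.
#' @export
purity_scan <- function(variants, region) {
  if (is.character(region)) region <- parse_region(region)
  n_total <- nrow(variants)
  inside <- variants$chrom == region$chrom &
    variants$pos >= region$start & variants$pos <= region$end
  n_inside <- sum(inside)
  n_outside <- n_total - n_inside
  n_snp <- sum(variants$var_class[inside] == "SNP")
  n_indel <- n_inside - n_snp
  rep <- list(
    region = region,
    n_total = n_total, n_inside = n_inside, n_outside = n_outside,
    outside_fraction = if (n_total) n_outside / n_total else 0,
    n_snp = n_snp, n_indel = n_indel,
    snp_fraction = if (n_inside) n_snp / n_inside else 0,
    indel_fraction = if (n_inside) n_indel / n_inside else 0,
    outside_positions = variants[!inside, c("chrom", "pos"), drop = FALSE]
  )
  class(rep) <- "purity_report"
  rep
}

#' @export
print.purity_report <- function(x, ...) {
  cat(sprintf("purity scan: %d variants, %d inside target region, %d (%.1f%%) outside\n",
              x$n_total, x$n_inside, x$n_outside, 100 * x$outside_fraction))
  cat(sprintf("inside: %d (%.1f%%) SNPs, %d (%.1f%%) INDELs\n",
              x$n_snp, 100 * x$snp_fraction, x$n_indel, 100 * x$indel_fraction))
  invisible(x)
}

#' Percentages of a purity report, rounded for presentation
#'
#' One-decimal percentages as printed in reports; the underlying fractions
#' stay at full precision in the report object.
#'
#' @param report a `purity_report`.
#' @return named numeric vector (`outside_pct`, `snp_pct`, `indel_pct`).
#' @export
purity_percentages <- function(report) {
  c(outside_pct = round(100 * report$outside_fraction, 1),
    snp_pct = round(100 * report$snp_fraction, 1),
    indel_pct = round(100 * report$indel_fraction, 1))
}
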