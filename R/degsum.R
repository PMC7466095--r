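#' Select significantly differentially expressed genes
#'
#' Keeps records with `fdr` strictly below the threshold and assigns a
#' direction from the sign of the log fold change. Records that are
#' significant but have logFC exactly 0 carry no direction; they are flagged
#' with a warning and excluded.
#'
#' @param records DEG records with `gene_id`, `logFC`, `fdr`.
#' @param fdr_threshold significance threshold (strict, default 0.05).
#' @return the significant records with a `direction` (`up`/`down`) column.
#' @export
significant <- function(records, fdr_threshold = 0.05) {
  sig <- records$fdr < fdr_threshold
  ambiguous <- sig & records$logFC == 0
  if (any(ambiguous)) {
    warning(sum(ambiguous), " significant record(s) with logFC = 0 excluded as ambiguous")
  }
  out <- records[sig & !ambiguous, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  out
}

#' Per-chromosome up/down counts
#'
#' Tabulates significant DEG records by chromosome, contrast and direction,
#' with a `Total` row per contrast. The counts partition the significant
#' set: totals equal the number of input records per contrast.
#'
#' @param records significant records from [significant()] carrying `chrom`
#'   and `contrast`.
#' @return data.frame with `contrast`, `chrom`, `n_up`, `n_down`; the last
#'   row of each contrast has `chrom = "Total"`.
#' @export
per_chromosome_counts <- function(records) {
  if (!nrow(records)) {
    return(data.frame(contrast = character(), chrom = character(),
                      n_up = integer(), n_down = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (ctr in sort(unique(records$contrast))) {
    r <- records[records$contrast == ctr, , drop = FALSE]
    chroms <- unique(r$chrom)
    suppressWarnings({
      num <- as.numeric(chroms)
      chroms <- if (anyNA(num)) sort(chroms) else chroms[order(num)]
    })
    n_up <- vapply(chroms, function(ch) sum(r$chrom == ch & r$direction == "up"), 0L)
    n_down <- vapply(chroms, function(ch) sum(r$chrom == ch & r$direction == "down"), 0L)
    out[[ctr]] <- data.frame(
      contrast = ctr, chrom = c(chroms, "Total"),
      n_up = c(n_up, sum(n_up)), n_down = c(n_down, sum(n_down)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genes commonly regulated in two contrasts
#'
#' Intersects the significant sets of two contrasts: common up = upregulated
#' in both, common down = downregulated in both; genes significant in both
#' with opposite signs are reported separately as discordant and belong to
#' neither common set.
#'
#' @param records_a,records_b significant records from [significant()] for
#'   the two contrasts.
#' @return list with character vectors `common_up`, `common_down`,
#'   `discordant`.
#' @export
common_degs <- function(records_a, records_b) {
  up_a <- records_a$gene_id[records_a$direction == "up"]
  dn_a <- records_a$gene_id[records_a$direction == "down"]
  up_b <- records_b$gene_id[records_b$direction == "up"]
  dn_b <- records_b$gene_id[records_b$direction == "down"]
  list(common_up = sort(intersect(up_a, up_b)),
       common_down = sort(intersect(dn_a, dn_b)),
       discordant = sort(union(intersect(up_a, dn_b), intersect(dn_a, up_b))))
}

#' Subset genes overlapping a genomic region
#'
#' 1-based inclusive overlap: a gene is included iff its chromosome matches
#' and its `[start, end]` span shares at least one base with the region.
#'
#' @param genes data.frame with `chrom`, `start`, `end`.
#' @param region `"chrom:start-end"` string or list with `chrom`, `start`,
#'   `end`.
#' @return the overlapping subset of `genes`.
#' @export
intersect_region <- function(genes, region) {
  if (is.character(region)) region <- parse_region(region)
  keep <- genes$chrom == region$chrom &
    intervals_overlap(genes$start, genes$end, region$start, region$end)
  genes[keep, , drop = FALSE]
}
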