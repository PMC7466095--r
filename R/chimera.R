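#' Extract diagnostic sites from a three-way alignment
#'
#' Takes an alignment of the line's sequence with both parental alleles of a
#' border gene (three rows of equal aligned length, gaps as `-`) and emits
#' one site per position where the parents differ. Runs of adjacent
#' diagnostic columns in which a parent carries a gap are collapsed into a
#' single site (one indel = one site) anchored at the position of their
#' first column. Each site records which parent the line matches.
#'
#' @param aln named character vector of aligned sequences with names `line`,
#'   `donor`, `background`.
#' @param anchor_pos reference coordinate of the first non-gap base of the
#'   anchor row.
#' @param anchor_row which row's coordinate system positions are reported in
#'   (default `"background"`; the donor row when the printed positions are
#'   donor coordinates).
#' @return data.frame with `pos`, `background_allele`, `donor_allele`,
#'   `line_allele`, `support` (`matches_donor` / `matches_background` /
#'   `matches_neither`).
#' @export
call_diagnostic_sites <- function(aln, anchor_pos = 1,
                                  anchor_row = c("background", "donor", "line")) {
  anchor_row <- match.arg(anchor_row)
  need <- c("line", "donor", "background")
  if (!all(need %in% names(aln))) {
    stop("alignment must have rows named line, donor, background")
  }
  rows <- lapply(aln[need], function(s) strsplit(toupper(s), "")[[1]])
  len <- unique(lengths(rows))
  if (length(len) != 1L) stop("alignment rows have unequal lengths")
  ln <- rows$line; dn <- rows$donor; bg <- rows$background
  anc <- rows[[anchor_row]]
  # reference position of each column, left-anchored across anchor-row gaps
  pos <- as.integer(anchor_pos) - 1L + cummax(cumsum(anc != "-") * (anc != "-"))
  pos <- as.integer(pmax(pos, anchor_pos))

  diag_col <- dn != bg
  gap_col <- diag_col & (dn == "-" | bg == "-")
  # group adjacent gap-bearing diagnostic columns into one event
  grp <- integer(len)
  cur <- 0L
  for (i in seq_len(len)) {
    if (!diag_col[i]) next
    if (gap_col[i] && i > 1L && diag_col[i - 1L] && gap_col[i - 1L] &&
        grp[i - 1L] > 0L) {
      grp[i] <- grp[i - 1L]
    } else {
      cur <- cur + 1L
      grp[i] <- cur
    }
  }
  if (cur == 0L) {
    return(data.frame(pos = integer(), background_allele = character(),
                      donor_allele = character(), line_allele = character(),
                      support = character(), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(cur), function(k) {
    cols <- which(grp == k)
    b <- paste(bg[cols], collapse = "")
    d <- paste(dn[cols], collapse = "")
    l <- paste(ln[cols], collapse = "")
    support <- if (l == d) "matches_donor" else if (l == b) "matches_background" else "matches_neither"
    data.frame(pos = pos[cols[1]], background_allele = b, donor_allele = d,
               line_allele = l, support = support, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Localize an intra-gene recombination point from diagnostic sites
#'
#' Under a single-crossover model the line's allele matches the donor up to
#' the crossover and the background after it. The split index over the
#' ordered informative sites is chosen to maximize (donor-supporting sites
#' before) + (background-supporting sites after) - i.e. minimal
#' misclassified sites, robust to isolated sequencing errors.
#' `matches_neither` sites are excluded from the objective but counted in
#' `n_sites_total`. At least `min_run` concordant sites are required on each
#' side of the chosen split.
#'
#' @param sites data.frame from [call_diagnostic_sites()], ordered by `pos`.
#' @param min_run minimum concordant sites on each side (default 3).
#' @param gene_id optional gene identifier carried into the report.
#' @return object of class `chimera_report`: `last_donor_site`,
#'   `first_background_site`, the open `interval` between them, run lengths,
#'   misclassification count, `n_sites_total`.
#' @export
locate_recombination <- function(sites, min_run = 3, gene_id = NA_character_) {
  sites <- sites[order(sites$pos), , drop = FALSE]
  inf <- sites[sites$support != "matches_neither", , drop = FALSE]
  n <- nrow(inf)
  is_d <- inf$support == "matches_donor"
  is_b <- inf$support == "matches_background"
  if (n == 0L) stop("no chimera detected: no informative sites")
  # score(k) = donor sites among 1..k + background sites among (k+1)..n
  cum_d <- c(0L, cumsum(is_d))
  cum_b <- c(0L, cumsum(is_b))
  score <- cum_d[1:(n + 1L)] + (cum_b[n + 1L] - cum_b[1:(n + 1L)])
  k <- which.max(score) - 1L  # first maximizer
  d_before <- cum_d[k + 1L]
  b_after <- cum_b[n + 1L] - cum_b[k + 1L]
  if (d_before < min_run || b_after < min_run) {
    stop("no chimera detected: fewer than ", min_run,
         " concordant sites on one side of the best split")
  }
  last_donor <- max(inf$pos[seq_len(k)][is_d[seq_len(k)]])
  after <- seq.int(k + 1L, n)
  first_bg <- min(inf$pos[after][is_b[after]])
  rep <- list(gene_id = gene_id,
              last_donor_site = last_donor,
              first_background_site = first_bg,
              interval = c(last_donor, first_bg),
              run_donor = d_before, run_background = b_after,
              n_misclassified = n - max(score),
              n_sites_total = nrow(sites))
  class(rep) <- "chimera_report"
  rep
}

#' @export
print.chimera_report <- function(x, ...) {
  cat(sprintf("chimera: recombination in open interval (%s, %s)%s\n",
              format(x$last_donor_site, big.mark = ","),
              format(x$first_background_site, big.mark = ","),
              if (is.na(x$gene_id)) "" else paste0(" of ", x$gene_id)))
  cat(sprintf("  %d donor-supporting sites before, %d background-supporting after, %d misclassified, %d sites total\n",
              x$run_donor, x$run_background, x$n_misclassified, x$n_sites_total))
  invisible(x)
}

#' Which gene feature contains the recombination interval?
#'
#' Maps the open interval of a [locate_recombination()] report onto a gene
#' model and returns the feature kind(s) overlapping it (`"intergenic"` if
#' the interval touches no feature).
#'
#' @param report a `chimera_report`.
#' @param ann a [annotation()] containing the gene.
#' @param gene_id gene to annotate against (defaults to the report's).
#' @return character vector of feature kinds.
#' @export
annotate_interval <- function(report, ann, gene_id = report$gene_id) {
  g <- ann$genes[ann$genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(g)) stop("gene not in annotation: ", gene_id)
  a <- report$last_donor_site
  b <- report$first_background_site
  lo <- a + 1L  # open interval
  hi <- b - 1L
  if (hi < g$start || lo > g$end) stop("interval outside gene span of ", gene_id)
  f <- ann$features[ann$features$gene_id == gene_id, , drop = FALSE]
  ov <- f[intervals_overlap(f$start, f$end, lo, hi), , drop = FALSE]
  if (!nrow(ov)) return("intergenic")
  unique(ov$kind[order(ov$start)])
}

#' Count residual differences between two aligned segments
#'
#' Position-wise classification of an aligned sequence pair: columns where
#' both rows carry a base but disagree count as SNPs; each maximal gap run
#' (in either row) counts as one INDEL.
#'
#' @param seg_a,seg_b aligned sequences of equal length, gaps as `-`.
#' @return list with `n_snp`, `n_indel`.
#' @export
count_residual_differences <- function(seg_a, seg_b) {
  a <- strsplit(toupper(seg_a), "")[[1]]
  b <- strsplit(toupper(seg_b), "")[[1]]
  if (length(a) != length(b)) stop("segments have unequal aligned length")
  gap <- (a == "-") != (b == "-")  # gap in exactly one row
  n_snp <- sum(a != b & a != "-" & b != "-")
  n_indel <- sum(gap & !c(FALSE, gap[-length(gap)]))
  list(n_snp = n_snp, n_indel = n_indel)
}
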