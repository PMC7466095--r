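AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Local protein alignment with an e-value proxy
#'
#' Smith-Waterman local alignment with affine gap penalties (a gap of length
#' L costs `gap_open + L * gap_extend`), scored with a standard substitution
#' matrix. A desk-scale stand-in for an external protein search: the e-value
#' proxy converts the raw score through the Karlin-Altschul form
#' `E = K * m * n * exp(-lambda * S)` with fixed gapped-search parameters.
#'
#' @param seq_a,seq_b protein sequences (20-letter alphabet plus X).
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param lambda,k Karlin-Altschul parameters for the e-value proxy.
#' @return list with `score`, `identity_pct`, `evalue`.
#' @export
align_proteins <- function(seq_a, seq_b, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           lambda = 0.267, k = 0.041) {
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) stop("empty protein sequence")
    bad <- setdiff(strsplit(toupper(s), "")[[1]], AA_ALPHABET)
    if (length(bad)) stop("invalid residue(s): ", paste(bad, collapse = ", "))
  }
  mat <- get(data(list = matrix, package = "Biostrings",
                  envir = environment()), envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(seq_a)), Biostrings::AAString(toupper(seq_b)),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  s <- Biostrings::score(al)
  list(score = s,
       identity_pct = Biostrings::pid(al),
       evalue = k * nchar(seq_a) * nchar(seq_b) * exp(-lambda * s))
}

# best hit per query: highest score, ties broken by lexicographic subject id;
# returns a data.frame(query, subject, score, evalue, tie_broken)
best_hit_per_query <- function(hits) {
  if (!nrow(hits)) {
    return(data.frame(query = character(), subject = character(),
                      score = numeric(), evalue = numeric(),
                      tie_broken = logical(), stringsAsFactors = FALSE))
  }
  o <- order(hits$query_id, -hits$score, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$query_id)
  best <- h[first, , drop = FALSE]
  # a tie was broken if another hit of the same query reaches the same score
  tie <- vapply(seq_len(nrow(best)), function(i) {
    q <- best$query_id[i]
    sc <- hits$score[hits$query_id == q]
    sum(sc == max(sc)) > 1L
  }, logical(1))
  data.frame(query = best$query_id, subject = best$subject_id,
             score = best$score, evalue = best$evalue,
             tie_broken = tie, stringsAsFactors = FALSE)
}

#' Best bidirectional hits
#'
#' A pair (a, b) is a best bidirectional hit (BBH) iff b is a's
#' highest-scoring subject and a is b's highest-scoring subject, with both
#' directions at or below the e-value threshold. Score ties are broken by
#' lexicographic subject id and recorded in the output.
#'
#' @param hits 12-column hit table (see [read_hits()]) containing both
#'   directions.
#' @param evalue_threshold maximum e-value per direction (default 1e-10).
#' @return data.frame with `gene_a`, `gene_b` (lexicographically ordered
#'   within pair), `score` (max of the two directions), `evalue` (min), and
#'   `tie_broken`.
#' @export
best_bidirectional_hits <- function(hits, evalue_threshold = 1e-10) {
  h <- hits[hits$evalue <= evalue_threshold, , drop = FALSE]
  best <- best_hit_per_query(h)
  bm <- stats::setNames(best$subject, best$query)
  is_bbh <- !is.na(bm[best$subject]) & bm[best$subject] == best$query
  pairs <- best[is_bbh, , drop = FALSE]
  if (!nrow(pairs)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), evalue = numeric(),
                      tie_broken = logical(), stringsAsFactors = FALSE))
  }
  a <- pmin(pairs$query, pairs$subject)
  b <- pmax(pairs$query, pairs$subject)
  key <- paste(a, b)
  keep <- !duplicated(key)
  out <- data.frame(gene_a = a[keep], gene_b = b[keep], stringsAsFactors = FALSE)
  out$score <- vapply(seq_len(nrow(out)), function(i) {
    max(pairs$score[key == key[keep][i]])
  }, numeric(1))
  out$evalue <- vapply(seq_len(nrow(out)), function(i) {
    min(pairs$evalue[key == key[keep][i]])
  }, numeric(1))
  out$tie_broken <- vapply(seq_len(nrow(out)), function(i) {
    any(pairs$tie_broken[key == key[keep][i]])
  }, logical(1))
  rownames(out) <- NULL
  out
}

#' Type every gene of two regional gene sets
#'
#' Reproduces a printed relationship column from a similarity hit table:
#'
#' 1. *One-to-many (duplicated)*: a gene that is the best hit of two or more
#'    genes of the other species, and whose own best hit lies in that group,
#'    anchors a duplicated group - one relation per duplicated gene, typed
#'    `duplicated_donor` / `duplicated_background` after the side carrying
#'    the duplication. Recently duplicated genes are near-equally similar to
#'    their shared partner, so only members scoring at least
#'    `duplicate_score_ratio` of the group's best member count; a much
#'    weaker co-best-hit is not evidence of duplication.
#' 2. *BBH*: mutual best hits among the remaining genes.
#' 3. *Species-specific*: a gene with no hit at or below the threshold in
#'    the other set.
#' 4. *Homology*: remaining genes are paired by best hit restricted to the
#'    remaining partners (mutual where possible, else the gene's overall
#'    best partner) - the best-match fallback used when reciprocity fails.
#'
#' @param hits 12-column hit table restricted to (or filtered against) the
#'   two regional gene sets.
#' @param donor_genes,background_genes character vectors of gene ids.
#' @param evalue_threshold maximum e-value for an informative hit.
#' @param duplicate_score_ratio minimum score of a duplicated-group member
#'   relative to the group's best member.
#' @return data.frame with `donor_gene_id`, `background_gene_id` (NA on the
#'   empty side of species-specific rows), `relation`, `score`, `evalue`.
#' @export
classify_relationships <- function(hits, donor_genes, background_genes,
                                   evalue_threshold = 1e-10,
                                   duplicate_score_ratio = 0.9) {
  all_genes <- c(donor_genes, background_genes)
  side <- stats::setNames(c(rep("donor", length(donor_genes)),
                            rep("background", length(background_genes))),
                          all_genes)
  h <- hits[hits$evalue <= evalue_threshold &
              hits$query_id %in% all_genes &
              hits$subject_id %in% all_genes, , drop = FALSE]
  best <- best_hit_per_query(h)
  bm <- stats::setNames(best$subject, best$query)

  rel <- list()
  emit <- function(d, b, relation, score = NA_real_, evalue = NA_real_) {
    rel[[length(rel) + 1L]] <<- data.frame(
      donor_gene_id = d, background_gene_id = b, relation = relation,
      score = score, evalue = evalue, stringsAsFactors = FALSE)
  }
  typed <- character()

  # 1. one-to-many groups
  for (g in unique(best$subject)) {
    members <- best$query[best$subject == g]
    members <- setdiff(members, typed)
    if (length(members) >= 2L) {
      msc <- vapply(members, function(m) best$score[best$query == m][1], 0)
      members <- members[msc >= duplicate_score_ratio * max(msc)]
    }
    if (length(members) < 2L || g %in% typed) next
    if (is.na(bm[g]) || !(bm[g] %in% members)) next
    dup_side <- side[members[1]]
    relation <- if (dup_side == "donor") "duplicated_donor" else "duplicated_background"
    for (m in sort(members)) {
      sc <- best$score[best$query == m]
      ev <- best$evalue[best$query == m]
      if (dup_side == "donor") emit(m, g, relation, sc, ev)
      else emit(g, m, relation, sc, ev)
    }
    typed <- c(typed, g, members)
  }

  # 2. BBH among untyped genes
  for (i in seq_len(nrow(best))) {
    q <- best$query[i]; s <- best$subject[i]
    if (q %in% typed || s %in% typed) next
    if (side[q] != "donor") next  # emit once, from the donor side
    if (!is.na(bm[s]) && bm[s] == q) {
      emit(q, s, "BBH", best$score[i], best$evalue[i])
      typed <- c(typed, q, s)
    }
  }

  # 3. species-specific: no informative hit at all
  with_hits <- unique(c(h$query_id, h$subject_id))
  for (g in sort(setdiff(all_genes, c(typed, with_hits)))) {
    if (side[g] == "donor") emit(g, NA_character_, "species_specific_donor")
    else emit(NA_character_, g, "species_specific_background")
    typed <- c(typed, g)
  }

  # 4. homology: pair the remaining genes by best hit among themselves,
  #    falling back to the overall best partner
  remaining <- setdiff(all_genes, typed)
  for (g in sort(remaining)) {
    if (g %in% typed) next
    hg <- h[h$query_id == g & !(h$subject_id %in% typed), , drop = FALSE]
    if (!nrow(hg)) hg <- h[h$query_id == g, , drop = FALSE]
    hg <- hg[order(-hg$score, hg$subject_id), , drop = FALSE]
    partner <- hg$subject_id[1]
    if (side[g] == "donor") emit(g, partner, "homology", hg$score[1], hg$evalue[1])
    else emit(partner, g, "homology", hg$score[1], hg$evalue[1])
    typed <- c(typed, g, partner)
  }

  out <- do.call(rbind, rel)
  rownames(out) <- NULL
  out
}
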