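#' Locate a PCR product by exact primer matching
#'
#' Finds the amplicon defined by a primer pair on a template genome: the
#' forward primer matched exactly on the plus strand, the reverse primer
#' matched as its reverse complement downstream of it, product length at
#' most `max_product`. Marker primers are designed on known sequence, so no
#' mismatches are tolerated. No product is itself a genotype signal for
#' presence/absence (SCAR) markers, so absence returns `NULL` rather than
#' an error; multiple products are an error naming the loci.
#'
#' @param genome named character vector of template sequences.
#' @param forward,reverse primer sequences (ACGT, length >= 15).
#' @param max_product maximum product length in bp.
#' @return list with `chrom`, `start`, `end`, `sequence`, or `NULL` if the
#'   primers amplify nothing.
#' @export
find_amplicon <- function(genome, forward, reverse, max_product = 5000) {
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15L) stop("primer shorter than 15 bases")
    if (grepl("[^ACGT]", toupper(p))) stop("primer contains non-ACGT characters")
  }
  fwd <- toupper(forward)
  revc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(reverse))))
  products <- list()
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    fs <- Biostrings::start(Biostrings::matchPattern(fwd, subj))
    re <- Biostrings::end(Biostrings::matchPattern(revc, subj))
    for (s in fs) {
      ends <- re[re >= s + nchar(fwd) & re - s + 1L <= max_product]
      for (e in ends) {
        products[[length(products) + 1L]] <- list(
          chrom = chrom, start = s, end = e,
          sequence = substr(genome[[chrom]], s, e))
      }
    }
  }
  if (!length(products)) return(NULL)
  if (length(products) > 1L) {
    loci <- vapply(products, function(p) sprintf("%s:%d-%d", p$chrom, p$start, p$end), "")
    stop("primers amplify multiple loci: ", paste(loci, collapse = ", "))
  }
  products[[1L]]
}

#' Digest a sequence with one restriction enzyme
#'
#' Cuts at every occurrence of the recognition site (overlapping occurrences
#' included), `cut_offset` bases into the site from its 5' end (0 cuts
#' immediately before the site). Fragment lengths always sum to the input
#' length.
#'
#' @param sequence DNA string.
#' @param site recognition sequence (ACGT).
#' @param cut_offset bases of the site left of the cut.
#' @return sorted integer vector of fragment lengths.
#' @export
digest <- function(sequence, site, cut_offset = 0) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", site)) stop("recognition site must be ACGT only")
  if (nchar(site) < 4L) stop("recognition site shorter than 4 bases")
  len <- nchar(sequence)
  m <- Biostrings::matchPattern(toupper(site), Biostrings::DNAString(sequence))
  cuts <- as.integer(Biostrings::start(m) - 1L + cut_offset)
  cuts <- sort(unique(cuts[cuts > 0L & cuts < len]))
  sort(diff(c(0L, cuts, len)))
}

# do two fragment-length multisets match within a relative tolerance?
patterns_match <- function(a, b, tolerance = 0) {
  if (length(a) != length(b)) return(FALSE)
  a <- sort(a); b <- sort(b)
  all(abs(a - b) <= tolerance * pmax(a, b))
}

#' Call a CAPS genotype from fragment patterns
#'
#' Compares the line's digestion pattern (fragment-length multiset) with the
#' two parental patterns of the same assay. An exact (within tolerance)
#' match to one parent calls that parent; a match to the union of both
#' parental patterns calls heterozygous; identical parental patterns make
#' the assay uninformative regardless of the line.
#'
#' @param line_fragments,background_fragments,donor_fragments integer
#'   vectors of fragment lengths from [digest()].
#' @param tolerance relative length tolerance (0 = exact; 0.05 mimics
#'   agarose-gel resolution).
#' @return one of `"background"`, `"donor"`, `"heterozygous"`,
#'   `"uninformative"`.
#' @export
caps_genotype <- function(line_fragments, background_fragments,
                          donor_fragments, tolerance = 0) {
  if (patterns_match(background_fragments, donor_fragments, tolerance)) {
    return("uninformative")
  }
  if (patterns_match(line_fragments, donor_fragments, tolerance)) return("donor")
  if (patterns_match(line_fragments, background_fragments, tolerance)) {
    return("background")
  }
  union_pattern <- sort(unique(c(background_fragments, donor_fragments)))
  if (patterns_match(sort(unique(line_fragments)), union_pattern, tolerance)) {
    return("heterozygous")
  }
  "uninformative"
}

#' Find enzymes that distinguish two amplicon alleles
#'
#' Screens an enzyme table for enzymes whose digestion patterns differ
#' between the background and donor alleles of an amplicon - the in-silico
#' equivalent of scanning polymorphic SNPs for created/destroyed restriction
#' sites.
#'
#' @param amp_background,amp_donor the two allelic amplicon sequences.
#' @param enzymes data.frame with `enzyme`, `site`, `cut_offset`
#'   (default [restriction_enzymes()]).
#' @param tolerance relative fragment-length tolerance for calling two
#'   patterns equal.
#' @return data.frame of informative enzymes with both expected patterns
#'   (comma-separated fragment lengths); zero rows if none distinguish.
#' @export
design_caps <- function(amp_background, amp_donor,
                        enzymes = restriction_enzymes(), tolerance = 0) {
  if (!nrow(enzymes)) stop("empty enzyme table")
  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    pb <- digest(amp_background, enzymes$site[i], enzymes$cut_offset[i])
    pd <- digest(amp_donor, enzymes$site[i], enzymes$cut_offset[i])
    if (!patterns_match(pb, pd, tolerance)) {
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = enzymes$enzyme[i], site = enzymes$site[i],
        cut_offset = enzymes$cut_offset[i],
        pattern_background = paste(pb, collapse = ","),
        pattern_donor = paste(pd, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(enzyme = character(), site = character(),
                      cut_offset = integer(), pattern_background = character(),
                      pattern_donor = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Resolve unknown ancestry calls with marker genotypes
#'
#' Genes without expressed variant evidence stay `unknown` after the
#' dual-reference classification; informative SCAR/CAPS genotypes fill those
#' in. An unknown call with an informative marker genotype becomes that
#' genotype (provenance `"marker"`). A non-unknown call is never changed: a
#' marker genotype contradicting the variant evidence raises a `conflict`
#' flag instead.
#'
#' @param calls classified calls from [classify_ancestry()].
#' @param marker_calls data.frame with `gene_id` and `call`
#'   (`background` / `donor` / `heterozygous` / `uninformative`).
#' @return `calls` with updated `call`/`provenance` and a logical `conflict`
#'   column.
#' @export
resolve_unknowns <- function(calls, marker_calls) {
  if (!"conflict" %in% names(calls)) calls$conflict <- FALSE
  for (i in seq_len(nrow(marker_calls))) {
    g <- marker_calls$gene_id[i]
    mk <- marker_calls$call[i]
    j <- which(calls$gene_id == g)
    if (!length(j) || !(mk %in% c("background", "donor"))) next
    if (calls$call[j] == "unknown") {
      calls$call[j] <- mk
      calls$provenance[j] <- "marker"
    } else if (calls$call[j] != mk) {
      calls$conflict[j] <- TRUE
      warning("marker genotype for ", g, " (", mk,
              ") conflicts with variant call (", calls$call[j], ")")
    }
  }
  calls
}
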