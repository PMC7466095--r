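#' Build a reconstruction map
#'
#' A reconstruction map is a piecewise coordinate mapping from two source
#' genomes (background, donor) into a merged target genome: an ordered table
#' of segments, each copying `[source_start, source_end]` of `source_chrom`
#' in the `source` genome onto `[target_start, target_end]` of
#' `target_chrom`. Target segments must tile each target chromosome
#' contiguously from 1 without overlap, and each segment's target length
#' must equal its source length, so the map is invertible per source.
#'
#' @param segments data.frame with columns `source` (`background`/`donor`),
#'   `source_chrom`, `source_start`, `source_end`, `target_chrom`,
#'   `target_start`, `target_end`.
#' @return data.frame of class `reconstruction_map`.
#' @export
reconstruction_map <- function(segments) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need <- c("source", "source_chrom", "source_start", "source_end",
            "target_chrom", "target_start", "target_end")
  if (!all(need %in% names(segments))) {
    stop("reconstruction_map: need columns ", paste(need, collapse = ", "))
  }
  src_len <- segments$source_end - segments$source_start
  tgt_len <- segments$target_end - segments$target_start
  if (any(src_len != tgt_len)) {
    stop("reconstruction_map: segment source and target lengths differ")
  }
  if (any(src_len < 0)) stop("reconstruction_map: segment with negative length")
  for (ch in unique(segments$target_chrom)) {
    s <- segments[segments$target_chrom == ch, , drop = FALSE]
    s <- s[order(s$target_start), , drop = FALSE]
    if (s$target_start[1] != 1L) {
      stop("reconstruction_map: target chromosome ", ch, " does not start at 1")
    }
    if (nrow(s) > 1L && any(s$target_start[-1L] != s$target_end[-nrow(s)] + 1L)) {
      stop("reconstruction_map: target segments not contiguous on ", ch)
    }
  }
  class(segments) <- c("reconstruction_map", "data.frame")
  segments
}

#' Invert a reconstruction map
#'
#' Swaps source and target so that coordinates can be carried back from the
#' merged genome into one source genome.
#'
#' @param map a [reconstruction_map()].
#' @param source which source genome to invert onto.
#' @return data.frame of segments mapping target coordinates to that source
#'   (not a `reconstruction_map`, since source coordinates need not tile).
#' @export
invert_map <- function(map, source = c("background", "donor")) {
  source <- match.arg(source)
  s <- map[map$source == source, , drop = FALSE]
  data.frame(source = "target",
             source_chrom = s$target_chrom,
             source_start = s$target_start, source_end = s$target_end,
             target_chrom = s$source_chrom,
             target_start = s$source_start, target_end = s$source_end,
             stringsAsFactors = FALSE)
}

# map a single position through a segment table; NA if not covered
map_position <- function(segments, chrom, pos, source = NULL) {
  s <- segments
  if (!is.null(source) && "source" %in% names(s)) {
    s <- s[s$source == source, , drop = FALSE]
  }
  hit <- which(s$source_chrom == chrom & s$source_start <= pos & s$source_end >= pos)
  if (!length(hit)) return(NA_integer_)
  i <- hit[1L]
  s$target_start[i] + (pos - s$source_start[i])
}

#' Infer introgression breakpoint intervals from ordered ancestry calls
#'
#' The donor block is the maximal run of donor-called genes along the
#' background coordinate system; interleaved `unknown` calls (unexpressed
#' genes) bridge the run up to `max_bridge` genes, while a background call
#' breaks it. Each block edge gets an open uncertainty interval: at the
#' lower edge, from the last background evidence before the block (the last
#' background-called gene's end, or a variant within it) to the first
#' donor-diagnostic variant inside the block; mirrored at the upper edge.
#' Block edges without flanking evidence degenerate to the chromosome edges
#' (0 / `Inf`).
#'
#' @param calls ancestry calls carrying gene coordinates: data.frame with
#'   `gene_id`, `chrom`, `start`, `end`, `call`, sorted or sortable by
#'   position on the background genome.
#' @param variants filtered [variant_table()] called against the background
#'   reference (donor-diagnostic positions).
#' @param max_bridge maximum run of unknown calls bridged inside a block.
#' @param strict error when more than one donor block is found.
#' @return data.frame of class `breakpoint_intervals`, one row per block:
#'   `chrom`, `first_gene`, `last_gene`, `n_genes`, `lower_last_background`,
#'   `lower_first_donor`, `upper_last_donor`, `upper_first_background`.
#' @export
infer_breakpoints <- function(calls, variants, max_bridge = 3, strict = TRUE) {
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  if (!any(calls$call == "donor")) stop("no introgression detected")
  blocks <- list()
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    don <- which(cc$call == "donor")
    if (!length(don)) next
    # group donor indices: same block while the gap contains no background
    # call and at most max_bridge unknowns
    start_i <- don[1L]
    prev <- don[1L]
    for (i in don[-1L]) {
      broken <- FALSE
      if (i - prev > 1L) {
        gap <- (prev + 1L):(i - 1L)
        broken <- any(cc$call[gap] == "background") || length(gap) > max_bridge
      }
      if (broken) {
        blocks[[length(blocks) + 1L]] <- list(chrom = ch, idx = start_i:prev, cc = cc)
        start_i <- i
      }
      prev <- i
    }
    blocks[[length(blocks) + 1L]] <- list(chrom = ch, idx = start_i:prev, cc = cc)
  }
  if (strict && length(blocks) > 1L) {
    desc <- vapply(blocks, function(b) {
      sprintf("%s:%s..%s", b$chrom, b$cc$gene_id[b$idx[1]], b$cc$gene_id[rev(b$idx)[1]])
    }, "")
    stop("multiple donor blocks found in strict mode: ", paste(desc, collapse = "; "))
  }
  rows <- lapply(blocks, function(b) {
    cc <- b$cc
    idx <- b$idx
    block_genes <- cc[idx, , drop = FALSE]
    block_start <- min(block_genes$start)
    block_end <- max(block_genes$end)
    v <- variants[variants$chrom == b$chrom, , drop = FALSE]
    # donor-diagnostic variants inside the block's gene spans
    in_block <- logical(nrow(v))
    bg_donor <- block_genes[block_genes$call == "donor", , drop = FALSE]
    for (j in seq_len(nrow(bg_donor))) {
      in_block <- in_block | (v$pos >= bg_donor$start[j] & v$pos <= bg_donor$end[j])
    }
    first_donor_var <- if (any(in_block)) min(v$pos[in_block]) else block_start
    last_donor_var <- if (any(in_block)) max(v$pos[in_block]) else block_end
    before <- cc[cc$end < block_start & cc$call == "background", , drop = FALSE]
    after <- cc[cc$start > block_end & cc$call == "background", , drop = FALSE]
    lower_bg <- if (nrow(before)) max(before$end) else 0
    upper_bg <- if (nrow(after)) min(after$start) else Inf
    data.frame(chrom = b$chrom,
               first_gene = block_genes$gene_id[1L],
               last_gene = block_genes$gene_id[nrow(block_genes)],
               n_genes = nrow(block_genes),
               lower_last_background = lower_bg,
               lower_first_donor = first_donor_var,
               upper_last_donor = last_donor_var,
               upper_first_background = upper_bg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("breakpoint_intervals", "data.frame")
  out
}

#' Merge the background and donor genomes into the line's genome
#'
#' Reconstructs the introgression line's genome: the background genome with
#' the region between the breakpoints replaced by the donor's complementary
#' segment. Cut placement inside each open uncertainty interval defaults to
#' its midpoint (the evidence only bounds the crossover); `"last_donor"` /
#' `"first_background"` anchor the cuts at the bounding evidence instead.
#' Chromosomes without a block are carried over unchanged as identity
#' segments.
#'
#' @param background,donor named character vectors of sequences.
#' @param donor_span donor-side source span: list with `chrom`, `start`,
#'   `end` (or `NULL` for no replacement, yielding an identity
#'   reconstruction of the background).
#' @param breakpoints single-block [infer_breakpoints()] result.
#' @param cut cut placement rule within each uncertainty interval.
#' @return list with `genome` (named character vector) and `map`
#'   (a [reconstruction_map()]).
#' @export
merge_genomes <- function(background, donor, donor_span, breakpoints,
                          cut = c("midpoint", "last_donor", "first_background")) {
  cut <- match.arg(cut)
  segs <- list()
  add <- function(source, schrom, s, e, tchrom, ts) {
    segs[[length(segs) + 1L]] <<- data.frame(
      source = source, source_chrom = schrom, source_start = s, source_end = e,
      target_chrom = tchrom, target_start = ts, target_end = ts + (e - s),
      stringsAsFactors = FALSE)
  }
  if (is.null(donor_span)) {
    for (ch in names(background)) {
      add("background", ch, 1L, nchar(background[[ch]]), ch, 1L)
    }
  } else {
    if (nrow(breakpoints) != 1L) stop("merge_genomes expects exactly one block")
    bp <- breakpoints[1L, ]
    ch <- bp$chrom
    len <- nchar(background[[ch]])
    low <- switch(cut,
      midpoint = floor((max(bp$lower_last_background, 0) + bp$lower_first_donor) / 2),
      last_donor = bp$lower_first_donor - 1L,
      first_background = max(bp$lower_last_background, 0))
    up <- switch(cut,
      midpoint = ceiling((bp$upper_last_donor + min(bp$upper_first_background, len + 1)) / 2),
      last_donor = bp$upper_last_donor + 1L,
      first_background = min(bp$upper_first_background, len + 1))
    if (low >= up) stop("merge_genomes: overlapping cuts (lower >= upper)")
    pos <- 1L
    if (low >= 1L) {
      add("background", ch, 1L, low, ch, pos)
      pos <- pos + low
    }
    dlen <- donor_span$end - donor_span$start + 1L
    if (dlen > 0L) {
      add("donor", donor_span$chrom, donor_span$start, donor_span$end, ch, pos)
      pos <- pos + dlen
    }
    if (up <= len) add("background", ch, up, len, ch, pos)
    for (other in setdiff(names(background), ch)) {
      add("background", other, 1L, nchar(background[[other]]), other, 1L)
    }
  }
  map <- reconstruction_map(do.call(rbind, segs))
  genome <- vapply(unique(map$target_chrom), function(tch) {
    s <- map[map$target_chrom == tch, , drop = FALSE]
    s <- s[order(s$target_start), , drop = FALSE]
    paste(vapply(seq_len(nrow(s)), function(i) {
      src <- if (s$source[i] == "background") background else donor
      substr(src[[s$source_chrom[i]]], s$source_start[i], s$source_end[i])
    }, ""), collapse = "")
  }, "")
  names(genome) <- unique(map$target_chrom)
  list(genome = genome, map = map)
}

#' Lift gene models through a reconstruction map
#'
#' Transfers gene (and feature) coordinates from one source genome onto the
#' reconstructed target. A gene fully inside one segment of its source is
#' shifted by that segment's offset. A gene overlapping a segment boundary
#' (a junction of the reconstruction) is returned in `chimeric_candidates`
#' rather than silently lifted; a gene outside every segment of its source
#' is returned in `unmapped`.
#'
#' @param map a [reconstruction_map()] (or an [invert_map()] result, with
#'   `source = "target"`).
#' @param ann a [annotation()] in source coordinates.
#' @param source which source the annotation belongs to.
#' @return list with `lifted` (a [annotation()]), `chimeric_candidates` and
#'   `unmapped` (gene data frames).
#' @export
liftover <- function(map, ann, source = c("background", "donor", "target")) {
  source <- match.arg(source)
  s <- map[map$source == source, , drop = FALSE]
  g <- ann$genes
  status <- character(nrow(g))
  offset <- integer(nrow(g))
  tchrom <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    seg <- s[s$source_chrom == g$chrom[i], , drop = FALSE]
    contains <- seg$source_start <= g$start[i] & seg$source_end >= g$end[i]
    touches <- intervals_overlap(seg$source_start, seg$source_end, g$start[i], g$end[i])
    if (any(contains)) {
      j <- which(contains)[1L]
      status[i] <- "lifted"
      offset[i] <- seg$target_start[j] - seg$source_start[j]
      tchrom[i] <- seg$target_chrom[j]
    } else if (any(touches)) {
      status[i] <- "chimeric"
    } else {
      status[i] <- "unmapped"
    }
  }
  lifted_genes <- g[status == "lifted", , drop = FALSE]
  if (nrow(lifted_genes)) {
    off <- offset[status == "lifted"]
    lifted_genes$start <- lifted_genes$start + off
    lifted_genes$end <- lifted_genes$end + off
    lifted_genes$chrom <- tchrom[status == "lifted"]
  }
  f <- ann$features[ann$features$gene_id %in% lifted_genes$gene_id, , drop = FALSE]
  if (nrow(f)) {
    off_by_gene <- stats::setNames(offset[status == "lifted"],
                                   g$gene_id[status == "lifted"])
    f$start <- f$start + off_by_gene[f$gene_id]
    f$end <- f$end + off_by_gene[f$gene_id]
  }
  list(lifted = annotation(lifted_genes, f),
       chimeric_candidates = g[status == "chimeric", , drop = FALSE],
       unmapped = g[status == "unmapped", , drop = FALSE])
}

# longest strictly increasing subsequence; returns indices (O(n log n),
# deterministic: leftmost optimum)
lis_indices <- function(x) {
  n <- length(x)
  if (!n) return(integer())
  tails <- integer(0)   # index of smallest tail of an increasing subseq of each length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {  # first position with tail value >= x[i]
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(length(tails))
  k <- tails[length(tails)]
  for (j in rev(seq_along(tails))) {
    out[j] <- k
    k <- prev[k]
  }
  out
}

#' Check segment order between the parental gene arrangements
#'
#' A desk-scale collinearity check: one-to-one ortholog pairs are ranked by
#' position in each parent; the collinear subset is the longest subsequence
#' strictly increasing in both ranks, and every maximal run of excluded
#' pairs (consecutive in background order) is reported as a translocated
#' block.
#'
#' @param relations data.frame with `donor_gene_id`, `background_gene_id`,
#'   `relation`; only one-to-one relations (`BBH`, `homology`) are used.
#' @param donor_order,background_order character vectors of gene ids in
#'   coordinate order on each parent.
#' @return list with `pairs` (rank table with `in_collinear` flag) and
#'   `translocated_blocks` (list of character vectors of donor gene ids);
#'   empty report on empty input.
#' @export
segment_order_check <- function(relations, donor_order, background_order) {
  r <- relations[relations$relation %in% c("BBH", "homology") &
                   !is.na(relations$donor_gene_id) &
                   !is.na(relations$background_gene_id), , drop = FALSE]
  r$donor_rank <- match(r$donor_gene_id, donor_order)
  r$background_rank <- match(r$background_gene_id, background_order)
  r <- r[!is.na(r$donor_rank) & !is.na(r$background_rank), , drop = FALSE]
  if (!nrow(r)) {
    return(list(pairs = data.frame(), translocated_blocks = list()))
  }
  r <- r[order(r$background_rank), , drop = FALSE]
  keep <- lis_indices(r$donor_rank)
  r$in_collinear <- seq_len(nrow(r)) %in% keep
  excl <- which(!r$in_collinear)
  blocks <- list()
  if (length(excl)) {
    grp <- cumsum(c(1L, diff(excl) != 1L))
    blocks <- lapply(split(excl, grp), function(ix) r$donor_gene_id[ix])
    names(blocks) <- NULL
  }
  rownames(r) <- NULL
  list(pairs = r[, c("donor_gene_id", "background_gene_id", "relation",
                     "donor_rank", "background_rank", "in_collinear")],
       translocated_blocks = blocks)
}
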