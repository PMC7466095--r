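#' Configuration for the synthetic introgression-line generator
#'
#' Defines the study conditions the generator emulates: two divergent
#' parental genomes with shared, species-specific and duplicated genes, a
#' homozygous introgression on one chromosome whose upper crossover can fall
#' inside the last block gene's 3'UTR, expression-dependent variant
#' visibility, and a low rate of stray singleton variants. Defaults give
#' ~17 diagnostic variants per 1.7 kb gene at an 80:20 SNP:INDEL mixture.
#'
#' @param seed integer seed; one pseudo-random stream per operation is
#'   derived from it, so identical configs give byte-identical outputs.
#' @param n_chromosomes,chromosome_length,n_genes_per_chromosome genome
#'   layout. Genes are laid out on a fixed grid of non-overlapping,
#'   plus-strand slots.
#' @param snp_rate,indel_rate substitutions / indel events per bp between
#'   the parents.
#' @param indel_len_geometric_p geometric length parameter for indels
#'   (lengths capped at 50 bp; indels never span feature boundaries).
#' @param n_species_specific_donor,n_species_specific_background,n_duplicated
#'   extra genes annotated in only one parent (placed on the last
#'   chromosome, away from the introgression).
#' @param introgression_chromosome,introgression_gene_span chromosome index
#'   and (first, last) shared-gene indices of the planted donor block;
#'   `NULL` span plants nothing.
#' @param breakpoint_in_utr place the upper crossover strictly inside the
#'   3'UTR of the last block gene, producing a chimeric gene.
#' @param expression_dropout fraction of genes emitting no variants
#'   (unexpressed).
#' @param variant_error_rate spurious isolated variants per bp.
#' @param utr5_length,cds_length,utr3_length fixed feature layout of every
#'   gene (5'UTR-CDS-3'UTR).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 2L, chromosome_length = 75000L,
                       n_genes_per_chromosome = 20L,
                       snp_rate = 0.008, indel_rate = 0.002,
                       indel_len_geometric_p = 0.5,
                       n_species_specific_donor = 2L,
                       n_species_specific_background = 2L,
                       n_duplicated = 1L,
                       introgression_chromosome = 1L,
                       introgression_gene_span = c(8L, 14L),
                       breakpoint_in_utr = TRUE,
                       expression_dropout = 0.2,
                       variant_error_rate = 1e-5,
                       utr5_length = 200L, cds_length = 1200L,
                       utr3_length = 300L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_genes_per_chromosome = as.integer(n_genes_per_chromosome),
              snp_rate = snp_rate, indel_rate = indel_rate,
              indel_len_geometric_p = indel_len_geometric_p,
              n_species_specific_donor = as.integer(n_species_specific_donor),
              n_species_specific_background = as.integer(n_species_specific_background),
              n_duplicated = as.integer(n_duplicated),
              introgression_chromosome = as.integer(introgression_chromosome),
              introgression_gene_span = introgression_gene_span,
              breakpoint_in_utr = isTRUE(breakpoint_in_utr),
              expression_dropout = expression_dropout,
              variant_error_rate = variant_error_rate,
              utr5_length = as.integer(utr5_length),
              cds_length = as.integer(cds_length),
              utr3_length = as.integer(utr3_length))
  for (f in c("snp_rate", "indel_rate", "indel_len_geometric_p",
              "expression_dropout", "variant_error_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("sim_config: ", f, " outside [0,1]")
  }
  footprint <- cfg$utr5_length + cfg$cds_length + cfg$utr3_length
  cfg$gene_footprint <- footprint
  cfg$slot_length <- footprint + 1300L  # >= 600 bp margin each side
  n_extra <- cfg$n_species_specific_donor + cfg$n_species_specific_background +
    cfg$n_duplicated
  max_slots <- cfg$chromosome_length %/% cfg$slot_length
  if (cfg$n_genes_per_chromosome > max_slots) {
    stop("sim_config: chromosome_length too small for n_genes_per_chromosome")
  }
  if (cfg$n_genes_per_chromosome + n_extra > max_slots) {
    stop("sim_config: chromosome_length too small for the extra ",
         "species-specific/duplicated genes on the last chromosome")
  }
  if (!is.null(cfg$introgression_gene_span)) {
    sp <- cfg$introgression_gene_span
    if (length(sp) != 2L || sp[1] > sp[2] || sp[1] < 1L ||
        sp[2] > cfg$n_genes_per_chromosome) {
      stop("sim_config: introgression_gene_span outside the gene count")
    }
    if (cfg$introgression_chromosome < 1L ||
        cfg$introgression_chromosome > cfg$n_chromosomes) {
      stop("sim_config: introgression_chromosome outside n_chromosomes")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

SIM_BASES <- c("A", "C", "G", "T")

sim_chrom_name <- function(i) sprintf("chr%02d", i)

# gene grid for one chromosome: shared slots 1..n, extras appended
sim_gene_layout <- function(cfg, chrom_i, n_extra_here = 0L) {
  n <- cfg$n_genes_per_chromosome + n_extra_here
  slot0 <- (seq_len(n) - 1L) * cfg$slot_length
  start <- slot0 + 601L
  data.frame(slot = seq_len(n), start = start,
             end = start + cfg$gene_footprint - 1L,
             utr5_end = start + cfg$utr5_length - 1L,
             cds_end = start + cfg$utr5_length + cfg$cds_length - 1L)
}

# map background positions to donor positions through a per-chromosome
# indel table (anchor, delta); positions inside deleted ranges are invalid
bg_to_donor_pos <- function(map, pos) {
  if (!nrow(map)) return(as.integer(pos))
  cum <- c(0L, cumsum(map$delta))
  as.integer(pos + cum[findInterval(pos - 0.5, map$anchor) + 1L])
}

#' Generate a divergent parental genome pair with a truth record
#'
#' Background genome drawn uniformly over ACGT; donor genome derived from it
#' by planting substitutions and short indels at the configured rates, with
#' indels kept strictly inside one feature/intergenic region so coordinate
#' arithmetic stays exact. Shared genes are annotated in both parents at
#' homologous positions; species-specific and duplicated extra genes are
#' annotated in one parent only, on the last chromosome. Every planted
#' difference is recorded in a variant ledger (background coordinates,
#' left-anchored indels) together with per-chromosome coordinate maps.
#'
#' @param config a [sim_config()].
#' @return object of class `intro_sim`: `config`, `background` and `donor`
#'   (each `genome` + `annotation`), `ledger`, `maps`, `truth`.
#' @export
generate_parents <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)
  L <- cfg$chromosome_length
  n_ssd <- cfg$n_species_specific_donor
  n_ssb <- cfg$n_species_specific_background
  n_dup <- cfg$n_duplicated

  bg_genome <- character(cfg$n_chromosomes)
  donor_genome <- character(cfg$n_chromosomes)
  names(bg_genome) <- names(donor_genome) <- sim_chrom_name(seq_len(cfg$n_chromosomes))
  ledger <- list()
  maps <- list()
  bg_genes <- list(); bg_features <- list()
  dn_genes <- list(); dn_features <- list()
  truth_genes <- list()

  for (ci in seq_len(cfg$n_chromosomes)) {
    ch <- sim_chrom_name(ci)
    last <- ci == cfg$n_chromosomes
    n_extra_here <- if (last) n_ssd + n_ssb + n_dup else 0L
    layout <- sim_gene_layout(cfg, ci, n_extra_here)

    bg_chars <- sample(SIM_BASES, L, replace = TRUE)

    # region partition (feature boundaries) so indels never span a boundary
    breaks <- sort(unique(c(0L, layout$start - 1L, layout$utr5_end,
                            layout$cds_end, layout$end, L)))
    region_of <- function(p) findInterval(p, breaks, left.open = TRUE)

    n_sub <- stats::rbinom(1L, L, cfg$snp_rate)
    sub_pos <- sort(sample.int(L, n_sub))
    sub_alt <- vapply(sub_pos, function(p) {
      sample(setdiff(SIM_BASES, bg_chars[p]), 1L)
    }, "")

    n_ind <- stats::rbinom(1L, L - 60L, cfg$indel_rate)
    ind_anchor <- sort(sample.int(L - 60L, n_ind))
    ind_len <- pmin(stats::rgeom(n_ind, cfg$indel_len_geometric_p) + 1L, 50L)
    ind_ins <- stats::runif(n_ind) < 0.5

    occupied <- logical(L)
    occupied[sub_pos] <- TRUE
    keep <- logical(n_ind)
    for (k in seq_len(n_ind)) {
      a <- ind_anchor[k]; len <- ind_len[k]
      span <- if (ind_ins[k]) a:(a + 1L) else a:(a + len)
      if (!ind_ins[k] && region_of(a + 1L) != region_of(a + len)) next
      if (any(occupied[span])) next
      occupied[span] <- TRUE
      keep[k] <- TRUE
    }
    ind_anchor <- ind_anchor[keep]; ind_len <- ind_len[keep]; ind_ins <- ind_ins[keep]

    led <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), class = character(), delta = integer(),
                      stringsAsFactors = FALSE)
    if (n_sub) {
      led <- rbind(led, data.frame(chrom = ch, pos = sub_pos,
                                   ref = bg_chars[sub_pos], alt = sub_alt,
                                   class = "SNP", delta = 0L,
                                   stringsAsFactors = FALSE))
    }
    if (length(ind_anchor)) {
      ins_seq <- vapply(ind_len, function(l) {
        paste(sample(SIM_BASES, l, replace = TRUE), collapse = "")
      }, "")
      ref <- character(length(ind_anchor)); alt <- character(length(ind_anchor))
      for (k in seq_along(ind_anchor)) {
        a <- ind_anchor[k]
        if (ind_ins[k]) {
          ref[k] <- bg_chars[a]
          alt[k] <- paste0(bg_chars[a], ins_seq[k])
        } else {
          ref[k] <- paste(bg_chars[a:(a + ind_len[k])], collapse = "")
          alt[k] <- bg_chars[a]
        }
      }
      led <- rbind(led, data.frame(chrom = ch, pos = ind_anchor, ref = ref,
                                   alt = alt,
                                   class = "INDEL",
                                   delta = ifelse(ind_ins, ind_len, -ind_len),
                                   stringsAsFactors = FALSE))
    }
    led <- led[order(led$pos), , drop = FALSE]
    rownames(led) <- NULL
    ledger[[ch]] <- led
    maps[[ch]] <- data.frame(anchor = led$pos[led$class == "INDEL"],
                             delta = led$delta[led$class == "INDEL"])

    # donor sequence: substitutions, then indels assembled left to right
    dn_chars <- bg_chars
    if (n_sub) dn_chars[sub_pos] <- sub_alt
    bg_str <- paste(bg_chars, collapse = "")
    dn_sub_str <- paste(dn_chars, collapse = "")
    if (nrow(maps[[ch]])) {
      pieces <- character(0)
      lastp <- 1L
      idx <- which(led$class == "INDEL")
      for (k in idx) {
        a <- led$pos[k]
        pieces <- c(pieces, substr(dn_sub_str, lastp, a))
        if (led$delta[k] > 0L) {         # insertion after the anchor base
          pieces <- c(pieces, substr(led$alt[k], 2L, nchar(led$alt[k])))
          lastp <- a + 1L
        } else {                          # deletion of the bases after the anchor
          lastp <- a - led$delta[k] + 1L
        }
      }
      pieces <- c(pieces, substr(dn_sub_str, lastp, L))
      donor_genome[ch] <- paste(pieces, collapse = "")
    } else {
      donor_genome[ch] <- dn_sub_str
    }
    bg_genome[ch] <- bg_str

    # annotations
    f_of <- function(p) bg_to_donor_pos(maps[[ch]], p)
    for (gi in seq_len(nrow(layout))) {
      row <- layout[gi, ]
      shared <- gi <= cfg$n_genes_per_chromosome
      if (shared) {
        cls <- "shared"
      } else {
        k <- gi - cfg$n_genes_per_chromosome
        cls <- if (k <= n_ssd) "donor_specific"
          else if (k <= n_ssd + n_ssb) "background_specific"
          else "duplicated_copy"
      }
      bid <- sprintf("BG%02dG%03d", ci, gi)
      did <- sprintf("DN%02dG%03d", ci, gi)
      feat <- function(id, s, u5e, ce, e) {
        data.frame(gene_id = id,
                   kind = c("five_prime_UTR", "CDS", "three_prime_UTR"),
                   start = c(s, u5e + 1L, ce + 1L),
                   end = c(u5e, ce, e), stringsAsFactors = FALSE)
      }
      in_bg <- cls %in% c("shared", "background_specific")
      in_dn <- cls %in% c("shared", "donor_specific", "duplicated_copy")
      if (in_bg) {
        bg_genes[[length(bg_genes) + 1L]] <- data.frame(
          gene_id = bid, chrom = ch, start = row$start, end = row$end,
          strand = "+", stringsAsFactors = FALSE)
        bg_features[[length(bg_features) + 1L]] <-
          feat(bid, row$start, row$utr5_end, row$cds_end, row$end)
      }
      if (in_dn) {
        ds <- f_of(row$start); du5 <- f_of(row$utr5_end)
        dce <- f_of(row$cds_end); de <- f_of(row$end)
        dn_genes[[length(dn_genes) + 1L]] <- data.frame(
          gene_id = did, chrom = ch, start = ds, end = de,
          strand = "+", stringsAsFactors = FALSE)
        dn_features[[length(dn_features) + 1L]] <- feat(did, ds, du5, dce, de)
      }
      truth_genes[[length(truth_genes) + 1L]] <- data.frame(
        chrom = ch, index = gi, class = cls,
        background_gene_id = if (in_bg) bid else NA_character_,
        donor_gene_id = if (in_dn) did else NA_character_,
        ancestry = "background", stringsAsFactors = FALSE)
    }
  }

  truth <- list(genes = do.call(rbind, truth_genes),
                species_specific_donor =
                  unlist(lapply(truth_genes, function(g)
                    if (g$class == "donor_specific") g$donor_gene_id else NULL)),
                species_specific_background =
                  unlist(lapply(truth_genes, function(g)
                    if (g$class == "background_specific") g$background_gene_id else NULL)),
                duplicated =
                  unlist(lapply(truth_genes, function(g)
                    if (g$class == "duplicated_copy") g$donor_gene_id else NULL)),
                breakpoints = NULL, chimeric_gene = NA_character_,
                crossover = NA_integer_)
  truth$genes$expressed <- stats::runif(nrow(truth$genes)) >= cfg$expression_dropout

  structure(list(config = cfg,
                 background = list(genome = bg_genome,
                                   annotation = annotation(do.call(rbind, bg_genes),
                                                           do.call(rbind, bg_features))),
                 donor = list(genome = donor_genome,
                              annotation = annotation(do.call(rbind, dn_genes),
                                                      do.call(rbind, dn_features))),
                 ledger = ledger, maps = maps, truth = truth),
            class = "intro_sim")
}

#' @export
print.intro_sim <- function(x, ...) {
  cat("intro_sim:", x$config$n_chromosomes, "chromosome(s) x",
      x$config$chromosome_length, "bp,",
      nrow(x$background$annotation$genes), "background /",
      nrow(x$donor$annotation$genes), "donor genes,",
      sum(vapply(x$ledger, nrow, 0L)), "planted differences",
      if (!is.null(x$truth$breakpoints)) "(introgression planted)" else "", "\n")
  invisible(x)
}

# positions deleted from the background in one chromosome's ledger
deleted_positions <- function(led) {
  d <- led[led$class == "INDEL" & led$delta < 0L, , drop = FALSE]
  if (!nrow(d)) return(integer())
  unlist(lapply(seq_len(nrow(d)), function(k) (d$pos[k] + 1L):(d$pos[k] - d$delta[k])))
}

#' Plant a homozygous introgression into the background genome
#'
#' Replaces the background segment between two cut points with the donor's
#' homologous segment, producing the line's genome. The lower cut falls in
#' the intergenic gap before the first block gene; the upper cut falls in
#' the intergenic gap after the last block gene, or - with
#' `breakpoint_in_utr` - strictly inside that gene's 3'UTR, making it
#' chimeric (donor 5'UTR+CDS+3'UTR head, background 3'UTR tail). The truth
#' record is updated with the block genes' ancestry, the cut positions
#' (background coordinates; `crossover` is the last donor base) and the
#' chimeric gene id.
#'
#' @param sim an `intro_sim` from [generate_parents()].
#' @param config configuration (defaults to the one inside `sim`).
#' @return `sim` with a `line` element (`genome` + [reconstruction_map()])
#'   and an updated truth record.
#' @export
plant_introgression <- function(sim, config = sim$config) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  span <- cfg$introgression_gene_span
  ich <- sim_chrom_name(cfg$introgression_chromosome)
  L <- cfg$chromosome_length
  segs <- list()
  add <- function(source, schrom, s, e, tchrom, ts) {
    segs[[length(segs) + 1L]] <<- data.frame(
      source = source, source_chrom = schrom, source_start = s, source_end = e,
      target_chrom = tchrom, target_start = ts, target_end = ts + (e - s),
      stringsAsFactors = FALSE)
  }
  if (is.null(span)) {
    for (ch in names(sim$background$genome)) add("background", ch, 1L, L, ch, 1L)
    sim$line <- list(genome = sim$background$genome,
                     map = reconstruction_map(do.call(rbind, segs)))
    return(sim)
  }
  tg <- sim$truth$genes
  extras_here <- tg$chrom == ich & tg$class != "shared"
  if (any(extras_here)) {
    stop("introgression span conflicts with species-specific/duplicated genes ",
         "on ", ich, "; place the introgression on another chromosome")
  }
  shared <- tg[tg$chrom == ich & tg$class == "shared", , drop = FALSE]
  g <- sim$background$annotation$genes
  gene_of <- function(i) g[g$gene_id == shared$background_gene_id[shared$index == i], ]
  g1 <- gene_of(span[1]); g2 <- gene_of(span[2])
  led <- sim$ledger[[ich]]
  dead <- deleted_positions(led)

  prev_end <- if (span[1] > 1L) gene_of(span[1] - 1L)$end else 0L
  cand_l <- setdiff((prev_end + 1L):(g1$start - 1L), dead)
  cutL <- cand_l[sample.int(length(cand_l), 1L)]

  if (cfg$breakpoint_in_utr) {
    utr3_start <- g2$end - cfg$utr3_length + 1L
    # the sequenced border gene shows locally elevated 3'UTR divergence
    # (multiple concordant variants on each side of the crossover); top the
    # chimeric gene's 3'UTR up to ~8 diagnostic substitutions so a
    # crossover with >= 3 flanking differences per side exists
    led_utr <- led[led$pos >= utr3_start & led$pos <= g2$end, , drop = FALSE]
    n_extra <- max(0L, 8L - nrow(led_utr))
    if (n_extra > 0L) {
      blocked <- unique(c(dead,
        unlist(lapply(seq_len(nrow(led)), function(k) {
          (led$pos[k] - 1L):(led$pos[k] + max(1L, abs(led$delta[k])) + 1L)
        }))))
      free <- setdiff((utr3_start + 2L):(g2$end - 2L), blocked)
      extra_pos <- sort(free[sample.int(length(free), min(n_extra, length(free)))])
      map_i <- sim$maps[[ich]]
      bgseq <- sim$background$genome[[ich]]
      for (p in extra_pos) {
        refb <- substr(bgseq, p, p)
        altb <- sample(setdiff(SIM_BASES, refb), 1L)
        dp <- bg_to_donor_pos(map_i, p)
        substr(sim$donor$genome[[ich]], dp, dp) <- altb
        led <- rbind(led, data.frame(chrom = ich, pos = p, ref = refb,
                                     alt = altb, class = "SNP", delta = 0L,
                                     stringsAsFactors = FALSE))
      }
      led <- led[order(led$pos), , drop = FALSE]
      rownames(led) <- NULL
      sim$ledger[[ich]] <- led
    }
    # place the crossover where the chimeric gene is localizable: at least
    # three diagnostic differences on each side within the gene, and at
    # least one donor-side difference already inside the 3'UTR
    cand_u <- setdiff((utr3_start + 5L):(g2$end - 5L), dead)
    vpos <- led$pos[led$pos >= g2$start & led$pos <= g2$end]
    vind <- led$class[led$pos >= g2$start & led$pos <= g2$end] == "INDEL"
    donor_side <- function(c) sum(ifelse(vind, vpos <= c - 1L, vpos <= c))
    bg_side <- function(c) sum(ifelse(vind, vpos >= c, vpos > c))
    utr_head <- function(c) sum(vpos >= utr3_start & ifelse(vind, vpos <= c - 1L, vpos <= c))
    ok <- vapply(cand_u, function(c) {
      donor_side(c) >= 3L && bg_side(c) >= 3L && utr_head(c) >= 1L
    }, logical(1))
    if (any(ok)) cand_u <- cand_u[ok]
  } else {
    next_start <- if (span[2] < cfg$n_genes_per_chromosome) {
      gene_of(span[2] + 1L)$start
    } else L + 1L
    cand_u <- setdiff((g2$end + 1L):(next_start - 1L), dead)
  }
  cutR <- cand_u[sample.int(length(cand_u), 1L)]

  map <- sim$maps[[ich]]
  dL <- bg_to_donor_pos(map, cutL)
  dR <- bg_to_donor_pos(map, cutR)
  line_seq <- paste0(substr(sim$background$genome[[ich]], 1L, cutL - 1L),
                     substr(sim$donor$genome[[ich]], dL, dR),
                     substr(sim$background$genome[[ich]], cutR + 1L, L))
  pos <- 1L
  if (cutL > 1L) { add("background", ich, 1L, cutL - 1L, ich, pos); pos <- pos + cutL - 1L }
  add("donor", ich, dL, dR, ich, pos); pos <- pos + (dR - dL + 1L)
  if (cutR < L) add("background", ich, cutR + 1L, L, ich, pos)
  for (ch in setdiff(names(sim$background$genome), ich)) {
    add("background", ch, 1L, L, ch, 1L)
  }
  genome <- sim$background$genome
  genome[ich] <- line_seq

  sim$line <- list(genome = genome,
                   map = reconstruction_map(do.call(rbind, segs)))
  block <- tg$chrom == ich & tg$class == "shared" &
    tg$index >= span[1] & tg$index <= span[2]
  sim$truth$genes$ancestry[block] <- "donor"
  sim$truth$breakpoints <- list(chrom = ich, lower = cutL, upper = cutR)
  sim$truth$crossover <- cutR
  if (cfg$breakpoint_in_utr) {
    sim$truth$chimeric_gene <- shared$donor_gene_id[shared$index == span[2]]
    sim$truth$chimeric_gene_background <- shared$background_gene_id[shared$index == span[2]]
  }
  sim
}

# is a ledger row part of the line's donor block?
row_in_block <- function(led, lower, upper) {
  snp <- led$class == "SNP" & led$pos >= lower & led$pos <= upper
  ind <- led$class == "INDEL" & led$pos >= lower & led$pos <= upper - 1L
  snp | ind
}

#' Simulate the line's expressed variant calls against one parent
#'
#' Emits, for every expressed gene of the chosen reference, all line-versus-
#' reference mismatches within the gene span as homozygous variants (the
#' transcriptome-derived callset: unexpressed genes emit nothing), plus
#' spurious isolated singleton variants at the configured error rate.
#' Against the background reference the mismatches are the donor-block
#' differences in background coordinates; against the donor reference they
#' are the differences outside the block - including the chimeric gene's
#' background tail - in donor coordinates.
#'
#' @param sim an `intro_sim` with a planted line.
#' @param reference `"background"` or `"donor"`.
#' @return a [variant_table()].
#' @export
simulate_variant_calls <- function(sim, reference = c("background", "donor")) {
  reference <- match.arg(reference)
  cfg <- sim$config
  if (is.null(sim$line)) stop("plant the introgression first (plant_introgression)")
  set.seed(cfg$seed + if (reference == "background") 2L else 3L)
  bp <- sim$truth$breakpoints
  tg <- sim$truth$genes
  ann <- sim[[reference]]$annotation
  expressed_ids <- c(tg$background_gene_id[tg$expressed], tg$donor_gene_id[tg$expressed])
  genes <- ann$genes[ann$genes$gene_id %in% expressed_ids, , drop = FALSE]

  rows <- list()
  for (ch in names(sim$ledger)) {
    led <- sim$ledger[[ch]]
    if (!nrow(led)) next
    in_block <- if (!is.null(bp) && bp$chrom == ch) {
      row_in_block(led, bp$lower, bp$upper)
    } else rep(FALSE, nrow(led))
    if (reference == "background") {
      cand <- led[in_block, , drop = FALSE]
      if (!nrow(cand)) next
      pos_out <- cand$pos
      ref_out <- cand$ref; alt_out <- cand$alt
    } else {
      cand <- led[!in_block, , drop = FALSE]
      if (!nrow(cand)) next
      pos_out <- bg_to_donor_pos(sim$maps[[ch]], cand$pos)
      ref_out <- cand$alt; alt_out <- cand$ref   # mirrored orientation
    }
    gch <- genes[genes$chrom == ch, , drop = FALSE]
    keep <- logical(length(pos_out))
    for (i in seq_len(nrow(gch))) {
      keep <- keep | (pos_out >= gch$start[i] & pos_out <= gch$end[i])
    }
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, pos = pos_out[keep], ref = ref_out[keep], alt = alt_out[keep],
      stringsAsFactors = FALSE)
  }
  true_vars <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  depth <- if (nrow(true_vars)) sample(10:60, nrow(true_vars), replace = TRUE) else numeric()

  # spurious isolated singletons (at most one per gene, never two adjacent)
  genome <- sim[[reference]]$genome
  total_len <- sum(nchar(genome))
  n_err <- stats::rbinom(1L, total_len, cfg$variant_error_rate)
  err_rows <- list()
  used_genes <- character()
  for (k in seq_len(n_err)) {
    ch <- sample(names(genome), 1L)
    p <- sample.int(nchar(genome[[ch]]), 1L)
    gch <- ann$genes[ann$genes$chrom == ch, , drop = FALSE]
    hit <- gch$gene_id[gch$start <= p & gch$end >= p]
    if (length(hit) && hit[1] %in% used_genes) next
    if (any(true_vars$chrom == ch & abs(true_vars$pos - p) <= 1L)) next
    used_genes <- c(used_genes, hit)
    base <- substr(genome[[ch]], p, p)
    if (stats::runif(1L) < 0.8) {
      err_rows[[length(err_rows) + 1L]] <- data.frame(
        chrom = ch, pos = p, ref = base,
        alt = sample(setdiff(SIM_BASES, base), 1L), stringsAsFactors = FALSE)
    } else {
      err_rows[[length(err_rows) + 1L]] <- data.frame(
        chrom = ch, pos = p, ref = base,
        alt = paste0(base, sample(SIM_BASES, 1L)), stringsAsFactors = FALSE)
    }
  }
  err <- if (length(err_rows)) do.call(rbind, err_rows) else NULL
  all_rows <- rbind(true_vars, err)
  depth_all <- c(depth, if (!is.null(err)) sample(8:40, nrow(err), replace = TRUE))
  o <- order(all_rows$chrom, all_rows$pos)
  variant_table(chrom = all_rows$chrom[o], pos = all_rows$pos[o],
                ref = all_rows$ref[o], alt = all_rows$alt[o],
                genotype_class = "homozygous", mean_depth = depth_all[o])
}

#' Ortholog pairing of the simulated parents
#' @param sim an `intro_sim`.
#' @return data.frame with `background_gene_id`, `donor_gene_id` for the
#'   shared genes.
#' @export
sim_gene_pairing <- function(sim) {
  tg <- sim$truth$genes
  s <- tg[tg$class == "shared", , drop = FALSE]
  data.frame(background_gene_id = s$background_gene_id,
             donor_gene_id = s$donor_gene_id, stringsAsFactors = FALSE)
}

#' Simulate differential-expression tables for two fruit stages
#'
#' Draws true up/down DEG sets (a common core shared by both stages, of
#' which a configurable number lies inside the introgressed block, plus
#' stage-specific extras) and emits one table per stage over all shared
#' background genes: truth genes get |logFC| above 1.5 with fdr < 0.05,
#' null genes get fdr >= 0.05. The drawn truth sets are recorded in
#' `sim$truth$deg`.
#'
#' @param sim an `intro_sim` (line may or may not be planted).
#' @param n_common_up,n_common_down sizes of the common DEG sets.
#' @param n_in_region how many common DEGs to place inside the donor block
#'   (ignored when no block is planted).
#' @param n_stage_only up/down extras per stage: list with `br_up`,
#'   `br_down`, `mr_up`, `mr_down`.
#' @return `sim` with `deg` (list of `BR` and `MR` data frames) and updated
#'   truth.
#' @export
simulate_deg_tables <- function(sim, n_common_up = 7L, n_common_down = 8L,
                                n_in_region = 5L,
                                n_stage_only = list(br_up = 2L, br_down = 2L,
                                                    mr_up = 3L, mr_down = 4L)) {
  cfg <- sim$config
  set.seed(cfg$seed + 4L)
  tg <- sim$truth$genes
  shared <- tg[tg$class == "shared", , drop = FALSE]
  g <- sim$background$annotation$genes
  ids <- shared$background_gene_id
  block_ids <- shared$background_gene_id[shared$ancestry == "donor"]
  n_in_region <- min(n_in_region, length(block_ids), n_common_up + n_common_down)

  in_region <- if (n_in_region > 0L) sample(block_ids, n_in_region) else character()
  pool <- setdiff(ids, block_ids)  # exactly n_in_region common DEGs in-block
  n_common <- n_common_up + n_common_down
  common <- c(in_region, sample(pool, n_common - length(in_region)))
  common_up <- common[seq_len(n_common_up)]
  common_down <- setdiff(common, common_up)
  pool2 <- setdiff(ids, common)
  extras <- sample(pool2, sum(unlist(n_stage_only)))
  br_up_x <- extras[seq_len(n_stage_only$br_up)]
  extras <- setdiff(extras, br_up_x)
  br_down_x <- extras[seq_len(n_stage_only$br_down)]
  extras <- setdiff(extras, br_down_x)
  mr_up_x <- extras[seq_len(n_stage_only$mr_up)]
  mr_down_x <- setdiff(extras, mr_up_x)

  truth_deg <- list(br_up = sort(c(common_up, br_up_x)),
                    br_down = sort(c(common_down, br_down_x)),
                    mr_up = sort(c(common_up, mr_up_x)),
                    mr_down = sort(c(common_down, mr_down_x)))

  make_table <- function(up, down, contrast) {
    m <- match(ids, g$gene_id)
    lfc <- stats::rnorm(length(ids), 0, 0.3)
    fdr <- stats::runif(length(ids), 0.05, 1)
    iu <- ids %in% up; idn <- ids %in% down
    lfc[iu] <- stats::runif(sum(iu), 1.5, 8)
    lfc[idn] <- -stats::runif(sum(idn), 1.5, 8)
    sig <- iu | idn
    fdr[sig] <- stats::runif(sum(sig), 1e-8, 0.01)
    data.frame(gene_id = ids, chrom = g$chrom[m], start = g$start[m],
               end = g$end[m], logFC = lfc, fdr = fdr, contrast = contrast,
               stringsAsFactors = FALSE)
  }
  sim$deg <- list(BR = make_table(truth_deg$br_up, truth_deg$br_down, "BR"),
                  MR = make_table(truth_deg$mr_up, truth_deg$mr_down, "MR"))
  sim$truth$deg <- truth_deg
  sim
}

#' Extract one shared gene's sequence from line and parents
#'
#' Uses the generator's coordinate maps to pull the gene's span out of the
#' background, donor and line genomes. Returns `NULL` for the line allele
#' when the gene straddles a reconstruction junction (the chimeric gene).
#'
#' @param sim an `intro_sim` with a planted line.
#' @param background_gene_id shared gene id (background side).
#' @return list with `background`, `donor`, `line` sequences (line possibly
#'   `NULL`).
#' @export
sim_gene_sequences <- function(sim, background_gene_id) {
  tg <- sim$truth$genes
  row <- tg[!is.na(tg$background_gene_id) &
              tg$background_gene_id == background_gene_id, , drop = FALSE]
  if (!nrow(row) || row$class != "shared") stop("not a shared gene: ", background_gene_id)
  g <- sim$background$annotation$genes
  gb <- g[g$gene_id == background_gene_id, ]
  dg <- sim$donor$annotation$genes
  gd <- dg[dg$gene_id == row$donor_gene_id, ]
  seq_bg <- substr(sim$background$genome[[gb$chrom]], gb$start, gb$end)
  seq_dn <- substr(sim$donor$genome[[gd$chrom]], gd$start, gd$end)
  map <- sim$line$map
  ts <- map_position(map, gb$chrom, gb$start, source = "background")
  te <- map_position(map, gb$chrom, gb$end, source = "background")
  if (is.na(ts) || is.na(te)) {
    ts <- map_position(map, gd$chrom, gd$start, source = "donor")
    te <- map_position(map, gd$chrom, gd$end, source = "donor")
  }
  seq_line <- if (is.na(ts) || is.na(te) || (te - ts + 1L) < 1L) NULL else
    substr(sim$line$genome[[gb$chrom]], ts, te)
  list(background = seq_bg, donor = seq_dn, line = seq_line)
}

#' CAPS-genotype a set of simulated genes
#'
#' For each requested gene, designs an informative enzyme from the two
#' parental alleles ([design_caps()]) and genotypes the line's allele
#' ([caps_genotype()]) - the in-silico analogue of resolving unexpressed
#' genes with markers. Genes without an informative enzyme, or whose line
#' allele cannot be extracted intact, come back `uninformative`.
#'
#' @param sim an `intro_sim` with a planted line.
#' @param background_gene_ids shared gene ids to assay.
#' @param enzymes enzyme table (default [restriction_enzymes()]).
#' @return data.frame with `gene_id` and `call`, usable with
#'   [resolve_unknowns()].
#' @export
sim_marker_genotypes <- function(sim, background_gene_ids,
                                 enzymes = restriction_enzymes()) {
  calls <- vapply(background_gene_ids, function(gid) {
    seqs <- sim_gene_sequences(sim, gid)
    if (is.null(seqs$line)) return("uninformative")
    assays <- design_caps(seqs$background, seqs$donor, enzymes)
    if (!nrow(assays)) return("uninformative")
    caps_genotype(digest(seqs$line, assays$site[1], assays$cut_offset[1]),
                  digest(seqs$background, assays$site[1], assays$cut_offset[1]),
                  digest(seqs$donor, assays$site[1], assays$cut_offset[1]))
  }, "")
  data.frame(gene_id = background_gene_ids, call = unname(calls),
             stringsAsFactors = FALSE)
}

#' Three-way alignment of the chimeric gene
#'
#' Builds the exact multi-alignment of the chimeric border gene's line,
#' donor and background alleles from the generator's ledger (substitution
#' columns aligned one-to-one, insertions/deletions as gap columns), in
#' background coordinates over the gene span - the simulated analogue of
#' Sanger-sequencing the border gene and aligning it to both parents.
#'
#' @param sim an `intro_sim` with a planted chimeric gene.
#' @return list with `aln` (named character vector: `line`, `donor`,
#'   `background`), `anchor_pos` (background coordinate of the first
#'   column), and `gene_id` (background-side id).
#' @export
sim_chimeric_alignment <- function(sim) {
  if (is.na(sim$truth$chimeric_gene)) stop("no chimeric gene planted")
  bp <- sim$truth$breakpoints
  gid <- sim$truth$chimeric_gene_background
  g <- sim$background$annotation$genes
  gb <- g[g$gene_id == gid, ]
  led <- sim$ledger[[bp$chrom]]
  led <- led[led$pos >= gb$start & led$pos <= gb$end, , drop = FALSE]
  bg_row <- character(); dn_row <- character(); ln_row <- character()
  p <- gb$start
  bg_seq <- sim$background$genome[[bp$chrom]]
  emit_match <- function(from, to) {
    if (to < from) return()
    s <- strsplit(substr(bg_seq, from, to), "")[[1]]
    bg_row <<- c(bg_row, s); dn_row <<- c(dn_row, s); ln_row <<- c(ln_row, s)
  }
  for (k in seq_len(nrow(led))) {
    v <- led[k, ]
    emit_match(p, v$pos - 1L)
    line_is_donor <- v$pos <= bp$upper  # within the donor block
    if (v$class == "SNP") {
      bg_row <- c(bg_row, v$ref)
      dn_row <- c(dn_row, v$alt)
      ln_row <- c(ln_row, if (line_is_donor) v$alt else v$ref)
      p <- v$pos + 1L
    } else if (v$delta > 0L) {  # insertion in donor after anchor base
      ins <- strsplit(substr(v$alt, 2L, nchar(v$alt)), "")[[1]]
      anchor <- substr(bg_seq, v$pos, v$pos)
      line_has <- v$pos <= bp$upper - 1L
      bg_row <- c(bg_row, anchor, rep("-", length(ins)))
      dn_row <- c(dn_row, anchor, ins)
      ln_row <- c(ln_row, anchor, if (line_has) ins else rep("-", length(ins)))
      p <- v$pos + 1L
    } else {                    # deletion in donor of bases after the anchor
      delled <- strsplit(substr(v$ref, 2L, nchar(v$ref)), "")[[1]]
      anchor <- substr(bg_seq, v$pos, v$pos)
      line_lacks <- v$pos <= bp$upper - 1L
      bg_row <- c(bg_row, anchor, delled)
      dn_row <- c(dn_row, anchor, rep("-", length(delled)))
      ln_row <- c(ln_row, anchor, if (line_lacks) rep("-", length(delled)) else delled)
      p <- v$pos + nchar(v$ref)
    }
  }
  emit_match(p, gb$end)
  list(aln = c(line = paste(ln_row, collapse = ""),
               donor = paste(dn_row, collapse = ""),
               background = paste(bg_row, collapse = "")),
       anchor_pos = gb$start, gene_id = gid)
}

#' Write a simulation to disk as standard formats
#'
#' FASTA genomes, GFF3 annotations, gzipped VCFs against both references,
#' the ortholog pairing, DEG tables (if simulated) and the truth record as
#' JSON.
#'
#' @param sim an `intro_sim` with a planted line.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_sim_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome_background = file.path(dir, "background.fa"),
    genome_donor = file.path(dir, "donor.fa"),
    genome_line = file.path(dir, "line.fa"),
    genes_background = file.path(dir, "background.gff3"),
    genes_donor = file.path(dir, "donor.gff3"),
    vcf_background = file.path(dir, "line_vs_background.vcf.gz"),
    vcf_donor = file.path(dir, "line_vs_donor.vcf.gz"),
    gene_pairing = file.path(dir, "gene_pairing.tsv"),
    truth = file.path(dir, "truth.json"))
  write_genome(sim$background$genome, paths["genome_background"])
  write_genome(sim$donor$genome, paths["genome_donor"])
  write_genome(sim$line$genome, paths["genome_line"])
  write_annotation(sim$background$annotation, paths["genes_background"])
  write_annotation(sim$donor$annotation, paths["genes_donor"])
  write_variants(simulate_variant_calls(sim, "background"), paths["vcf_background"])
  write_variants(simulate_variant_calls(sim, "donor"), paths["vcf_donor"])
  utils::write.table(sim_gene_pairing(sim), paths["gene_pairing"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$genes <- as.list(truth$genes)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, null = "null",
                              digits = NA), paths["truth"])
  if (!is.null(sim$deg)) {
    paths["deg_br"] <- file.path(dir, "deg_br.tsv")
    paths["deg_mr"] <- file.path(dir, "deg_mr.tsv")
    write_deg_table(sim$deg$BR, paths["deg_br"])
    write_deg_table(sim$deg$MR, paths["deg_mr"])
  }
  invisible(paths)
}
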