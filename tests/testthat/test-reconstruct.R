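toy_calls <- function(calls) {
  n <- length(calls)
  data.frame(gene_id = paste0("g", seq_len(n)), chrom = "c",
             start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
             call = calls, stringsAsFactors = FALSE)
}

test_that("breakpoint intervals are bounded by flanking evidence on a toy case", {
  calls <- toy_calls(c("background", "background", "donor", "donor", "background"))
  # donor-diagnostic variants inside genes 3 and 4
  v <- variant_table(chrom = "c", pos = c(3100L, 3400L, 4200L), ref = "A", alt = "T")
  bp <- infer_breakpoints(calls, v)
  expect_identical(nrow(bp), 1L)
  expect_equal(bp$lower_last_background, 2500)   # end of gene 2
  expect_identical(bp$lower_first_donor, 3100L)  # first variant in gene 3
  expect_identical(bp$upper_last_donor, 4200L)
  expect_equal(bp$upper_first_background, 5000)  # start of gene 5
})

test_that("all-donor calls degenerate to chromosome edges", {
  calls <- toy_calls(c("donor", "donor", "donor"))
  v <- variant_table(chrom = "c", pos = c(1100L, 3200L), ref = "A", alt = "T")
  bp <- infer_breakpoints(calls, v)
  expect_identical(bp$lower_last_background, 0)
  expect_identical(bp$upper_first_background, Inf)
})

test_that("unknowns bridge a block but background calls and long gaps break it", {
  v <- variant_table(chrom = "c", pos = c(2100L, 4100L), ref = "A", alt = "T")
  bridged <- infer_breakpoints(
    toy_calls(c("background", "donor", "unknown", "donor", "background")), v)
  expect_identical(bridged$n_genes, 3L)
  expect_error(infer_breakpoints(
    toy_calls(c("donor", "background", "donor")), v), "multiple donor blocks")
  expect_error(infer_breakpoints(
    toy_calls(c("donor", "unknown", "donor")), v, max_bridge = 0),
    "multiple donor blocks")
  expect_error(infer_breakpoints(toy_calls(c("background", "unknown")), v),
               "no introgression")
  multi <- infer_breakpoints(toy_calls(c("donor", "background", "donor")), v,
                             strict = FALSE)
  expect_identical(nrow(multi), 2L)
})

test_that("reconstruction maps validate lengths, tiling and invert cleanly", {
  segs <- data.frame(source = c("background", "donor", "background"),
                     source_chrom = "c", source_start = c(1L, 501L, 2001L),
                     source_end = c(1000L, 1500L, 3000L),
                     target_chrom = "t", target_start = c(1L, 1001L, 2001L),
                     target_end = c(1000L, 2000L, 3000L))
  map <- reconstruction_map(segs)
  inv <- invert_map(map, "background")
  expect_identical(inv$target_start, c(1L, 2001L))
  bad <- segs; bad$target_end[1] <- 999L
  expect_error(reconstruction_map(bad), "lengths differ")
  bad2 <- segs; bad2$target_start[2] <- 1100L; bad2$target_end[2] <- 2099L
  expect_error(reconstruction_map(bad2), "contiguous")
})

test_that("merging genomes conserves length and respects cut placement", {
  set.seed(1)
  bg <- c(c1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = ""))
  dn <- c(c1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = ""))
  bp <- data.frame(chrom = "c1", first_gene = "g", last_gene = "g", n_genes = 1L,
                   lower_last_background = 1000, lower_first_donor = 1200,
                   upper_last_donor = 1900, upper_first_background = 2100)
  span <- list(chrom = "c1", start = 1150L, end = 1950L)
  rec <- merge_genomes(bg, dn, span, bp)
  low_cut <- floor((1000 + 1200) / 2)
  up_cut <- ceiling((1900 + 2100) / 2)
  expect_equal(nchar(rec$genome[["c1"]]),
               3000L - (up_cut - low_cut - 1L) + (1950L - 1150L + 1L))
  expect_identical(substr(rec$genome[["c1"]], 1, low_cut), substr(bg[[1]], 1, low_cut))
  expect_identical(substr(rec$genome[["c1"]], low_cut + 1, low_cut + 801),
                   substr(dn[[1]], 1150, 1950))
  expect_identical(nrow(rec$map), 3L)
  # identity reconstruction with no donor span
  rec0 <- merge_genomes(bg, dn, NULL, bp)
  expect_identical(rec0$genome[["c1"]], bg[["c1"]])
  expect_identical(nrow(rec0$map), 1L)
})

test_that("liftover shifts contained genes, flags junction and unmapped genes", {
  segs <- reconstruction_map(data.frame(
    source = c("background", "donor", "background"),
    source_chrom = "c", source_start = c(1L, 501L, 2001L),
    source_end = c(1000L, 1500L, 3000L),
    target_chrom = "t", target_start = c(1L, 1001L, 2001L),
    target_end = c(1000L, 2000L, 3000L)))
  ann <- annotation(data.frame(
    gene_id = c("inside", "junction", "outside"), chrom = "c",
    start = c(100L, 900L, 1200L), end = c(300L, 1100L, 1400L), strand = "+"))
  lifted <- liftover(segs, ann, "background")
  expect_identical(lifted$lifted$genes$gene_id, "inside")
  expect_identical(lifted$lifted$genes$start, 100L)
  expect_identical(lifted$chimeric_candidates$gene_id, "junction")
  expect_identical(lifted$unmapped$gene_id, "outside")
  # donor gene shifted by its segment offset
  dann <- annotation(data.frame(gene_id = "dg", chrom = "c",
                                start = 600L, end = 700L, strand = "+"))
  dl <- liftover(segs, dann, "donor")
  expect_identical(dl$lifted$genes$start, 1100L)
  # round trip through the inverted map restores source coordinates
  back <- liftover(invert_map(segs, "donor"), dl$lifted, "target")
  expect_identical(back$lifted$genes$start, 600L)
})

test_that("lift-over round-trips exactly on random maps", {
  set.seed(42)
  for (i in 1:1000) {
    n_seg <- sample(2:5, 1)
    src_start <- cumsum(c(1L, sample.int(500, n_seg - 1) + 50L))
    seg_len <- sample.int(400, n_seg) + 100L
    tgt_start <- cumsum(c(1L, head(seg_len, -1)))
    segs <- reconstruction_map(data.frame(
      source = "background", source_chrom = "c",
      source_start = src_start, source_end = src_start + seg_len - 1L,
      target_chrom = "t", target_start = tgt_start,
      target_end = tgt_start + seg_len - 1L))
    k <- sample.int(n_seg, 1)
    gs <- src_start[k] + sample.int(seg_len[k], 1) - 1L
    ge <- min(gs + sample.int(50, 1), src_start[k] + seg_len[k] - 1L)
    ann <- annotation(data.frame(gene_id = "g", chrom = "c", start = gs,
                                 end = ge, strand = "+"))
    fwd <- liftover(segs, ann, "background")
    back <- liftover(invert_map(segs, "background"), fwd$lifted, "target")
    expect_identical(back$lifted$genes$start, gs)
    expect_identical(back$lifted$genes$end, ge)
  }
})

test_that("the inferred interval contains the true breakpoint across seeds", {
  contained <- logical(0)
  for (s in 1:25) {
    sim <- plant_introgression(generate_parents(small_sim_config(
      seed = s, expression_dropout = 0, variant_error_rate = 0)))
    vb <- filter_variants(simulate_variant_calls(sim, "background"))
    vd <- filter_variants(simulate_variant_calls(sim, "donor"))
    cb <- count_variants_per_gene(vb, sim$background$annotation)
    cd <- count_variants_per_gene(vd, sim$donor$annotation)
    calls <- classify_ancestry(merge_gene_counts(cb, cd, sim_gene_pairing(sim)))
    g <- sim$background$annotation$genes
    calls <- cbind(calls, g[match(calls$gene_id, g$gene_id),
                            c("chrom", "start", "end")])
    bp <- infer_breakpoints(calls, vb)
    tb <- sim$truth$breakpoints
    contained <- c(contained,
                   bp$lower_last_background < tb$lower &
                     tb$lower < bp$lower_first_donor &
                     bp$upper_last_donor <= tb$upper &
                     tb$upper < bp$upper_first_background)
  }
  expect_identical(mean(contained), 1)
})

test_that("the collinear subset equals exhaustive search on small instances", {
  set.seed(8)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    x <- sample.int(n)
    expect_identical(length(introdissect:::lis_indices(x)), lis_oracle(x))
  }
  # reversed order keeps exactly one pair
  expect_identical(length(introdissect:::lis_indices(10:1)), 1L)
})

test_that("segment order check reports the embedded donor segment as one block", {
  tbl3 <- load_relationship_table()
  rel <- classify_relationships(implied_hits(tbl3),
                                fixture_gene_sets(tbl3, TRUE)$donor,
                                fixture_gene_sets(tbl3, TRUE)$background)
  d <- tbl3[!is.na(tbl3$donor_gene), c("donor_gene", "donor_start")]
  d <- d[!duplicated(d$donor_gene), ]
  b <- tbl3[!is.na(tbl3$background_gene), c("background_gene", "background_start")]
  b <- b[!duplicated(b$background_gene), ]
  soc <- segment_order_check(rel, d$donor_gene[order(d$donor_start)],
                             b$background_gene[order(b$background_start)])
  expect_identical(length(soc$translocated_blocks), 1L)
  # perfectly collinear input: no blocks
  rel2 <- data.frame(donor_gene_id = paste0("d", 1:5),
                     background_gene_id = paste0("b", 1:5), relation = "BBH")
  soc2 <- segment_order_check(rel2, paste0("d", 1:5), paste0("b", 1:5))
  expect_identical(length(soc2$translocated_blocks), 0L)
  # empty input: empty report
  expect_identical(nrow(segment_order_check(rel2[0, ], character(), character())$pairs), 0L)
})
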