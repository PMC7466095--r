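test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(snp_rate = 1.5), "snp_rate")
  expect_error(sim_config(expression_dropout = -0.1), "expression_dropout")
  expect_error(sim_config(introgression_gene_span = c(5, 50)), "span")
  expect_error(sim_config(chromosome_length = 5000), "chromosome_length")
})

test_that("zero divergence yields identical genomes and empty truth lists", {
  cfg <- sim_config(seed = 3, snp_rate = 0, indel_rate = 0,
                    n_species_specific_donor = 0,
                    n_species_specific_background = 0, n_duplicated = 0,
                    breakpoint_in_utr = FALSE)
  sim <- generate_parents(cfg)
  expect_identical(unname(sim$background$genome), unname(sim$donor$genome))
  expect_length(sim$truth$species_specific_donor, 0)
  expect_length(sim$truth$duplicated, 0)
  expect_identical(sum(vapply(sim$ledger, nrow, 0L)), 0L)
})

test_that("generation is deterministic given the seed", {
  s1 <- plant_introgression(generate_parents(sim_config(seed = 11)))
  s2 <- plant_introgression(generate_parents(sim_config(seed = 11)))
  expect_identical(s1$background$genome, s2$background$genome)
  expect_identical(s1$donor$genome, s2$donor$genome)
  expect_identical(s1$line$genome, s2$line$genome)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_variant_calls(s1, "background"),
                   simulate_variant_calls(s2, "background"))
  s1 <- simulate_deg_tables(s1); s2 <- simulate_deg_tables(s2)
  expect_identical(s1$deg, s2$deg)
})

test_that("inter-parent substitution count matches the configured rate", {
  cfg <- sim_config(seed = 5, indel_rate = 0, breakpoint_in_utr = FALSE,
                    n_species_specific_donor = 0,
                    n_species_specific_background = 0, n_duplicated = 0)
  sim <- generate_parents(cfg)
  # position-wise comparison (no indels, so coordinates agree)
  n_sub <- sum(vapply(names(sim$background$genome), function(ch) {
    a <- strsplit(sim$background$genome[[ch]], "")[[1]]
    b <- strsplit(sim$donor$genome[[ch]], "")[[1]]
    sum(a != b)
  }, 0L))
  L <- cfg$n_chromosomes * cfg$chromosome_length
  expected <- L * cfg$snp_rate
  sd3 <- 3 * sqrt(L * cfg$snp_rate * (1 - cfg$snp_rate))
  expect_gt(n_sub, expected - sd3)
  expect_lt(n_sub, expected + sd3)
})

test_that("a planted line equals background outside the block and donor inside", {
  sim <- plant_introgression(generate_parents(small_sim_config(seed = 9)))
  bp <- sim$truth$breakpoints
  ch <- bp$chrom
  line <- sim$line$genome[[ch]]
  bg <- sim$background$genome[[ch]]
  expect_identical(substr(line, 1, bp$lower - 1), substr(bg, 1, bp$lower - 1))
  expect_identical(substring(line, nchar(line) - (nchar(bg) - bp$upper) + 1),
                   substring(bg, bp$upper + 1))
  dl <- introdissect:::bg_to_donor_pos(sim$maps[[ch]], bp$lower)
  dr <- introdissect:::bg_to_donor_pos(sim$maps[[ch]], bp$upper)
  expect_identical(substr(line, bp$lower, bp$lower + (dr - dl)),
                   substr(sim$donor$genome[[ch]], dl, dr))
  # length conservation
  expect_identical(nchar(line), nchar(bg) - (bp$upper - bp$lower + 1L) + (dr - dl + 1L))
  # truth ancestry by construction
  tg <- sim$truth$genes
  span <- sim$config$introgression_gene_span
  in_block <- tg$chrom == ch & tg$index >= span[1] & tg$index <= span[2]
  expect_true(all(tg$ancestry[in_block] == "donor"))
  expect_true(all(tg$ancestry[!in_block] == "background"))
})

test_that("a zero-gene span leaves the line identical to the background", {
  cfg <- sim_config(seed = 2, introgression_gene_span = NULL)
  sim <- plant_introgression(generate_parents(cfg))
  expect_identical(sim$line$genome, sim$background$genome)
  expect_identical(nrow(simulate_variant_calls(sim, "background")[
    integer(0), , drop = FALSE]), 0L)
})

test_that("the chimeric gene matches donor over its head and background over its tail", {
  sim <- plant_introgression(generate_parents(small_sim_config(
    seed = 21, expression_dropout = 0, variant_error_rate = 0)))
  bp <- sim$truth$breakpoints
  expect_false(is.na(sim$truth$chimeric_gene))
  g <- sim$background$annotation$genes
  gb <- g[g$gene_id == sim$truth$chimeric_gene_background, ]
  # crossover strictly inside the 3'UTR
  utr3_start <- gb$end - sim$config$utr3_length + 1L
  expect_gt(bp$upper, utr3_start)
  expect_lt(bp$upper, gb$end)
  ch <- bp$chrom
  map <- sim$maps[[ch]]
  dstart <- introdissect:::bg_to_donor_pos(map, gb$start)
  dcut <- introdissect:::bg_to_donor_pos(map, bp$upper)
  line <- sim$line$genome[[ch]]
  lstart <- introdissect:::map_position(sim$line$map, ch, gb$start, source = "donor")
  # head (5'UTR + CDS + 3'UTR up to the crossover) is donor sequence
  lstart_d <- bp$lower + (dstart - introdissect:::bg_to_donor_pos(map, bp$lower))
  head_len <- dcut - dstart + 1L
  expect_identical(substr(line, lstart_d, lstart_d + head_len - 1L),
                   substr(sim$donor$genome[[ch]], dstart, dcut))
  # tail (rest of the 3'UTR) is background sequence
  expect_identical(substring(line, lstart_d + head_len,
                             lstart_d + head_len + (gb$end - bp$upper) - 1L),
                   substr(sim$background$genome[[ch]], bp$upper + 1L, gb$end))
})

test_that("unexpressed genes emit no variants against either reference", {
  sim <- plant_introgression(generate_parents(sim_config(
    seed = 13, expression_dropout = 0.5, variant_error_rate = 0)))
  vb <- simulate_variant_calls(sim, "background")
  vd <- simulate_variant_calls(sim, "donor")
  tg <- sim$truth$genes
  silent <- tg[!tg$expressed, ]
  anns <- list(background = sim$background$annotation$genes,
               donor = sim$donor$annotation$genes)
  for (i in seq_len(nrow(silent))) {
    for (side in c("background", "donor")) {
      gid <- silent[[paste0(side, "_gene_id")]][i]
      if (is.na(gid)) next
      g <- anns[[side]][anns[[side]]$gene_id == gid, ]
      v <- if (side == "background") vb else vd
      expect_identical(sum(v$chrom == g$chrom & v$pos >= g$start & v$pos <= g$end), 0L)
    }
  }
  # full dropout silences everything
  sim2 <- plant_introgression(generate_parents(sim_config(
    seed = 13, expression_dropout = 1, variant_error_rate = 0)))
  expect_identical(nrow(simulate_variant_calls(sim2, "background")), 0L)
  expect_identical(nrow(simulate_variant_calls(sim2, "donor")), 0L)
})

test_that("block variant count equals the planted divergence in expressed gene spans", {
  sim <- plant_introgression(generate_parents(small_sim_config(
    seed = 31, expression_dropout = 0, variant_error_rate = 0)))
  vb <- simulate_variant_calls(sim, "background")
  bp <- sim$truth$breakpoints
  led <- sim$ledger[[bp$chrom]]
  g <- sim$background$annotation$genes
  in_gene <- rep(FALSE, nrow(led))
  for (i in seq_len(nrow(g))) {
    in_gene <- in_gene | (led$pos >= g$start[i] & led$pos <= g$end[i])
  }
  expected <- sum(introdissect:::row_in_block(led, bp$lower, bp$upper) & in_gene)
  expect_identical(nrow(vb), expected)
})

test_that("SNP:INDEL mixture of emitted variants is near 80:20", {
  snp <- 0L; tot <- 0L
  for (s in 1:5) {
    sim <- plant_introgression(generate_parents(sim_config(
      seed = s, expression_dropout = 0, variant_error_rate = 0)))
    vb <- simulate_variant_calls(sim, "background")
    snp <- snp + sum(vb$var_class == "SNP")
    tot <- tot + nrow(vb)
  }
  expect_gt(snp / tot, 0.72)
  expect_lt(snp / tot, 0.88)
})

test_that("simulated DEG tables encode the planted truth sets", {
  sim <- plant_introgression(generate_parents(sim_config(seed = 17)))
  sim <- simulate_deg_tables(sim)
  for (stage in c("BR", "MR")) {
    tab <- sim$deg[[stage]]
    sig <- significant(tab)
    key <- tolower(stage)
    expect_setequal(sig$gene_id[sig$direction == "up"],
                    sim$truth$deg[[paste0(key, "_up")]])
    expect_setequal(sig$gene_id[sig$direction == "down"],
                    sim$truth$deg[[paste0(key, "_down")]])
  }
  # empty truth sets produce no significant rows
  sim0 <- simulate_deg_tables(sim, n_common_up = 0, n_common_down = 0,
                              n_in_region = 0,
                              n_stage_only = list(br_up = 0, br_down = 0,
                                                  mr_up = 0, mr_down = 0))
  expect_identical(nrow(significant(sim0$deg$BR)), 0L)
})

test_that("written simulation files parse back through the readers", {
  sim <- plant_introgression(generate_parents(small_sim_config(seed = 41)))
  d <- withr::local_tempdir()
  paths <- write_sim_files(sim, d)
  expect_identical(read_genome(paths[["genome_line"]]), sim$line$genome)
  ann <- read_annotation(paths[["genes_background"]])
  expect_identical(nrow(ann$genes), nrow(sim$background$annotation$genes))
  v <- read_variants(paths[["vcf_background"]])
  expect_identical(nrow(v), nrow(simulate_variant_calls(sim, "background")))
  truth <- jsonlite::fromJSON(paths[["truth"]])
  expect_identical(truth$breakpoints$lower, sim$truth$breakpoints$lower)
})
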