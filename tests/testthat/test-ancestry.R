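test_that("the depth filter is inclusive at the threshold and drops heterozygotes", {
  v <- variant_table(chrom = "c", pos = 1:4, ref = "A", alt = "T",
                     genotype_class = c("homozygous", "homozygous",
                                        "heterozygous", "homozygous"),
                     mean_depth = c(4, 5, 100, 50))
  f <- filter_variants(v)
  expect_identical(f$pos, c(2L, 4L))           # depth 4 dropped, 5 kept, het dropped
  f2 <- filter_variants(v, require_homozygous = FALSE)
  expect_identical(f2$pos, c(2L, 3L, 4L))
  expect_error(filter_variants(v, min_mean_depth = -1), "non-negative")
})

test_that("a hand-enumerated mixed set filters to the expected survivors", {
  v <- variant_table(chrom = "c", pos = 1:10, ref = "A", alt = "T",
                     genotype_class = "homozygous",
                     mean_depth = c(3, 8, 12, 4, 9, 22, 2, 7, 31, 6))
  expect_identical(nrow(filter_variants(v)), 7L)
})

test_that("variant-to-gene assignment matches a brute-force membership test", {
  set.seed(99)
  for (rep in 1:5) {
    genes <- data.frame(gene_id = paste0("g", 1:6), chrom = sample(c("c1", "c2"), 6, TRUE),
                        start = sample.int(900, 6), strand = "+")
    genes$end <- genes$start + sample.int(80, 6)
    ann <- annotation(genes)
    v <- variant_table(chrom = sample(c("c1", "c2"), 60, TRUE),
                       pos = sample.int(1000, 60), ref = "A", alt = "T")
    counts <- suppressWarnings(count_variants_per_gene(v, ann))
    for (i in seq_len(nrow(genes))) {
      brute <- sum(vapply(seq_len(nrow(v)), function(k) {
        v$chrom[k] == genes$chrom[i] && v$pos[k] >= genes$start[i] &&
          v$pos[k] <= genes$end[i]
      }, logical(1)))
      expect_identical(counts$n_variants[i], brute)
    }
  }
})

test_that("empty input yields zero counts and unexpressed flags", {
  ann <- annotation(data.frame(gene_id = "g", chrom = "c", start = 1L,
                               end = 10L, strand = "+"))
  counts <- count_variants_per_gene(variant_table(), ann)
  expect_identical(counts$n_variants, 0L)
  expect_false(counts$expressed)
})

test_that("ancestry classification follows the dual-reference count rule", {
  counts <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                       donor_gene_id = NA,
                       n_vs_background = c(17L, 0L, 3L, 1L, 1L),
                       n_vs_donor = c(0L, 0L, 3L, 9L, 0L),
                       expressed = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  calls <- classify_ancestry(counts)
  expect_identical(calls$call,
                   c("donor",      # 17 vs 0: the wild-gene regime
                     "unknown",    # unexpressed
                     "unknown",    # tie
                     "background", # 1 vs 9
                     "unknown"))   # winner below min_informative
  # a single stray variant cannot flip a call
  calls2 <- classify_ancestry(data.frame(gene_id = "x", donor_gene_id = NA,
                                         n_vs_background = 1L, n_vs_donor = 0L,
                                         expressed = TRUE))
  expect_identical(calls2$call, "unknown")
})

test_that("swapping the references flips donor and background, unknown invariant", {
  set.seed(7)
  counts <- data.frame(gene_id = paste0("g", 1:50), donor_gene_id = NA,
                       n_vs_background = rpois(50, 5), n_vs_donor = rpois(50, 5),
                       expressed = TRUE)
  fwd <- classify_ancestry(counts)
  swapped <- counts
  swapped$n_vs_background <- counts$n_vs_donor
  swapped$n_vs_donor <- counts$n_vs_background
  rev <- classify_ancestry(swapped)
  expect_identical(rev$call[fwd$call == "donor"],
                   rep("background", sum(fwd$call == "donor")))
  expect_identical(rev$call[fwd$call == "background"],
                   rep("donor", sum(fwd$call == "background")))
  expect_identical(rev$call[fwd$call == "unknown"],
                   rep("unknown", sum(fwd$call == "unknown")))
})

test_that("ancestry recovery is exact on error-free simulated data", {
  sim <- plant_introgression(generate_parents(sim_config(
    seed = 19, expression_dropout = 0, variant_error_rate = 0)))
  vb <- filter_variants(simulate_variant_calls(sim, "background"))
  vd <- filter_variants(simulate_variant_calls(sim, "donor"))
  cb <- count_variants_per_gene(vb, sim$background$annotation)
  cd <- count_variants_per_gene(vd, sim$donor$annotation)
  calls <- classify_ancestry(merge_gene_counts(cb, cd, sim_gene_pairing(sim)))
  tg <- sim$truth$genes[sim$truth$genes$class == "shared", ]
  truth <- tg$ancestry[match(calls$gene_id, tg$background_gene_id)]
  expect_identical(calls$call, truth)
})

test_that("the purity scan reproduces the published accounting regime", {
  # 458 variants, 452 inside the target region (365 SNPs / 87 INDELs),
  # 6 outside on other chromosomes
  region <- list(chrom = "chr7", start = 59085047, end = 59488648)
  inside_pos <- seq(region$start + 100, by = 800, length.out = 452)
  v <- variant_table(
    chrom = c(rep("chr7", 452), "chr1", "chr4", "chr5", "chr5", "chr12", "chr12"),
    pos = c(inside_pos, 1e6, 2e6, 3e6, 4e6, 5e6, 6e6),
    ref = c(rep("A", 365), rep("AT", 87), rep("A", 6)),
    alt = c(rep("G", 365), rep("A", 87), rep("G", 6)))
  rep <- purity_scan(v, region)
  expect_identical(rep$n_total, 458L)
  expect_identical(rep$n_inside, 452L)
  expect_identical(rep$n_outside, 6L)
  expect_identical(rep$n_snp, 365L)
  expect_identical(rep$n_indel, 87L)
  pct <- purity_percentages(rep)
  expect_identical(unname(pct["outside_pct"]), 1.3)
  expect_identical(unname(pct["snp_pct"]), 80.8)
  expect_identical(unname(pct["indel_pct"]), 19.2)
  # conservation
  expect_identical(rep$n_inside + rep$n_outside, rep$n_total)
  expect_identical(nrow(rep$outside_positions), 6L)
})

test_that("an empty variant set gives an all-zero purity report", {
  rep <- purity_scan(variant_table(), "c:1-100")
  expect_identical(rep$n_total, 0L)
  expect_identical(rep$outside_fraction, 0)
  expect_identical(rep$snp_fraction, 0)
})

test_that("purity counts are conserved on random inputs", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample.int(100, 1)
    v <- variant_table(chrom = sample(c("c1", "c2"), n, TRUE),
                       pos = sample.int(1e4, n, TRUE), ref = "A", alt = "T")
    rep <- purity_scan(v, list(chrom = "c1", start = 2000, end = 7000))
    expect_identical(rep$n_inside + rep$n_outside, n)
  }
})
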