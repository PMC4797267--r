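test_that("positions annotate strand-aware into the seven categories", {
  g <- fixture_genome(); genes <- fixture_genes(); sch <- category_scheme()
  at <- function(pos) annotate_position(genes, sch, "chrT", pos, g)
  # + strand gene: tx 2000-5000, exons (2000,2500) (4000,5000), CDS 2200-4500
  expect_equal(at(1500), "promoter")   # inside [1000, 2000)
  expect_equal(at(5010), "TTS")        # 10 bases past txEnd
  expect_equal(at(2100), "utr5")       # exonic, 5' of CDS
  expect_equal(at(4800), "utr3")       # exonic, 3' of CDS
  expect_equal(at(2300), "exon")       # CDS-overlapping exonic
  expect_equal(at(3000), "intron")
  expect_equal(at(9000), "intergenic")
  # - strand gene: tx 12000-15000, promoter downstream of txEnd in genome order
  expect_equal(at(15500), "promoter")
  expect_equal(at(11500), "TTS")
  expect_equal(at(14800), "utr5")      # genome-right exonic is 5' on - strand
  expect_equal(at(12200), "utr3")
  expect_equal(at(13500), "intron")
})

test_that("a chromosome without genes is entirely intergenic", {
  g <- genome_model(tibble::tibble(chrom = c("chrT", "chrEmpty"),
                                   length = c(20000, 5000)))
  expect_equal(annotate_position(fixture_genes(), category_scheme(),
                                 "chrEmpty", 10, g), "intergenic")
  bg <- genomic_background_fractions(empty <- fixture_genes()[0, ],
                                     genome_model(tibble::tibble(chrom = "c", length = 1e5)))
  expect_equal(bg$fraction[bg$category == "intergenic"], 1)
})

test_that("base-wise category fractions partition the genome exactly", {
  # fixed fixture
  bg <- genomic_background_fractions(fixture_genes(), fixture_genome())
  expect_equal(sum(bg$fraction), 1)
  expect_equal(sum(bg$bases), 20000)
  # simulated gene sets
  for (seed in 1:3) {
    gg <- simulate_genome(fast_config(seed = seed))
    bg <- genomic_background_fractions(gg$genes, gg$genome)
    expect_equal(sum(bg$fraction), 1)
    expect_equal(sum(bg$bases), sum(gg$genome$length))
  }
})

test_that("a single gene contributes exactly its kilobase of promoter", {
  G <- 1e5
  genome <- genome_model(tibble::tibble(chrom = "c", length = G))
  gene <- tibble::tibble(gene = "g", chrom = "c", strand = "+",
                         tx_start = 50000, tx_end = 55000,
                         cds_start = 50500, cds_end = 54500,
                         exon_starts = list(50000), exon_ends = list(55000))
  bg <- genomic_background_fractions(gene, genome)
  expect_equal(bg$fraction[bg$category == "promoter"], 1000 / G)
  expect_equal(bg$fraction[bg$category == "TTS"], 1000 / G)
})

test_that("annotation is a pure function of the gene set, not its order", {
  gg <- simulate_genome(fast_config(seed = 5))
  sites <- tibble::tibble(chrom = gg$genome$chrom[1],
                          center = seq(500, gg$genome$length[1] - 500,
                                       length.out = 300))
  a1 <- annotate_sites(sites, gg$genes, gg$genome)
  withr::with_seed(1, perm <- sample(nrow(gg$genes)))
  a2 <- annotate_sites(sites, gg$genes[perm, ], gg$genome)
  expect_identical(a1$category, a2$category)
})

test_that("category profiles normalize within each class label", {
  sim <- simulate_chip_experiment(fast_config(seed = 9))
  sites <- dplyr::mutate(sim$truth, label = true_class)
  prof <- category_profile(sites, sim$genes, sim$genome)
  sums <- tapply(prof$fraction, prof$label, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  counts <- tapply(prof$n, prof$label, sum)
  expect_equal(unname(counts["all"]), nrow(sites))
  # degenerate input: all sites at one position gives an indicator profile
  one <- category_profile(tibble::tibble(chrom = "chrT", center = rep(1500, 5)),
                          fixture_genes(), fixture_genome())
  expect_equal(sort(one$fraction, decreasing = TRUE)[1], 1)
  expect_error(category_profile(sites[0, ], sim$genes, sim$genome), "empty")
})

test_that("log-space enrichment matches closed forms and a log-sum oracle", {
  expect_equal(enrichment_test(10, 10, 0.5), 10 * log10(0.5))
  expect_equal(enrichment_test(0, 10, 0.5), 0)
  expect_error(enrichment_test(5, 10, 1.5), "p0")
  expect_error(enrichment_test(11, 10, 0.5), "k <= n")

  logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  brute <- function(k, n, p0) {
    logsumexp(dbinom(k:n, n, p0, log = TRUE)) / log(10)
  }
  grid <- expand.grid(n = c(10, 100, 500), p0 = c(0.01, 0.05, 0.5, 0.9))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; p0 <- grid$p0[i]
    for (k in unique(c(1, round(n * p0), round(n * 0.5), n))) {
      k <- max(1, min(n, k))
      expect_equal(enrichment_test(k, n, p0), brute(k, n, p0),
                   tolerance = 1e-10)
    }
  }
})

test_that("enrichment is monotone non-increasing in k and exact far below underflow", {
  lp <- enrichment_test(0:200, 200, 0.07)
  expect_true(all(diff(lp) <= 1e-12))
  # a tail far below the smallest positive double is returned exactly
  deep <- enrichment_test(5000, 10000, 0.01)
  expect_true(is.finite(deep) && deep < -3000)
})

test_that("fold over background reproduces the printed ratios", {
  expect_equal(fold_over_background(0.083, 0.01), 8.3)
  expect_equal(fold_over_background(0.18, 0.01), 18)
  expect_equal(fold_over_background(0.3, 0.3), 1)
  expect_error(fold_over_background(0.1, 0), "> 0")
})

test_that("the combined enrichment table carries k, n, p0, log10 p and fold", {
  sim <- simulate_chip_experiment(fast_config(seed = 13))
  d <- compare_conditions(sim$peaks_a, sim$peaks_b, sim$reads_a, sim$reads_b)
  enr <- category_enrichment(d, sim$genes, sim$genome)
  expect_true(all(c("label", "category", "k", "n", "p0", "log10_p", "fold")
                  %in% names(enr)))
  prom <- enr[enr$label == "induced" & enr$category == "promoter", ]
  expect_equal(prom$fold, (prom$k / prom$n) / prom$p0)
  expect_equal(prom$log10_p, enrichment_test(prom$k, prom$n, prom$p0))
})
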