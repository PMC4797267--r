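test_that("the simulator is byte-deterministic given a config", {
  a <- simulate_chip_experiment(fast_config(seed = 17))
  b <- simulate_chip_experiment(fast_config(seed = 17))
  expect_identical(a, b)
  c <- simulate_chip_experiment(fast_config(seed = 18))
  expect_false(identical(a$reads_a, c$reads_a))
  # the standalone genome generator reproduces the experiment's gene layout
  g <- simulate_genome(fast_config(seed = 17))
  expect_identical(g$genes, a$genes)
  expect_identical(g$genome$length, a$genome$length)
})

test_that("emitted reads conserve the configured depth exactly", {
  cfg <- fast_config(seed = 4)
  sim <- simulate_chip_experiment(cfg)
  expect_equal(nrow(sim$reads_a), cfg$depth_a)
  expect_equal(nrow(sim$reads_b), cfg$depth_b)
  expect_equal(read_depth(sim$reads_a), nrow(sim$reads_a))
  # every read lies within chromosome bounds
  L <- sim$genome$length[match(sim$reads_a$chrom, sim$genome$chrom)]
  expect_true(all(sim$reads_a$start >= 0 & sim$reads_a$end <= L))
})

test_that("truth table encodes the configured class structure", {
  cfg <- fast_config(seed = 7)
  sim <- simulate_chip_experiment(cfg)
  tt <- sim$truth
  expect_equal(sum(tt$true_class == "induced"), cfg$n_induced)
  expect_equal(sum(tt$true_class == "repressed"), cfg$n_repressed)
  ind <- tt[tt$true_class == "induced", ]
  expect_true(all(ind$enrichment_b / ind$enrichment_a >= cfg$effect_fold))
  rep_ <- tt[tt$true_class == "repressed", ]
  expect_true(all(rep_$enrichment_a / rep_$enrichment_b >= cfg$effect_fold))
  com <- tt[tt$true_class == "common", ]
  ratio <- com$enrichment_b / com$enrichment_a
  expect_true(all(ratio >= 0.5 & ratio <= 2))
  # promoter placement honors the configured fractions
  expect_equal(sum(ind$category_intent == "promoter"),
               round(cfg$promoter_fraction[["induced"]] * cfg$n_induced))
})

test_that("capacity and degenerate configurations behave as specified", {
  expect_error(simulate_genome(sim_config(genome_length = 1e4, n_genes = 500)),
               "do not fit")
  # zero genes: a valid genome where everything annotates intergenic
  cfg <- fast_config(seed = 2, n_genes = 0,
                     promoter_fraction = c(induced = 0, repressed = 0, common = 0))
  sim <- simulate_chip_experiment(cfg)
  expect_equal(nrow(sim$genes), 0)
  ann <- annotate_sites(sim$truth, sim$genes, sim$genome)
  expect_true(all(ann$category == "intergenic"))
})

test_that("a null experiment yields no induced or repressed calls", {
  # all sites common (equal enrichment in both conditions): at the 4-fold
  # cut the classifier finds nothing differential, across seeds
  for (seed in 1:5) {
    cfg <- fast_config(seed = seed, n_induced = 0, n_repressed = 0,
                       n_common = 40)
    sim <- simulate_chip_experiment(cfg)
    d <- compare_conditions(sim$peaks_a, sim$peaks_b, sim$reads_a, sim$reads_b)
    expect_equal(sum(d$label != "common"), 0)
  }
})

test_that("common sites have the same count distribution in both conditions", {
  # depth-normalized window counts at common sites, pooled over seeds,
  # pass a two-sample rank test comfortably above alpha = 0.01
  na <- nb <- c()
  for (seed in 1:3) {
    sim <- simulate_chip_experiment(fast_config(seed = seed))
    com <- sim$truth[sim$truth$true_class == "common", ]
    ca <- vapply(seq_len(nrow(com)), function(i)
      window_count(sim$reads_a, com$chrom[i], com$center[i], 200), numeric(1))
    cb <- vapply(seq_len(nrow(com)), function(i)
      window_count(sim$reads_b, com$chrom[i], com$center[i], 200), numeric(1))
    na <- c(na, ca * 1e7 / read_depth(sim$reads_a))
    nb <- c(nb, cb * 1e7 / read_depth(sim$reads_b))
  }
  p <- stats::wilcox.test(na, nb, exact = FALSE)$p.value
  expect_gt(p, 0.01)
})

test_that("planting the motif in every induced site makes them all motif-positive", {
  cfg <- fast_config(seed = 12,
                     motif_fraction = c(induced = 1, repressed = 0, common = 0))
  sim <- simulate_chip_experiment(cfg)
  ind <- sim$truth[sim$truth$true_class == "induced", ]
  hits <- vapply(seq_len(nrow(ind)), function(i)
    site_has_motif(cfg$motif, sim$genome, ind$chrom[i], ind$center[i]),
    logical(1))
  expect_true(all(hits))
  expect_true(all(ind$has_motif))
})

test_that("truth tables round-trip through TSV", {
  sim <- simulate_chip_experiment(fast_config(seed = 3))
  path <- tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(sim$truth))
  expect_equal(back$center, sim$truth$center)
  expect_equal(back$true_class, sim$truth$true_class)
})
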