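test_that("window counting uses midpoint containment in a half-open window", {
  reads <- tibble::tibble(chrom = "chrT", start = c(100, 149, 150),
                          end = c(200, 249, 250))  # midpoints 150, 199, 200
  expect_equal(window_count(reads, "chrT", 100, 200), 2)  # [0, 200)
  expect_equal(window_count(tibble::tibble(chrom = character(),
                                           start = double(), end = double()),
                            "chrT", 100, 200), 0L)
  expect_error(window_count(reads, "chrT", 100, 3), "even")
  expect_error(window_count(reads, "chrX", 100, 200, genome = fixture_genome()),
               "unknown chromosome")
})

test_that("exact p-value matches hand-derived values and brute-force oracles", {
  expect_equal(differential_pvalue(5, 5, 1e6, 1e6), 1)
  expect_equal(differential_pvalue(0, 10, 1e6, 1e6), 2 * 0.5^10)
  expect_equal(differential_pvalue(0, 0, 1e6, 1e6), 1)

  # independent oracle 1: stats::binom.test on the same conditional model
  withr::with_seed(11, {
    ca <- sample(0:60, 40, replace = TRUE)
    cb <- sample(0:60, 40, replace = TRUE)
    da <- sample(c(1e5, 3e5, 1e6), 40, replace = TRUE)
    db <- sample(c(1e5, 5e5, 2e6), 40, replace = TRUE)
  })
  got <- differential_pvalue(ca, cb, da, db)
  want <- vapply(seq_along(ca), function(i) {
    n <- ca[i] + cb[i]
    if (n == 0) return(1)
    stats::binom.test(cb[i], n, db[i] / (da[i] + db[i]))$p.value
  }, double(1))
  expect_equal(got, want, tolerance = 1e-12)

  # independent oracle 2: direct summation of binomial terms
  brute <- function(ca, cb, da, db) {
    n <- ca + cb
    p <- db / (da + db)
    d <- vapply(0:n, function(i) exp(lchoose(n, i) + i * log(p) +
                                       (n - i) * log1p(-p)), double(1))
    min(1, sum(d[d <= d[cb + 1] * (1 + 1e-7)]))
  }
  for (pair in list(c(0, 10), c(3, 17), c(40, 160), c(100, 100))) {
    expect_equal(differential_pvalue(pair[1], pair[2], 2e5, 4e5),
                 brute(pair[1], pair[2], 2e5, 4e5), tolerance = 1e-10)
  }
})

test_that("p-value is exactly symmetric under condition swap", {
  withr::with_seed(3, {
    ca <- sample(0:200, 60, replace = TRUE)
    cb <- sample(0:200, 60, replace = TRUE)
    da <- sample(1e5:1e6, 60)
    db <- sample(1e5:1e6, 60)
  })
  expect_identical(differential_pvalue(ca, cb, da, db),
                   differential_pvalue(cb, ca, db, da))
})

test_that("fold change follows the reads-per-ten-million pseudocount formula", {
  expect_equal(fold_change(7, 7, 1e6, 1e6), 1)
  expect_equal(fold_change(0, 0, 1e6, 1e6), 1)
  expect_equal(fold_change(10, 40, 1e7, 1e7, pseudocount = 1), 41 / 11)
  # depth invariance: scaling counts and depths together changes nothing
  expect_equal(fold_change(30, 120, 1e5, 1e5), fold_change(300, 1200, 1e6, 1e6))
})

test_that("classification thresholds are inclusive as published", {
  p <- diff_params()
  expect_equal(classify_site(4.0, 1e-4, p), "induced")
  expect_equal(classify_site(0.25, 1e-4, p), "repressed")
  expect_equal(classify_site(3.9, 1e-10, p), "common")
  expect_equal(classify_site(4.1, 1.1e-4, p), "common")
  expect_equal(classify_site(0.25, 1e-6, p), "repressed")
})

test_that("comparison labels every site, is condition-swap symmetric, and works from one-sided peaks", {
  sim <- simulate_chip_experiment(fast_config(seed = 21))
  d <- compare_conditions(sim$peaks_a, sim$peaks_b, sim$reads_a, sim$reads_b)

  # partition: every evaluation site gets exactly one of the three labels
  expect_true(all(d$label %in% c("induced", "repressed", "common")))
  s <- glance(d)
  expect_equal(s$n_induced + s$n_repressed + s$n_common, s$n_sites)

  # swapping conditions swaps induced <-> repressed and inverts the fold
  dsw <- compare_conditions(sim$peaks_b, sim$peaks_a, sim$reads_b, sim$reads_a)
  expect_equal(dsw$center, d$center)
  expect_equal(dsw$fold_change, 1 / d$fold_change, tolerance = 1e-12)
  expect_identical(dsw$p_value, d$p_value)
  map <- c(induced = "repressed", repressed = "induced", common = "common")
  expect_identical(unname(map[d$label]), dsw$label)

  # with peaks from one condition only, sites are still evaluated and labeled
  d1 <- compare_conditions(sim$peaks_a, sim$peaks_a[0, ], sim$reads_a,
                           sim$reads_b)
  expect_equal(nrow(d1), nrow(sim$peaks_a))
  expect_true(all(d1$label %in% c("induced", "repressed", "common")))

  expect_error(compare_conditions(sim$peaks_a[0, ], sim$peaks_b[0, ],
                                  sim$reads_a, sim$reads_b), "no peaks")
})

test_that("evaluation centers are deduplicated and at least window/2 apart", {
  sim <- simulate_chip_experiment(fast_config(seed = 22))
  d <- compare_conditions(sim$peaks_a, sim$peaks_b, sim$reads_a, sim$reads_b)
  gaps <- unlist(tapply(d$center, d$chrom, function(x) diff(sort(x))))
  expect_true(all(gaps >= 100))
  # truth sites appear once each even when called as peaks in both conditions
  expect_lte(nrow(d), nrow(sim$truth))
})

test_that("classification is stable when both depths and counts scale together", {
  counts <- expand.grid(ca = c(0, 5, 20, 80), cb = c(0, 5, 20, 80))
  for (k in c(10, 100)) {
    f1 <- fold_change(counts$ca, counts$cb, 1e5, 1e5)
    f2 <- fold_change(counts$ca * k, counts$cb * k, 1e5 * k, 1e5 * k)
    expect_equal(f1, f2, tolerance = 1e-12)
    # significance only sharpens with scale: labels at the published cut can
    # only move from common toward induced/repressed, never reverse
    p1 <- differential_pvalue(counts$ca, counts$cb, 1e5, 1e5)
    p2 <- differential_pvalue(counts$ca * k, counts$cb * k, 1e5 * k, 1e5 * k)
    was_sig <- p1 <= 1e-4
    expect_true(all(p2[was_sig] <= 1e-4))
  }
})
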