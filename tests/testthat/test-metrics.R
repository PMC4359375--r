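test_that("rpkm follows the density formula and its scaling laws", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(59, 500, 5e6), 23.6)
  expect_error(rpkm(1, 0, 1e6), "feature_length")
  expect_error(rpkm(1, 100, 0), "total_mapped")

  set.seed(14)
  for (i in 1:50) {
    c0 <- sample(1:1000, 1); l0 <- sample(50:5000, 1); t0 <- sample(1e5:1e7, 1)
    expect_equal(rpkm(2 * c0, l0, t0), 2 * rpkm(c0, l0, t0))
    expect_equal(rpkm(c0, 2 * l0, t0), rpkm(c0, l0, t0) / 2)
    expect_equal(rpkm(c0, l0, 2 * t0), rpkm(c0, l0, t0) / 2)
  }
})

test_that("expression significance has the right extremes and symmetric null", {
  txome <- make_test_txome()
  feat <- feature_row("tx2", 0, 120)

  # no mRNA reads anywhere on the feature, reads elsewhere: p = 1
  off_feat <- alignments("tx1", start = rep(0L, 20), length = 60L)
  p <- expression_significance(feat, off_feat, txome, n_samples = 200, seed = 1)
  expect_equal(p, 1)

  # feature holds every read, anchors spread to its edges: near-minimal p
  # (a null window ties only when it lands exactly on the feature)
  all_on <- alignments("tx2", start = c(rep(0L, 25), rep(119L, 25)), length = 1L)
  p_min <- expression_significance(feat, all_on, txome, n_samples = 1000, seed = 2)
  expect_lt(p_min, 0.02)
  expect_gte(p_min, 1 / 1001)

  expect_error(expression_significance(feat, all_on, txome, n_samples = 10),
               "n_samples")

  # uniform single-base anchors everywhere: mean p near 0.5 across seeds
  set.seed(15)
  ps <- vapply(1:20, function(s) {
    tx <- sample(txome$info$transcript_id, 300, replace = TRUE,
                 prob = txome$info$length)
    lim <- txome$info$length[match(tx, txome$info$transcript_id)]
    reads <- alignments(tx, start = vapply(lim, function(m)
      sample.int(m, 1L) - 1L, integer(1)), length = 1L)
    expression_significance(feature_row("tx1", 20, 80), reads, txome,
                            n_samples = 1000, seed = s)
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("TE is gated on expression significance", {
  expect_equal(translational_efficiency(10, 5, 0.001), 2)
  expect_true(is.na(translational_efficiency(10, 5, 0.05)))
  expect_equal(translational_efficiency(0, 5, 0.001), 0)
  expect_true(is.na(translational_efficiency(10, 0, 0.001)))
  expect_error(translational_efficiency(-1, 5, 0.5), "must be >= 0")
})

test_that("thresholds take background percentiles with the 0.57 coverage floor", {
  bg <- data.frame(fp_rpkm = 1:10, coverage = seq(0.02, 0.38, length.out = 10))
  th <- derive_thresholds(bg)
  expect_equal(th$rpkm_cutoff, unname(stats::quantile(1:10, 0.9, type = 7))) # 9.1
  expect_equal(th$rpkm_cutoff, 9.1)
  expect_equal(th$coverage_cutoff, 0.57) # raised from a low percentile
  expect_lt(th$coverage_percentile_raw, 0.40)

  high <- data.frame(fp_rpkm = 1:10, coverage = seq(0.1, 1, 0.1))
  th2 <- derive_thresholds(high)
  expect_equal(th2$coverage_cutoff, 0.91) # above the floor: percentile wins

  expect_error(derive_thresholds(high[0, ]), "default_thresholds")
  d <- default_thresholds()
  expect_equal(c(d$rpkm_cutoff, d$coverage_cutoff, d$min_reads), c(11.8, 0.57, 5))

  # order invariance and monotonicity in the percentile
  set.seed(16)
  for (i in 1:25) {
    x <- data.frame(fp_rpkm = stats::runif(30, 0, 50),
                    coverage = stats::runif(30))
    shuffled <- x[sample(nrow(x)), ]
    expect_equal(derive_thresholds(shuffled)$rpkm_cutoff,
                 derive_thresholds(x)$rpkm_cutoff)
    expect_equal(derive_thresholds(x, percentile = 90)$rpkm_cutoff,
                 unname(stats::quantile(x$fp_rpkm, 0.9, type = 7)))
    expect_lte(derive_thresholds(x, percentile = 50)$rpkm_cutoff,
               derive_thresholds(x, percentile = 90)$rpkm_cutoff)
  }
})

test_that("quantile_linear matches the stats::quantile type-7 oracle", {
  expect_equal(quantile_linear(1:10, 0.9), 9.1)
  set.seed(17)
  for (i in 1:100) {
    x <- stats::rnorm(sample(2:60, 1))
    p <- stats::runif(1)
    expect_equal(quantile_linear(x, p), unname(stats::quantile(x, p, type = 7)))
  }
})

test_that("translation calls apply inclusive filters and are monotone", {
  th <- default_thresholds()
  m <- data.frame(feature_id = c("a", "b", "c"),
                  fp_rpkm = c(12, 500, 11.8),
                  coverage = c(0.60, 1.00, 0.57),
                  fp_count = c(6L, 4L, 5L))
  calls <- call_translation(m, th)
  expect_equal(calls$translated, c(TRUE, FALSE, TRUE))
  expect_false(calls$pass_min_reads[2]) # the anti-inflation rule

  # monotone: raising any metric never flips translated -> untranslated
  set.seed(18)
  for (i in 1:50) {
    base <- data.frame(feature_id = "x", fp_rpkm = stats::runif(1, 0, 30),
                       coverage = stats::runif(1), fp_count = sample(0:10, 1))
    before <- call_translation(base, th)$translated
    bumped <- base
    j <- sample(2:4, 1)
    bumped[[j]] <- bumped[[j]] + sample(1:5, 1)
    after <- call_translation(bumped, th)$translated
    expect_true(!before || after)
  }
})

test_that("call combination is a union with provenance", {
  got <- combine_calls(list(exp1 = c("a", "b"), exp2 = c("b", "c")))
  expect_equal(got$feature_id, c("a", "b", "c"))
  expect_equal(got$experiments[got$feature_id == "b"], "exp1,exp2")
  expect_equal(got$n_experiments, c(1L, 2L, 1L))

  single <- combine_calls(list(only = c("x", "y")))
  expect_equal(single$feature_id, c("x", "y"))

  # inclusion-exclusion on random sets
  set.seed(19)
  for (i in 1:20) {
    sets <- lapply(1:3, function(k) sample(letters, sample(3:12, 1)))
    names(sets) <- paste0("e", 1:3)
    got <- combine_calls(sets)
    expect_equal(nrow(got), length(unique(unlist(sets))))
    expect_equal(sum(got$n_experiments), sum(lengths(lapply(sets, unique))))
  }
})

test_that("replicate correlation is squared Pearson over shared features", {
  a <- data.frame(feature_id = letters[1:5], fp_rpkm = c(1, 2, 3, 4, 5))
  expect_equal(replicate_correlation(a, a), 1)
  flat <- transform(a, fp_rpkm = 2)
  expect_error(replicate_correlation(a, flat), "zero variance")
  expect_error(replicate_correlation(a[1:2, ], a[1:2, ]), "fewer than 3")

  set.seed(20)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- stats::rnorm(n); y <- 0.6 * x + stats::rnorm(n)
    ma <- data.frame(feature_id = as.character(1:n), fp_rpkm = x)
    mb <- data.frame(feature_id = as.character(1:n), fp_rpkm = y)
    # closed form from sums
    sx <- sum(x); sy <- sum(y); sxy <- sum(x * y)
    sxx <- sum(x^2); syy <- sum(y^2)
    r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
    expect_equal(replicate_correlation(ma, mb), r^2)
  }
})

test_that("vectorized metrics agree with the per-feature reference operations", {
  cfg <- tiny_config(seed = 77)
  ex <- simulate_experiment(cfg)
  txome <- ex$sim$txome
  features <- discover_features(txome)
  m <- compute_feature_metrics(features, ex$fp$small_polysome, ex$mrna, txome,
                               n_samples = 200, seed = 3)
  fp <- filter_by_length(ex$fp$small_polysome)
  idx <- sample(seq_len(nrow(features)), 40)
  for (i in idx) {
    f <- features[i, ]
    expect_equal(m$fp_count[i], feature_read_count(f, fp))
    expect_equal(m$coverage[i], coverage_fraction(f, fp))
    expect_equal(m$mrna_count[i], feature_read_count(f, ex$mrna, "midpoint"))
  }
  expect_equal(m$fp_rpkm,
               rpkm(m$fp_count, features$end - features$start,
                    sum(fp$multiplicity)))
})
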