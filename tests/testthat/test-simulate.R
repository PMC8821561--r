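test_that("truth simulation is deterministic, non-overlapping, and size-faithful", {
  cfg <- simulation_config(contigs = c("1" = 1.5e9, "2" = 1.5e9),
                           n_truth = 1000, size_range = c(50, 5e6))
  t1 <- simulate_truth(cfg, seed = 13)
  t2 <- simulate_truth(cfg, seed = 13)
  expect_identical(as.data.frame(t1)[1:5], as.data.frame(t2)[1:5])
  expect_false(identical(t1$start, simulate_truth(cfg, seed = 14)$start))

  # non-overlap within each contig
  df <- as.data.frame(t1)
  by_ch <- split(df, df$chrom)
  for (d in by_ch) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }

  # log-uniform sizes: goodness of fit on the log scale
  len <- df$end - df$start
  ks <- suppressWarnings(
    stats::ks.test(log(len), "punif", log(50), log(5e6)))
  expect_gt(ks$p.value, 0.01)

  cfg0 <- simulation_config(contigs = c("1" = 5e7), n_truth = 0)
  expect_equal(nrow(simulate_truth(cfg0, 1)), 0)

  tiny <- simulation_config(contigs = c("1" = 2e5), n_truth = 50,
                            size_range = c(5e4, 1e5))
  expect_error(simulate_truth(tiny, 1), "non-overlapping")
})

test_that("degenerate error models reproduce or ignore the truth exactly", {
  cfg <- small_sim_config(
    n_truth = 60,
    callers = list(perfect = caller_error_model(1, fpr_per_mb = 0),
                   blind = caller_error_model(0, fpr_per_mb = 2)),
    profiles = list(perfect = caller_profile("perfect", "paired_end"),
                    blind = caller_profile("blind", "coverage",
                                           merge_priority = 2L)))
  truth <- simulate_truth(cfg, seed = 2)
  perfect <- simulate_caller(truth, cfg, "perfect", seed = 3)
  expect_equal(perfect$calls$start, truth$start)
  expect_equal(perfect$calls$end, truth$end)
  expect_equal(perfect$calls$svtype, truth$svtype)
  expect_true(all(perfect$labels$label == "TRUE_POSITIVE"))

  blind <- simulate_caller(truth, cfg, "blind", seed = 3)
  expect_true(all(blind$labels$label == "FALSE_POSITIVE"))
})

test_that("labels partition every simulated call exactly once", {
  cfg <- small_sim_config(n_truth = 80, shared_rate_per_mb = 0.5)
  co <- simulate_cohort(cfg, seed = 17)
  for (nm in names(co$callsets)) {
    expect_identical(sort(co$labels[[nm]]$id), sort(co$callsets[[nm]]$id))
    expect_false(anyDuplicated(co$labels[[nm]]$id) > 0)
    expect_true(all(co$labels[[nm]]$label %in%
                      c("TRUE_POSITIVE", "FALSE_POSITIVE", "SHARED")))
  }
  # shared artifacts appear in every caller
  expect_true(all(vapply(co$labels, function(l)
    sum(l$label == "SHARED") > 0, logical(1))))
})

test_that("emitted true-positive fraction converges to the configured sensitivity", {
  cfg <- simulation_config(n_truth = 2000,
                           callers = list(c1 = caller_error_model(0.9,
                                                                  fpr_per_mb = 0)),
                           profiles = list(c1 = caller_profile("c1",
                                                               "paired_end")))
  truth <- simulate_truth(cfg, seed = 23)
  res <- simulate_caller(truth, cfg, "c1", seed = 24)
  frac <- nrow(res$calls) / nrow(truth)
  se <- sqrt(0.9 * 0.1 / 2000)
  expect_lt(abs(frac - 0.9), 3 * se)
})

test_that("mislabel probability flips types only for paired-end callers", {
  cfg <- small_sim_config(
    n_truth = 400,
    callers = list(pe = caller_error_model(1, fpr_per_mb = 0,
                                           mislabel_prob = 0.2),
                   cov = caller_error_model(1, fpr_per_mb = 0,
                                            mislabel_prob = 0.2)),
    profiles = list(pe = caller_profile("pe", "paired_end"),
                    cov = caller_profile("cov", "coverage",
                                         merge_priority = 2L)))
  truth <- simulate_truth(cfg, seed = 5)
  pe <- simulate_caller(truth, cfg, "pe", seed = 6)
  cov <- simulate_caller(truth, cfg, "cov", seed = 6)
  flips_pe <- mean(pe$calls$svtype != truth$svtype)
  expect_gt(flips_pe, 0.1); expect_lt(flips_pe, 0.3)
  expect_equal(cov$calls$svtype, truth$svtype)
})

test_that("analytic strategy expectations hit the closed forms", {
  mk_cfg <- function(s) simulation_config(
    callers = default_error_models(sensitivity = s))
  expect_equal(expected_strategy_stats(mk_cfg(1))$sensitivity, 1.0)
  expect_equal(expected_strategy_stats(mk_cfg(1), "union")$sensitivity, 1.0)
  est <- expected_strategy_stats(mk_cfg(0.9))
  expect_equal(est$sensitivity, 1 - (1 - 0.81)^2)
  expect_equal(expected_strategy_stats(mk_cfg(0.9), "union")$sensitivity,
               1 - 0.1^4)
  expect_true(est$assumes_independence)
  # pair intersection lets through far fewer false positives than a union
  expect_lt(est$expected_fp,
            0.05 * expected_strategy_stats(mk_cfg(0.9), "union")$expected_fp)
})

test_that("Monte-Carlo intersection-union sensitivity agrees with the analytic oracle", {
  cfg <- small_sim_config(n_truth = 500)
  est <- expected_strategy_stats(cfg)$sensitivity
  hits <- 0; total <- 0
  for (seed in 1:4) {
    co <- simulate_cohort(cfg, seed = seed)
    iu <- run_strategy("intersection_union", co$callsets)$calls
    dr <- suppressWarnings(detection_rate(co$truth, list(iu = iu), 0.5))
    hits <- hits + sum(dr$per_truth$any); total <- total + nrow(co$truth)
  }
  se <- sqrt(est * (1 - est) / total)
  expect_lt(abs(hits / total - est), 4 * se + 0.01)  # small jitter bias allowed
})
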