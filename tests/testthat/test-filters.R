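mk <- function(df, sample = "s1", origin = "delly")
  cnv_callset(df, sample = sample, origin = origin)

test_that("delamp removes both members of an opposite-type overlap", {
  cs <- mk(data.frame(chrom = "1", start = c(1000, 1050),
                      end = c(2000, 2050), svtype = c("DEL", "DUP")))
  res <- filter_delamp(cs, ro_min = 0.75)
  expect_equal(nrow(res$calls), 0)
  expect_equal(res$report$n_removed, 2)

  far <- mk(data.frame(chrom = "1", start = c(1000, 1700),
                       end = c(2000, 2700), svtype = c("DEL", "DUP")))
  expect_equal(nrow(filter_delamp(far, 0.75)$calls), 2)

  dels <- mk(data.frame(chrom = "1", start = c(0, 5000),
                        end = c(1000, 6000), svtype = "DEL"))
  expect_equal(nrow(filter_delamp(dels)$calls), 2)

  cov_prof <- caller_profile("cnvnator", "coverage")
  expect_warning(filter_delamp(cs, profile = cov_prof), "paired-end")
})

test_that("delamp output never contains a cross-type pair at the threshold (exhaustive scan)", {
  for (seed in 1:6) {
    cs <- random_callset(120, seed, origin = "delly")
    out <- filter_delamp(cs, ro_min = 0.75)$calls
    df <- as.data.frame(out)
    dels <- df[df$svtype == "DEL", ]; dups <- df[df$svtype == "DUP", ]
    if (nrow(dels) && nrow(dups)) {
      worst <- 0
      for (i in seq_len(nrow(dels))) for (j in seq_len(nrow(dups)))
        worst <- max(worst, ro_scalar(dels[i, ], dups[j, ]))
      expect_lt(worst, 0.75)
    }
  }
})

test_that("support-fraction filter keeps calls with either fraction above threshold", {
  cs <- mk(data.frame(chrom = "1", start = c(0, 5000, 10000),
                      end = c(1000, 6000, 11000), svtype = "DEL",
                      pe_frac = c(0.4, 0.2, NA),
                      sr_frac = c(0.1, 0.25, NA)))
  res <- filter_support_fraction(cs, min_frac = 0.3)
  kept <- res$calls
  expect_equal(nrow(kept), 2)
  expect_true(all(c(0, 10000) %in% kept$start))  # 0.4 passes; NA retained
  expect_equal(length(res$report$not_applicable), 1)
  # strictly greater than: exactly 0.3 fails
  cs2 <- mk(data.frame(chrom = "1", start = 0, end = 1000, svtype = "DEL",
                       pe_frac = 0.3, sr_frac = 0.3))
  expect_equal(nrow(filter_support_fraction(cs2, 0.3)$calls), 0)
})

test_that("adjusted-p filter keeps p below threshold and flags absent values", {
  cs <- mk(data.frame(chrom = "1", start = c(0, 5000, 10000),
                      end = c(1000, 6000, 11000), svtype = "DUP",
                      adjusted_p = c(0.01, 0.7, NA)), origin = "cnvnator")
  res <- filter_adjusted_p(cs, max_p = 0.5)
  expect_equal(nrow(res$calls), 2)
  expect_equal(res$report$removed$reason, "adjusted_p_high")
  expect_equal(length(res$report$not_applicable), 1)
})

test_that("same-signal confirmation keeps partner-matched calls and is threshold-monotone", {
  delly <- mk(data.frame(chrom = "1", start = c(0, 50000),
                         end = c(1000, 51000), svtype = "DEL"))
  manta <- mk(data.frame(chrom = "1", start = 100, end = 1100,
                         svtype = "DEL"), origin = "manta")
  res <- filter_same_signal_confirmation(delly, manta, ro_min = 0.75)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$start, 0)

  for (seed in 7:10) {
    a <- random_callset(100, seed, origin = "delly")
    b <- random_callset(100, seed + 50, origin = "manta")
    k50 <- filter_same_signal_confirmation(a, b, 0.5)$calls$id
    k75 <- filter_same_signal_confirmation(a, b, 0.75)$calls$id
    expect_true(all(k75 %in% k50))
  }
})

test_that("non-reference genotype filter keeps het/hom-alt and drops missing conservatively", {
  cs <- mk(data.frame(chrom = "1", start = c(0, 5000, 10000, 15000),
                      end = c(1000, 6000, 11000, 16000), svtype = "DEL",
                      genotype = c("HET", "HOM_REF", "MISSING", "HOM_ALT")))
  res <- filter_genotype_nonref(cs)
  expect_equal(sort(res$calls$genotype), c("HET", "HOM_ALT"))
  expect_equal(res$report$n_missing, 1)
  expect_setequal(res$report$removed$reason, c("hom_ref", "genotype_missing"))
})

test_that("frequency filter removes calls with common same-type population overlap", {
  cs <- mk(data.frame(chrom = "1", start = c(0, 50000, 100000),
                      end = c(10000, 60000, 110000), svtype = "DEL"))
  pop <- structure(data.frame(chrom = "1",
                              start = c(1000, 52000), end = c(9800, 62000),
                              svtype = c("DEL", "DEL"),
                              af = c(0.06, 0.01)),
                   class = c("sv_track", "data.frame"))
  res <- filter_frequency(cs, pop, af_max = 0.05, ro_min = 0.5)
  expect_equal(nrow(res$calls), 2)           # AF 0.06 removed
  expect_equal(res$report$removed$reason, "population_af_high")
  # type-mismatched overlap ignored under same_type
  pop$svtype <- c("DUP", "DEL")
  expect_equal(nrow(filter_frequency(cs, pop, 0.05)$calls), 3)
  # stricter af_max never retains more
  pop$svtype <- c("DEL", "DEL")
  n_loose <- nrow(filter_frequency(cs, pop, af_max = 0.1)$calls)
  n_tight <- nrow(filter_frequency(cs, pop, af_max = 0.005)$calls)
  expect_lte(n_tight, n_loose)
})

test_that("size/type rules apply in order with first match deciding", {
  cs <- mk(data.frame(chrom = "1", start = c(0, 1e5), end = c(6e4, 1.1e5),
                      svtype = "DUP"))
  drop_big <- list(size_rule("DUP", 5e4, Inf, "drop"))
  res <- filter_size_and_type(cs, drop_big)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$end - res$calls$start, 1e4)
  expect_equal(nrow(filter_size_and_type(cs, list())$calls), 2)
  expect_error(size_rule("DUP", 100, 50), "min_size")
})

test_that("region filter uses shared-bp semantics in both modes", {
  cs <- mk(data.frame(chrom = "1", start = c(1000, 50000),
                      end = c(2000, 51000), svtype = "DEL"))
  track <- structure(data.frame(chrom = "1", start = 900, end = 2100),
                     class = c("interval_track", "data.frame"))
  expect_equal(nrow(filter_region(cs, track, "exclude_overlapping")$calls), 1)
  expect_equal(nrow(filter_region(cs, track, "require_overlapping")$calls), 1)
  empty <- track[0, ]
  expect_equal(nrow(filter_region(cs, empty, "exclude_overlapping")$calls), 2)
})

test_that("every filter is contractive, idempotent and count-conserving", {
  cfg <- small_sim_config(n_truth = 80)
  co <- simulate_cohort(cfg, seed = 21)
  pop <- structure(cbind(as.data.frame(co$truth)[
    c("chrom", "start", "end", "svtype")],
    af = rep(c(0.001, 0.2), length.out = nrow(co$truth))),
    class = c("sv_track", "data.frame"))
  gt <- simulate_regenotyper(co$callsets$delly, co$truth, seed = 3)
  filters <- list(
    function(x) filter_delamp(x),
    function(x) filter_support_fraction(x),
    function(x) filter_adjusted_p(x),
    function(x) filter_same_signal_confirmation(x, co$callsets$manta, 0.5),
    function(x) filter_frequency(x, pop),
    function(x) filter_size_and_type(x, list(size_rule("DUP", 5e4, Inf,
                                                       "drop"))),
    function(x) filter_region(x, pop[1:20, c("chrom", "start", "end")],
                              "exclude_overlapping")
  )
  for (f in filters) {
    res <- f(co$callsets$delly)
    expect_true(all(res$calls$id %in% co$callsets$delly$id))
    expect_equal(res$report$n_retained + res$report$n_removed,
                 res$report$n_input)
    twice <- f(res$calls)
    expect_identical(twice$calls$id, res$calls$id)
  }
  resg <- filter_genotype_nonref(gt)
  expect_true(all(resg$calls$id %in% gt$id))
  expect_identical(filter_genotype_nonref(resg$calls)$calls$id,
                   resg$calls$id)
})
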