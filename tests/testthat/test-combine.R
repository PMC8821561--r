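pair_sets <- function(a_df, b_df, a = "delly", b = "manta") {
  list(cnv_callset(a_df, "s1", a), cnv_callset(b_df, "s1", b))
}

test_that("pair intersection takes priority coordinates and merges provenance", {
  s <- pair_sets(data.frame(chrom = "1", start = 0, end = 1000, svtype = "DEL"),
                 data.frame(chrom = "1", start = 100, end = 1100, svtype = "DEL"))
  out <- intersect_pair(s[[1]], s[[2]], ro_min = 0.75)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 100)          # manta outranks delly
  expect_equal(out$caller, "manta")
  expect_setequal(out$sources[[1]]$caller, c("delly", "manta"))

  # type mismatch and low overlap give empty results
  s2 <- pair_sets(data.frame(chrom = "1", start = 0, end = 1000, svtype = "DEL"),
                  data.frame(chrom = "1", start = 0, end = 1000, svtype = "DUP"))
  expect_equal(nrow(intersect_pair(s2[[1]], s2[[2]], 0.75)), 0)
  s3 <- pair_sets(data.frame(chrom = "1", start = 0, end = 1000, svtype = "DEL"),
                  data.frame(chrom = "1", start = 700, end = 1700, svtype = "DEL"))
  expect_equal(nrow(intersect_pair(s3[[1]], s3[[2]], 0.75)), 0)

  other <- cnv_callset(data.frame(chrom = "1", start = 0, end = 1000,
                                  svtype = "DEL"), "s2", "manta")
  expect_error(intersect_pair(s[[1]], other, 0.75), "different samples")
})

test_that("pair intersection selects the same match pairs in either order", {
  a <- random_callset(80, 101, origin = "delly")
  b <- random_callset(80, 102, origin = "manta")
  ab <- intersect_pair(a, b, 0.75)
  ba <- intersect_pair(b, a, 0.75)
  key <- function(cs) sort(vapply(cs$sources, function(s)
    paste(sort(sprintf("%s:%g-%g", s$caller, s$start, s$end)),
          collapse = ";"), character(1)))
  expect_identical(key(ab), key(ba))
  expect_identical(ab$start, ba$start)  # representative rule, not argument order
})

test_that("union collapses same-type matches into one record with full provenance", {
  one <- cnv_callset(data.frame(chrom = "1", start = 0, end = 1000,
                                svtype = "DEL"), "s1", "delly")
  expect_equal(nrow(combine_union(list(one))), 1)
  expect_identical(combine_union(list(one))$sources[[1]]$caller, "delly")

  sets <- lapply(c("manta", "delly", "erds", "cnvnator"), function(cl)
    cnv_callset(data.frame(chrom = "1", start = 0, end = 1000,
                           svtype = "DEL"), "s1", cl))
  u <- combine_union(sets, dedup_ro = 0.5)
  expect_equal(nrow(u), 1)
  expect_setequal(u$sources[[1]]$caller,
                  c("manta", "delly", "erds", "cnvnator"))
  expect_equal(u$caller, "manta")
  expect_equal(nrow(combine_union(list())), 0)
})

test_that("every union output call is connected to its representative at the dedup threshold", {
  cfg <- small_sim_config(n_truth = 100)
  for (seed in 1:4) {
    co <- simulate_cohort(cfg, seed = seed)
    u <- combine_union(co$callsets, dedup_ro = 0.5)
    # each provenance entry must overlap the representative interval at >= 0.5
    ok <- vapply(seq_len(nrow(u)), function(k) {
      rep_iv <- u[k, ]
      src <- u$sources[[k]]
      all(vapply(seq_len(nrow(src)), function(j)
        ro_scalar(list(chrom = rep_iv$chrom, start = rep_iv$start,
                       end = rep_iv$end),
                  list(chrom = src$chrom[j], start = src$start[j],
                       end = src$end[j])) >= 0.5, logical(1)))
    }, logical(1))
    expect_true(all(ok))
    # conservation: every input call appears in exactly one provenance group
    n_src <- sum(vapply(u$sources, nrow, integer(1)))
    expect_equal(n_src, sum(vapply(co$callsets, nrow, integer(1))))
  }
})

test_that("intersection-union keeps pair-supported calls and only those", {
  # DEL seen by both PE callers, absent from coverage callers
  mkset <- function(origin, df) cnv_callset(df, "s1", origin)
  delly <- mkset("delly", data.frame(chrom = "1", start = 0, end = 1000,
                                     svtype = "DEL"))
  manta <- mkset("manta", data.frame(chrom = "1", start = 50, end = 1050,
                                     svtype = "DEL"))
  erds <- empty_callset("s1", "erds")
  cnvn <- empty_callset("s1", "cnvnator")
  res <- combine_intersection_union(list(delly = delly, manta = manta,
                                         erds = erds, cnvnator = cnvn))
  expect_equal(nrow(res$calls), 1)
  expect_setequal(res$calls$sources[[1]]$caller, c("delly", "manta"))

  # present only in delly: fails both intersections
  res2 <- combine_intersection_union(list(delly = delly,
                                          manta = empty_callset("s1", "manta"),
                                          erds = erds, cnvnator = cnvn))
  expect_equal(nrow(res2$calls), 0)

  # present in all four at high mutual RO: exactly one record, both pools
  sets <- lapply(c("delly", "manta", "erds", "cnvnator"), function(cl)
    cnv_callset(data.frame(chrom = "1", start = 0, end = 1000,
                           svtype = "DEL"), "s1", cl))
  names(sets) <- c("delly", "manta", "erds", "cnvnator")
  res3 <- combine_intersection_union(sets)
  expect_equal(nrow(res3$calls), 1)
  expect_setequal(res3$calls$sources[[1]]$caller,
                  c("delly", "manta", "erds", "cnvnator"))
})

test_that("intersection-union output is contained in the union and pair-supported", {
  cfg <- small_sim_config(n_truth = 100)
  pairs <- list(pe = c("delly", "manta"), cov = c("erds", "cnvnator"))
  for (seed in 11:15) {
    co <- simulate_cohort(cfg, seed = seed)
    iu <- combine_intersection_union(co$callsets)$calls
    un <- combine_union(co$callsets, dedup_ro = 0.5)
    m <- match_sets(iu, un, ro_min = 0.5)
    expect_equal(nrow(m$pairs), nrow(iu))  # containment under the same dedup
    pair_ok <- vapply(iu$sources, function(s)
      all(pairs$pe %in% s$caller) || all(pairs$cov %in% s$caller),
      logical(1))
    expect_true(all(pair_ok))
  }
})

test_that("run_strategy composes stages and enforces the regenotyped input", {
  cfg <- small_sim_config(n_truth = 80)
  co <- simulate_cohort(cfg, seed = 33)
  un <- run_strategy("union", co$callsets)
  expect_identical(un$calls$id, combine_union(co$callsets, 0.5)$id)

  expect_error(run_strategy("union_sv2", co$callsets), "regenotyped")

  # all-hom-ref regenotyping empties the output
  rg <- un$calls
  df <- as.data.frame(rg); df$genotype <- "HOM_REF"
  rg_homref <- cnv_callset(df, "sim", "regenotyped")
  res <- run_strategy("union_sv2", co$callsets, genotyped = rg_homref)
  expect_equal(nrow(res$calls), 0)

  # sv2 variant is contractive relative to its base strategy
  rg2 <- simulate_regenotyper(combine_intersection_union(co$callsets)$calls,
                              co$truth, seed = 4)
  iu2 <- run_strategy("intersection_union_sv2", co$callsets, genotyped = rg2)
  iu <- run_strategy("intersection_union", co$callsets)
  expect_true(all(iu2$calls$id %in% iu$calls$id))
})
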