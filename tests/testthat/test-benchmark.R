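test_that("contingency statistics reproduce hand-computed values on the 20-call pool", {
  pool <- worked_example_pool()
  # remove 2 TP (c1, c2) and 8 FP (c11..c18)
  transform <- function(x)
    x[x$id %in% c(sprintf("c%d", 3:10), sprintf("c%d", 19:20)), ]
  r <- evaluate_filter(pool$calls, pool$labels, transform)
  expect_equal(unname(r$counts),
               c(8, 2, 2, 8))
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$specificity, 0.8)
  expect_equal(r$ppv, 0.8)
  expect_equal(r$accuracy, 0.8)
  expect_equal(r$baseline_ppv, 0.5)
  expect_equal(r$ppv_ratio, 1.6)
})

test_that("identity and annihilator transforms hit the degenerate statistics", {
  pool <- worked_example_pool()
  rid <- evaluate_filter(pool$calls, pool$labels, identity)
  expect_equal(rid$sensitivity, 1.0)
  expect_equal(rid$specificity, 0.0)
  expect_equal(rid$ppv_ratio, 1.0)
  rkill <- evaluate_filter(pool$calls, pool$labels,
                           function(x) x[integer(0), ])
  expect_equal(rkill$sensitivity, 0.0)
  expect_equal(rkill$specificity, 1.0)
  expect_true(is.na(rkill$ppv))
})

test_that("unlabeled calls abort and SHARED/DOUBTFUL stay out of the 2x2 table", {
  pool <- worked_example_pool()
  expect_error(evaluate_filter(pool$calls, pool$labels[-1, ], identity),
               "c1")
  lab <- pool$labels
  lab$label[c(1, 11)] <- c("SHARED", "DOUBTFUL")
  r <- evaluate_filter(pool$calls, lab, identity)
  expect_equal(sum(r$counts), 18)
  expect_equal(as.integer(r$excluded[c("SHARED", "DOUBTFUL")]), c(1L, 1L))
})

test_that("benchmark identities hold on every simulated report (independent recount)", {
  cfg <- small_sim_config(n_truth = 100)
  co <- simulate_cohort(cfg, seed = 8)
  for (cl in names(co$callsets)) {
    r <- evaluate_filter(co$callsets[[cl]], co$labels[[cl]],
                         function(x) filter_support_fraction(x)$calls)
    k <- r$counts
    expect_equal(r$sensitivity, unname(k["tp_kept"] /
                                         (k["tp_kept"] + k["tp_removed"])))
    expect_equal(r$specificity, unname(k["fp_removed"] /
                                         (k["fp_kept"] + k["fp_removed"])))
    if (!is.na(r$ppv))
      expect_equal(r$ppv, unname(k["tp_kept"] / (k["tp_kept"] + k["fp_kept"])))
    expect_equal(r$accuracy, unname((k["tp_kept"] + k["fp_removed"]) / sum(k)))
    expect_equal(sum(k), nrow(co$callsets[[cl]]))
  }
})

test_that("detection flags match the brute-force matcher and report best near-miss RO", {
  truth <- cnv_callset(data.frame(chrom = "1", start = 0, end = 1000,
                                  svtype = "DEL", id = "t1"), "s1", "truth")
  hit <- cnv_callset(data.frame(chrom = "1", start = 0, end = 1500,
                                svtype = "DEL"), "s1", "c1")  # ro 0.667
  res <- detection_rate(truth, list(c1 = hit), ro_min = 0.5)
  expect_true(res$per_truth$any[1])
  expect_equal(res$any_fraction, 1.0)

  miss <- cnv_callset(data.frame(chrom = "1", start = 0, end = 2500,
                                 svtype = "DEL"), "s1", "c1")  # ro 0.4
  res2 <- detection_rate(truth, list(c1 = miss), ro_min = 0.5)
  expect_false(res2$per_truth$any[1])
  expect_equal(res2$per_truth$best_ro[1], 0.4)

  for (seed in 41:44) {
    tr <- random_callset(60, seed, origin = "truth", disjoint = TRUE)
    cands <- list(a = random_callset(80, seed + 10, origin = "a"),
                  b = random_callset(80, seed + 20, origin = "b"))
    got <- suppressWarnings(detection_rate(tr, cands, ro_min = 0.5))
    for (nm in names(cands)) {
      want <- rep(FALSE, nrow(tr))
      want[oracle_match(tr, cands[[nm]], 0.5)$left] <- TRUE
      expect_identical(unname(got$per_truth[[nm]]), want)
    }
  }
})

test_that("detection is monotone non-increasing in the overlap threshold", {
  tr <- random_callset(80, 71, origin = "truth", disjoint = TRUE)
  cand <- random_callset(120, 72, origin = "a")
  fr <- vapply(c(0.3, 0.5, 0.7, 0.9), function(ro)
    suppressWarnings(detection_rate(tr, list(a = cand), ro))$any_fraction,
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("size bins are left-closed with the conventional boundaries", {
  cs <- cnv_callset(data.frame(
    chrom = "1", start = c(0, 1e5, 2e5, 3e5),
    end = c(3000, 1e5 + 5e4, 2e5 + 60, 3e5 + 2.5e5),
    svtype = c("DEL", "DUP", "DEL", "DEL")), "s1", "x")
  m <- size_bin_summary(cs)
  expect_equal(sum(m), 4)
  expect_equal(m["DEL", "[1000,5000)"], 3000 %/% 3000)   # 3 kb deletion
  expect_equal(m["DUP", "[50000,200000)"], 1)            # exactly 50 kb
  expect_equal(m["DEL", "[50,1000)"], 1)                 # 60 bp
  expect_equal(m["DEL", "[200000,Inf)"], 1)
  expect_equal(sum(size_bin_summary(empty_callset("s", "x"))), 0)
  expect_error(size_bin_summary(cs, bins = c(100, 50)), "increasing")
})

test_that("caller agreement counts equal all-pairs brute force", {
  sets <- lapply(1:3, function(k)
    random_callset(50, 300 + k, origin = paste0("c", k)))
  names(sets) <- paste0("c", 1:3)
  prof <- caller_overlap_profile(sets, ro_min = 0.5)
  for (a in 1:3) {
    want <- integer(nrow(sets[[a]]))
    for (b in setdiff(1:3, a)) {
      m <- oracle_match(sets[[a]], sets[[b]], 0.5)
      want[m$left] <- want[m$left] + 1L
    }
    got <- prof$per_call$agree_n[prof$per_call$set == paste0("c", a)]
    expect_identical(as.integer(got), want)
  }
  # unique call has agreement 0; identical call across sets scores n-1
  uniq <- cnv_callset(data.frame(chrom = "1", start = 0, end = 1000,
                                 svtype = "DEL"), "s1", "u")
  same <- lapply(1:3, function(k)
    cnv_callset(data.frame(chrom = "2", start = 5000, end = 9000,
                           svtype = "DUP"), "s1", paste0("s", k)))
  prof2 <- caller_overlap_profile(c(list(u = uniq), same))
  expect_equal(prof2$per_call$agree_n[prof2$per_call$set == "u"], 0)
  expect_equal(prof2$per_call$agree_n[prof2$per_call$set == "s1"], 2)
})
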