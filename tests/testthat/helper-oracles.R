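# Brute-force oracles and random fixture generators shared by the suite.
# The oracles deliberately avoid the package's interval index: plain O(n^2)
# scans over every pair, so they check the fast paths independently.

# random call rows on a small genome; overlaps allowed unless disjoint = TRUE
random_calls <- function(n, seed, chroms = c("1", "2"), max_pos = 1e6,
                         min_len = 100, max_len = 2e4, disjoint = FALSE) {
  set.seed(seed)
  if (disjoint) {
    # spaced placement guarantees non-overlap
    per <- ceiling(n / length(chroms))
    slots <- (max_len + 1000)
    df <- do.call(rbind, lapply(chroms, function(ch) {
      k <- min(per, n)
      start <- (seq_len(k) - 1) * slots + sample.int(500, k, replace = TRUE)
      len <- sample(min_len:max_len, k, replace = TRUE)
      data.frame(chrom = ch, start = start, end = start + len)
    }))[seq_len(n), ]
  } else {
    start <- sample.int(max_pos, n, replace = TRUE)
    len <- sample(min_len:max_len, n, replace = TRUE)
    df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                     start = start, end = start + len)
  }
  df$svtype <- sample(c("DEL", "DUP"), n, replace = TRUE)
  df
}

random_callset <- function(n, seed, sample = "s1", origin = "sim", ...) {
  cnv_callset(random_calls(n, seed, ...), sample = sample, origin = origin)
}

ro_scalar <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  o <- min(a$end, b$end) - max(a$start, b$start)
  max(0, o) / max(a$end - a$start, b$end - b$start)
}

# exhaustive greedy one-to-one matching over all pairs
oracle_match <- function(A, B, ro_min, same_type = TRUE) {
  A <- as.data.frame(A); B <- as.data.frame(B)
  cand <- NULL
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (same_type && A$svtype[i] != B$svtype[j]) next
    r <- ro_scalar(A[i, ], B[j, ])
    if (r >= ro_min)
      cand <- rbind(cand, data.frame(left = i, right = j, ro = r))
  }
  if (is.null(cand))
    return(data.frame(left = integer(), right = integer(), ro = numeric()))
  cand <- cand[order(-cand$ro, cand$left, cand$right), ]
  used_l <- used_r <- integer(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$left[k] %in% used_l || cand$right[k] %in% used_r) next
    keep[k] <- TRUE
    used_l <- c(used_l, cand$left[k]); used_r <- c(used_r, cand$right[k])
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

# linear-scan overlap count (>= min_bp shared bases)
oracle_count_overlaps <- function(calls, track, min_bp = 1) {
  calls <- as.data.frame(calls)
  vapply(seq_len(nrow(calls)), function(i) {
    sum(track$chrom == calls$chrom[i] &
          pmin(track$end, calls$end[i]) - pmax(track$start, calls$start[i]) >=
          min_bp)
  }, numeric(1))
}

# a labeled 20-call pool with ids c1..c20: 10 TP then 10 FP
worked_example_pool <- function() {
  cs <- cnv_callset(
    data.frame(chrom = "1", start = (0:19) * 1e4, end = (0:19) * 1e4 + 5e3,
               svtype = "DEL", id = sprintf("c%d", 1:20)),
    sample = "s1", origin = "pool")
  labels <- data.frame(id = sprintf("c%d", 1:20),
                       label = rep(c("TRUE_POSITIVE", "FALSE_POSITIVE"),
                                   each = 10),
                       stringsAsFactors = FALSE)
  list(calls = cs, labels = labels)
}

# small simulation config for fast cohort fixtures
small_sim_config <- function(n_truth = 120, ...) {
  simulation_config(contigs = c("1" = 1.5e7, "2" = 1.5e7),
                    n_truth = n_truth, ...)
}
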