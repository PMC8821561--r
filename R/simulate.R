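# Seeded simulator: synthetic truth sets and per-caller observed call sets
# under configurable error models.  Provides labeled fixtures for the
# filters, the combination strategies and the benchmark statistics.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Per-caller error model
#'
#' Describes how a simulated caller distorts the truth: a detection
#' probability (scalar, or a DEL/DUP x size-bin matrix for
#' size-dependent sensitivity), a false-positive rate per megabase,
#' Gaussian breakpoint jitter applied independently to each endpoint,
#' and -- for paired-end callers -- a probability of mislabeling the CNV
#' type (the artifact the delamp filter targets).  \code{emit_support}
#' attaches simulated read-support fractions (higher for true calls),
#' \code{emit_padj} simulated adjusted p values (lower for true calls).
#'
#' @param sensitivity scalar in [0,1], or matrix with rownames
#'   \code{DEL}/\code{DUP} and one column per size bin.
#' @param size_bins bin boundaries matching the sensitivity matrix
#'   columns.
#' @param fpr_per_mb expected false positives per megabase of genome.
#' @param jitter_sd breakpoint jitter standard deviation in bp.
#' @param mislabel_prob probability of flipping DEL/DUP (paired-end
#'   callers only; coverage signal cannot confuse loss with gain).
#' @param emit_support,emit_padj attach simulated quality fields.
#' @return a \code{caller_error_model}.
#' @export
caller_error_model <- function(sensitivity = 0.9,
                               size_bins = c(50, 1e3, 5e3, 5e4, 2e5),
                               fpr_per_mb = 5, jitter_sd = 0,
                               mislabel_prob = 0,
                               emit_support = FALSE, emit_padj = FALSE) {
  stopifnot(all(sensitivity >= 0), all(sensitivity <= 1),
            fpr_per_mb >= 0, jitter_sd >= 0,
            mislabel_prob >= 0, mislabel_prob <= 1)
  if (is.matrix(sensitivity) &&
      (!all(rownames(sensitivity) %in% SVTYPES) ||
       ncol(sensitivity) != length(size_bins)))
    stop("caller_error_model: sensitivity matrix must be DEL/DUP x size bins")
  structure(list(sensitivity = sensitivity, size_bins = size_bins,
                 fpr_per_mb = fpr_per_mb, jitter_sd = jitter_sd,
                 mislabel_prob = mislabel_prob,
                 emit_support = isTRUE(emit_support),
                 emit_padj = isTRUE(emit_padj)),
            class = "caller_error_model")
}

sens_for <- function(model, svtype, len) {
  s <- model$sensitivity
  if (!is.matrix(s)) return(rep(as.numeric(s), length(len)))
  bin <- findInterval(len, model$size_bins)
  bin[bin < 1] <- 1
  s[cbind(svtype, bin)]
}

#' Simulation configuration
#'
#' Study conditions for the simulator.  The defaults emulate a
#' four-caller ensemble on a reduced genome: 240 Mb over four contigs;
#' 2000 non-overlapping truth CNVs, 60% deletions, with sizes
#' log-uniform between 1 kb and 100 kb (the range where all four signal
#' types plausibly operate: above the coverage-caller bin size, within
#' the span array platforms report); per-caller sensitivity 0.9, five
#' false positives per megabase; paired-end callers jitter-free
#' (base-pair breakpoint precision), coverage callers with 100 bp
#' breakpoint jitter echoing their bin size.  Opposite-type mislabels
#' and cohort-shared artifacts are off by default and switched on
#' explicitly by tests that exercise the delamp filter and the SHARED
#' label.
#'
#' @param contigs named numeric vector of contig lengths in bp.
#' @param n_truth number of truth CNVs.
#' @param size_range length-2 numeric, log-uniform truth size range in
#'   bp (applies to both svtypes).
#' @param p_del fraction of deletions in the truth set.
#' @param callers named list of \code{caller_error_model}s.
#' @param profiles matching named list of \code{caller_profile}s.
#' @param shared_rate_per_mb rate of correlated artifact calls injected
#'   into every caller (labeled SHARED).
#' @param min_size minimum call size in bp.
#' @return a \code{simulation_config}.
#' @export
simulation_config <- function(contigs = c("1" = 6e7, "2" = 6e7,
                                          "3" = 6e7, "4" = 6e7),
                              n_truth = 2000,
                              size_range = c(1e3, 1e5),
                              p_del = 0.6,
                              callers = default_error_models(),
                              profiles = default_caller_profiles(),
                              shared_rate_per_mb = 0,
                              min_size = MIN_SV_SIZE) {
  stopifnot(length(contigs) >= 1, !is.null(names(contigs)),
            all(contigs > 0), n_truth >= 0,
            length(size_range) == 2, size_range[1] >= min_size,
            size_range[2] > size_range[1],
            p_del >= 0, p_del <= 1, shared_rate_per_mb >= 0)
  structure(list(contigs = contigs, n_truth = n_truth,
                 size_range = size_range, p_del = p_del,
                 callers = callers, profiles = profiles,
                 shared_rate_per_mb = shared_rate_per_mb,
                 min_size = min_size),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @param sensitivity,fpr_per_mb shared by the four default models.
#' @export
default_error_models <- function(sensitivity = 0.9, fpr_per_mb = 5) {
  list(
    manta    = caller_error_model(sensitivity, fpr_per_mb = fpr_per_mb,
                                  jitter_sd = 0, emit_support = TRUE),
    delly    = caller_error_model(sensitivity, fpr_per_mb = fpr_per_mb,
                                  jitter_sd = 0, emit_support = TRUE),
    erds     = caller_error_model(sensitivity, fpr_per_mb = fpr_per_mb,
                                  jitter_sd = 100),
    cnvnator = caller_error_model(sensitivity, fpr_per_mb = fpr_per_mb,
                                  jitter_sd = 100, emit_padj = TRUE)
  )
}

# draw n interval sizes, log-uniform over cfg$size_range
draw_sizes <- function(n, cfg) {
  round(exp(stats::runif(n, log(cfg$size_range[1]), log(cfg$size_range[2]))))
}

# place n intervals uniformly on the genome (contig weighted by length)
place_uniform <- function(n, sizes, cfg) {
  lens <- cfg$contigs
  ci <- sample(seq_along(lens), n, replace = TRUE, prob = lens)
  start <- floor(stats::runif(n) * pmax(1, lens[ci] - sizes))
  data.frame(chrom = names(lens)[ci], start = start,
             end = start + sizes, stringsAsFactors = FALSE)
}

#' Simulate a truth CNV set
#'
#' Draws \code{cfg$n_truth} non-overlapping truth calls: svtype
#' Bernoulli(\code{p_del}), sizes log-uniform over \code{size_range},
#' positions uniform on the genome with rejection of any overlap with a
#' previously placed call (nested/tandem events are deliberately
#' excluded so downstream labels stay unambiguous).  Deterministic given
#' the seed.
#'
#' @param cfg a \code{simulation_config}.
#' @param seed integer seed.
#' @param sample sample id of the truth set.
#' @return a \code{cnv_callset} with origin \code{"truth"}.
#' @export
simulate_truth <- function(cfg, seed = 1, sample = "sim") {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_truth
  if (n == 0) return(empty_callset(sample, "truth"))
  with_seed(seed, {
    placed <- vector("list", n)
    by_chrom <- lapply(cfg$contigs, function(...)
      list(start = numeric(0), end = numeric(0)))
    names(by_chrom) <- names(cfg$contigs)
    # the size is drawn once per call and only the position is re-sampled on
    # collision, so crowding cannot bias the size distribution
    sizes <- draw_sizes(n, cfg)
    for (k in seq_len(n)) {
      ok <- FALSE
      for (attempt in 1:200) {
        pos <- place_uniform(1, sizes[k], cfg)
        bc <- by_chrom[[pos$chrom]]
        if (!any(pos$start < bc$end & pos$end > bc$start)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("simulate_truth: could not place ", n,
             " non-overlapping calls (genome too small for the size range)")
      placed[[k]] <- pos
      by_chrom[[pos$chrom]]$start <- c(bc$start, pos$start)
      by_chrom[[pos$chrom]]$end <- c(bc$end, pos$end)
    }
    df <- do.call(rbind, placed)
    df$svtype <- ifelse(stats::runif(n) < cfg$p_del, "DEL", "DUP")
    df$id <- sprintf("truth_%04d", seq_len(n))
    cnv_callset(df, sample = sample, origin = "truth",
                min_size = cfg$min_size)
  })
}

# simulated quality fields: true calls get strong support / low adjusted p
sim_quality <- function(model, n, is_true) {
  pe <- sr <- padj <- rep(NA_real_, n)
  if (model$emit_support && n) {
    pe <- ifelse(is_true, stats::rbeta(n, 8, 2), stats::rbeta(n, 2, 8))
    sr <- ifelse(is_true, stats::rbeta(n, 8, 2), stats::rbeta(n, 2, 8))
  }
  if (model$emit_padj && n)
    padj <- ifelse(is_true, stats::rbeta(n, 1, 9), stats::rbeta(n, 6, 4))
  list(pe = pe, sr = sr, padj = padj)
}

#' Simulate one caller's observed call set
#'
#' Each truth call is emitted with its svtype-and-size-dependent
#' sensitivity; emitted breakpoints receive independent rounded Gaussian
#' jitter (end clamped to keep the minimum size); paired-end callers
#' flip the svtype with the mislabel probability.  False positives are
#' placed uniformly at \code{fpr_per_mb} (Poisson count) with sizes from
#' the truth distribution.  Optional cohort-shared artifact calls are
#' injected verbatim (plus jitter) and labeled \code{SHARED}.  Labels
#' partition the output exactly: \code{TRUE_POSITIVE} for truth-derived
#' calls, \code{FALSE_POSITIVE} for invented ones, \code{SHARED} for
#' artifacts.  Deterministic given the seed.
#'
#' @param truth truth \code{cnv_callset}.
#' @param cfg a \code{simulation_config}.
#' @param caller caller name (must key into \code{cfg$callers}).
#' @param seed integer seed.
#' @param shared optional data frame of shared-artifact intervals
#'   (\code{chrom}, \code{start}, \code{end}, \code{svtype}).
#' @return list with \code{calls} (a \code{cnv_callset}) and
#'   \code{labels} (data frame \code{id}, \code{label}).
#' @export
simulate_caller <- function(truth, cfg, caller, seed = 1, shared = NULL) {
  stopifnot(inherits(cfg, "simulation_config"),
            caller %in% names(cfg$callers))
  model <- cfg$callers[[caller]]
  profile <- cfg$profiles[[caller]]
  with_seed(seed, {
    tdf <- as.data.frame(truth)
    len <- tdf$end - tdf$start
    s <- sens_for(model, tdf$svtype, len)
    hit <- stats::runif(nrow(tdf)) < s
    emitted <- tdf[hit, c("chrom", "start", "end", "svtype"), drop = FALSE]
    emitted$label <- rep("TRUE_POSITIVE", nrow(emitted))

    genome_mb <- sum(cfg$contigs) / 1e6
    n_fp <- stats::rpois(1, model$fpr_per_mb * genome_mb)
    if (n_fp > 0) {
      fp <- place_uniform(n_fp, draw_sizes(n_fp, cfg), cfg)
      fp$svtype <- ifelse(stats::runif(n_fp) < cfg$p_del, "DEL", "DUP")
      fp$label <- "FALSE_POSITIVE"
      emitted <- rbind(emitted, fp)
    }
    if (!is.null(shared) && nrow(shared)) {
      sh <- shared[c("chrom", "start", "end", "svtype")]
      sh$label <- "SHARED"
      emitted <- rbind(emitted, sh)
    }
    n <- nrow(emitted)
    if (n == 0) {
      out <- list(calls = empty_callset(callset_sample(truth), caller),
                  labels = data.frame(id = character(),
                                      label = character(),
                                      stringsAsFactors = FALSE))
    } else {
    if (model$jitter_sd > 0) {
      emitted$start <- emitted$start + round(stats::rnorm(n, 0, model$jitter_sd))
      emitted$end <- emitted$end + round(stats::rnorm(n, 0, model$jitter_sd))
      emitted$start <- pmax(0, emitted$start)
      emitted$end <- pmax(emitted$end, emitted$start + cfg$min_size)
    }
    if (model$mislabel_prob > 0 && profile$signal_class == "paired_end") {
      flip <- stats::runif(n) < model$mislabel_prob
      emitted$svtype[flip] <- ifelse(emitted$svtype[flip] == "DEL",
                                     "DUP", "DEL")
    }
    q <- sim_quality(model, n, emitted$label == "TRUE_POSITIVE")
    emitted$pe_frac <- q$pe; emitted$sr_frac <- q$sr
    emitted$adjusted_p <- q$padj
    emitted$id <- sprintf("%s_%05d", caller, seq_len(n))
    calls <- cnv_callset(emitted[setdiff(names(emitted), "label")],
                         sample = callset_sample(truth), origin = caller,
                         min_size = cfg$min_size)
    labels <- data.frame(id = emitted$id, label = emitted$label,
                         stringsAsFactors = FALSE)
    labels <- labels[match(calls$id, labels$id), ]
    rownames(labels) <- NULL
    out <- list(calls = calls, labels = labels)
    }
    out
  })
}

#' Simulate a full four-caller cohort sample
#'
#' One truth set plus one observed call set per configured caller, with
#' cohort-shared artifacts (if any) drawn once and injected into every
#' caller.  Per-caller seeds are derived deterministically from the
#' master seed.
#'
#' @param cfg a \code{simulation_config}.
#' @param seed master integer seed.
#' @param sample sample id.
#' @return list with \code{truth}, \code{callsets} (named list),
#'   \code{labels} (named list of data frames) and \code{shared}.
#' @export
simulate_cohort <- function(cfg, seed = 1, sample = "sim") {
  stopifnot(inherits(cfg, "simulation_config"))
  sub <- with_seed(seed, sample.int(2^30, length(cfg$callers) + 2))
  truth <- simulate_truth(cfg, seed = sub[1], sample = sample)
  shared <- NULL
  if (cfg$shared_rate_per_mb > 0) {
    shared <- with_seed(sub[2], {
      n_sh <- stats::rpois(1, cfg$shared_rate_per_mb * sum(cfg$contigs) / 1e6)
      if (n_sh > 0) {
        sh <- place_uniform(n_sh, draw_sizes(n_sh, cfg), cfg)
        sh$svtype <- ifelse(stats::runif(n_sh) < cfg$p_del, "DEL", "DUP")
        sh
      } else NULL
    })
  }
  callsets <- list(); labels <- list()
  for (k in seq_along(cfg$callers)) {
    nm <- names(cfg$callers)[k]
    res <- simulate_caller(truth, cfg, nm, seed = sub[k + 2], shared = shared)
    callsets[[nm]] <- res$calls
    labels[[nm]] <- res$labels
  }
  list(truth = truth, callsets = callsets, labels = labels, shared = shared)
}

#' Simulate a regenotyper over candidate calls
#'
#' Emulates an external SVM regenotyper's output: truth-supported
#' candidates receive a non-reference genotype with probability
#' \code{p_nonref_true} (HET/HOM_ALT at 4:1), unsupported candidates
#' with probability \code{p_nonref_false}; a small fraction of
#' genotypes comes back missing.  "Truth-supported" means matching a
#' truth call at reciprocal overlap 0.5 (same type).
#'
#' @param calls candidate \code{cnv_callset}.
#' @param truth truth \code{cnv_callset}.
#' @param seed integer seed.
#' @param p_nonref_true,p_nonref_false non-reference genotype rates.
#' @param p_missing missing-genotype rate.
#' @return \code{calls} with genotypes filled in.
#' @export
simulate_regenotyper <- function(calls, truth, seed = 1,
                                 p_nonref_true = 0.95,
                                 p_nonref_false = 0.1,
                                 p_missing = 0.02) {
  stopifnot(is_cnv_callset(calls), is_cnv_callset(truth))
  m <- suppressWarnings(match_sets(calls, truth, ro_min = 0.5,
                                   same_type = TRUE))
  supported <- logical(nrow(calls))
  supported[m$pairs$left] <- TRUE
  with_seed(seed, {
    n <- nrow(calls)
    p <- ifelse(supported, p_nonref_true, p_nonref_false)
    nonref <- stats::runif(n) < p
    g <- ifelse(nonref,
                ifelse(stats::runif(n) < 0.8, "HET", "HOM_ALT"),
                "HOM_REF")
    g[stats::runif(n) < p_missing] <- "MISSING"
    df <- as.data.frame(calls)
    df$genotype <- g
    rewrap_callset(df, callset_sample(calls), "regenotyped")
  })
}

#' Analytic expected strategy performance under caller independence
#'
#' Closed-form expectations used as an independent oracle for the
#' simulator + combiner round trip.  Assuming callers detect each truth
#' call independently with sensitivities \code{s} (and ignoring
#' breakpoint jitter, which can break the within-pair intersection for
#' calls whose size is comparable to the jitter), the expected
#' per-truth-call sensitivity is \code{1 - prod(1 - s)} for the union
#' and \code{1 - (1 - s1*s2) * (1 - s3*s4)} for the intersection-union
#' (detected by at least one complete same-signal pair).  The expected
#' number of false-positive calls surviving a pair intersection is
#' computed by numerically integrating, over the size distribution and
#' uniform placements, the probability that two independent false calls
#' co-locate at reciprocal overlap \code{ro} or above.
#'
#' @param cfg a \code{simulation_config}.
#' @param strategy \code{"union"} or \code{"intersection_union"}.
#' @param pe_pair,cov_pair caller names (defaults: first two / last two
#'   configured callers).
#' @param ro intersection threshold for the false-positive co-location
#'   integral (default 0.75).
#' @param grid_n grid resolution of the numeric integral.
#' @return list with \code{sensitivity}, \code{expected_fp}, and the
#'   stated assumptions.
#' @export
expected_strategy_stats <- function(cfg,
                                    strategy = c("intersection_union",
                                                 "union"),
                                    pe_pair = NULL, cov_pair = NULL,
                                    ro = 0.75, grid_n = 120) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cfg, "simulation_config"))
  nm <- names(cfg$callers)
  pe_pair <- pe_pair %||% nm[1:2]
  cov_pair <- cov_pair %||% nm[3:4]
  mean_sens <- function(caller) {
    s <- cfg$callers[[caller]]$sensitivity
    mean(s)
  }
  s <- vapply(c(pe_pair, cov_pair), mean_sens, numeric(1))
  sensitivity <- if (strategy == "union") 1 - prod(1 - s)
  else 1 - (1 - s[1] * s[2]) * (1 - s[3] * s[4])

  G <- sum(cfg$contigs)
  lam <- vapply(c(pe_pair, cov_pair),
                function(cl) cfg$callers[[cl]]$fpr_per_mb * G / 1e6,
                numeric(1))
  if (strategy == "union") {
    expected_fp <- sum(lam)   # dedup collisions between FP sets are negligible
  } else {
    # E[w(L1, L2)]: measure of relative placements of two independent
    # intervals achieving ro >= threshold, integrated over the log-uniform
    # size distribution on a deterministic grid
    lg <- seq(log(cfg$size_range[1]), log(cfg$size_range[2]),
              length.out = grid_n)
    L <- exp(lg)
    w <- outer(L, L, function(l1, l2) {
      mx <- pmax(l1, l2)
      ifelse(pmin(l1, l2) >= ro * mx, l1 + l2 - 2 * ro * mx, 0)
    })
    Ew <- mean(w)  # uniform weight on the log grid = log-uniform sizes
    # per-type matching halves the effective partner intensity
    type_w <- cfg$p_del^2 + (1 - cfg$p_del)^2
    expected_fp <- (lam[1] * lam[2] + lam[3] * lam[4]) * type_w * Ew / G
  }
  list(strategy = strategy, sensitivity = unname(sensitivity),
       expected_fp = unname(expected_fp),
       assumes_independence = TRUE, ignores_jitter = TRUE)
}
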