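# Performance statistics against labeled truth pools and reference call sets.

TRUTH_LABELS <- c("TRUE_POSITIVE", "FALSE_POSITIVE", "SHARED", "DOUBTFUL")

#' Read / write truth labels
#'
#' Truth labels assign each call id one of \code{TRUE_POSITIVE},
#' \code{FALSE_POSITIVE}, \code{SHARED} (present in the index case and
#' the parents, a possible alignment artifact) or \code{DOUBTFUL}.  The
#' TSV carries two named columns, \code{id} and \code{label}.
#'
#' @param path TSV file.
#' @return data frame \code{id}, \code{label}.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df)))
    stop("read_labels: need columns 'id' and 'label'")
  bad <- setdiff(unique(df$label), TRUTH_LABELS)
  if (length(bad))
    stop("read_labels: unknown label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("read_labels: duplicated call id(s)")
  df[c("id", "label")]
}

#' @rdname read_labels
#' @param labels data frame \code{id}, \code{label}.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Benchmark a filter or strategy against a labeled call pool
#'
#' Applies \code{transform} to the labeled pool and cross-tabulates
#' retention against the labels.  Statistics are computed over the
#' labeled pool itself (not genome-wide): sensitivity is the fraction of
#' true-positive calls retained, specificity the fraction of
#' false-positive calls removed, PPV the true-positive fraction of the
#' retained calls, accuracy the fraction of calls handled correctly
#' (true positives kept plus false positives removed over all labeled
#' calls), and the PPV ratio compares the post-filter PPV with the
#' baseline PPV of the unfiltered pool.  \code{SHARED} and
#' \code{DOUBTFUL} calls are excluded from the 2x2 table and counted
#' separately.
#'
#' @param calls labeled \code{cnv_callset}.
#' @param labels data frame \code{id}, \code{label} covering every call
#'   (an unlabeled call is a hard error).
#' @param transform function mapping a call set to a filtered call set
#'   (a bare call set or a \code{list(calls=, report=)} filter result).
#' @return a \code{cnv_benchmark} report.
#' @export
evaluate_filter <- function(calls, labels, transform) {
  stopifnot(is_cnv_callset(calls), is.function(transform))
  lab <- labels$label[match(calls$id, labels$id)]
  if (anyNA(lab))
    stop("evaluate_filter: unlabeled call id(s): ",
         paste(utils::head(calls$id[is.na(lab)], 5), collapse = ", "))
  out <- transform(calls)
  if (is.list(out) && !is.data.frame(out) && !is.null(out$calls))
    out <- out$calls
  kept <- calls$id %in% out$id
  tp <- lab == "TRUE_POSITIVE"; fp <- lab == "FALSE_POSITIVE"
  counts <- c(tp_kept = sum(tp & kept), tp_removed = sum(tp & !kept),
              fp_kept = sum(fp & kept), fp_removed = sum(fp & !kept))
  benchmark_report(counts,
                   excluded = table(lab[!(tp | fp)]))
}

#' Assemble a benchmark report from contingency counts
#'
#' @param counts named vector \code{tp_kept}, \code{tp_removed},
#'   \code{fp_kept}, \code{fp_removed}.
#' @param excluded optional table of SHARED/DOUBTFUL counts.
#' @return a \code{cnv_benchmark}: the counts plus sensitivity,
#'   specificity, PPV (NA when nothing is retained), accuracy, baseline
#'   PPV and PPV ratio.
#' @export
benchmark_report <- function(counts, excluded = NULL) {
  k <- as.numeric(counts[c("tp_kept", "tp_removed", "fp_kept", "fp_removed")])
  names(k) <- c("tp_kept", "tp_removed", "fp_kept", "fp_removed")
  total <- sum(k)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  ppv <- div(k["tp_kept"], k["tp_kept"] + k["fp_kept"])
  baseline <- div(k["tp_kept"] + k["tp_removed"], total)
  structure(list(
    counts = k,
    sensitivity = unname(div(k["tp_kept"], k["tp_kept"] + k["tp_removed"])),
    specificity = unname(div(k["fp_removed"], k["fp_kept"] + k["fp_removed"])),
    ppv = unname(ppv),
    accuracy = unname(div(k["tp_kept"] + k["fp_removed"], total)),
    baseline_ppv = unname(baseline),
    ppv_ratio = unname(if (is.na(ppv) || is.na(baseline) || baseline == 0)
      NA_real_ else ppv / baseline),
    excluded = excluded), class = "cnv_benchmark")
}

#' @export
print.cnv_benchmark <- function(x, ...) {
  cat("benchmark report\n")
  cat(sprintf("  TP kept/removed: %d/%d   FP kept/removed: %d/%d\n",
              x$counts["tp_kept"], x$counts["tp_removed"],
              x$counts["fp_kept"], x$counts["fp_removed"]))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  ppv %s  accuracy %.3f  ppv_ratio %s\n",
              x$sensitivity, x$specificity,
              ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv)),
              x$accuracy,
              ifelse(is.na(x$ppv_ratio), "NA", sprintf("%.2f", x$ppv_ratio))))
  if (!is.null(x$excluded) && length(x$excluded) && sum(x$excluded) > 0)
    cat("  excluded from 2x2:",
        paste(names(x$excluded), as.integer(x$excluded), sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}

#' Detection rate of a truth set by candidate call sets
#'
#' A truth call counts as detected by a candidate set when it joins a
#' greedy one-to-one same-type match at reciprocal overlap
#' \code{ro_min} or above; the any-set flag is the disjunction over
#' candidate sets.  The best observed RO per truth call (many-to-many,
#' across all candidates) is reported as a diagnostic for near-misses --
#' reference techniques with sparse breakpoint resolution typically
#' produce truth intervals that match a call only at lower overlap.
#'
#' @param truth \code{cnv_callset} of reference calls.
#' @param candidates list of \code{cnv_callset}s (named; origins used
#'   otherwise).
#' @param ro_min detection threshold (default 0.5).
#' @return list with \code{per_truth} (data frame: truth id, one logical
#'   column per candidate set, \code{any}, \code{best_ro}),
#'   \code{fraction} (named per-set detection fractions) and
#'   \code{any_fraction}.
#' @export
detection_rate <- function(truth, candidates, ro_min = 0.5) {
  stopifnot(is_cnv_callset(truth))
  if (is_cnv_callset(candidates)) candidates <- list(candidates)
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    names(candidates) <- vapply(candidates, callset_origin, character(1))
  n <- nrow(truth)
  flags <- matrix(FALSE, n, length(candidates),
                  dimnames = list(NULL, names(candidates)))
  best <- numeric(n)
  for (k in seq_along(candidates)) {
    cs <- candidates[[k]]
    m <- suppressWarnings(match_sets(truth, cs, ro_min = ro_min,
                                     same_type = TRUE))
    flags[m$pairs$left, k] <- TRUE
    cand <- candidate_pairs(as.data.frame(truth), as.data.frame(cs),
                            ro_min = 0 + 1e-12, same_type = TRUE)
    if (nrow(cand)) {
      agg <- tapply(cand$ro, cand$left, max)
      idx <- as.integer(names(agg))
      best[idx] <- pmax(best[idx], as.numeric(agg))
    }
  }
  per_truth <- data.frame(id = truth$id, flags, any = rowSums(flags) > 0,
                          best_ro = best, stringsAsFactors = FALSE,
                          check.names = FALSE)
  list(per_truth = per_truth,
       fraction = if (n) colMeans(flags) else
         stats::setNames(rep(NA_real_, length(candidates)),
                         names(candidates)),
       any_fraction = if (n) mean(per_truth$any) else NA_real_)
}

#' Size-bin summary of a call set
#'
#' Counts calls per svtype and left-closed size bin.  The default bins
#' follow the conventional reporting ranges: [50 bp, 1 kb), [1, 5 kb),
#' [5, 50 kb), [50, 200 kb), [200 kb, Inf).
#'
#' @param calls \code{cnv_callset}.
#' @param bins strictly increasing bin boundaries in bp.
#' @return matrix of counts, svtype x bin.
#' @export
size_bin_summary <- function(calls, bins = c(50, 1e3, 5e3, 5e4, 2e5)) {
  stopifnot(is_cnv_callset(calls))
  if (is.unsorted(bins, strictly = TRUE))
    stop("size_bin_summary: bins must be strictly increasing")
  brk <- c(bins, Inf)
  labs <- paste0("[", format(brk[-length(brk)], trim = TRUE, scientific = FALSE),
                 ",", format(brk[-1], trim = TRUE, scientific = FALSE), ")")
  len <- calls$end - calls$start
  bin <- cut(len, breaks = brk, right = FALSE, labels = labs)
  out <- table(factor(calls$svtype, SVTYPES), bin)
  unclass(as.matrix(out))
}

#' Caller agreement profile
#'
#' For every call of every input set, which of the other sets confirm it
#' (greedy one-to-one same-type match at \code{ro_min} or above), plus a
#' histogram of agreement counts.  True calls tend to be confirmed by
#' several callers -- most often the same-signal partner -- while false
#' positives tend to be unique.
#'
#' @param callsets list of two or more \code{cnv_callset}s (named;
#'   origins used otherwise).
#' @param ro_min agreement threshold (default 0.5).
#' @return list with \code{per_call} (data frame: set, id,
#'   \code{agree_n}, \code{agree_with} comma-joined set names) and
#'   \code{histogram} (table of \code{agree_n} per set).
#' @export
caller_overlap_profile <- function(callsets, ro_min = 0.5) {
  stopifnot(length(callsets) >= 2,
            all(vapply(callsets, is_cnv_callset, logical(1))))
  if (is.null(names(callsets)) || any(!nzchar(names(callsets))))
    names(callsets) <- vapply(callsets, callset_origin, character(1))
  nm <- names(callsets)
  agree <- lapply(callsets, function(cs)
    matrix(FALSE, nrow(cs), length(nm), dimnames = list(NULL, nm)))
  for (a in seq_along(callsets)) for (b in seq_along(callsets)) {
    if (a >= b) next
    m <- suppressWarnings(match_sets(callsets[[a]], callsets[[b]],
                                     ro_min = ro_min, same_type = TRUE))
    agree[[a]][m$pairs$left, b] <- TRUE
    agree[[b]][m$pairs$right, a] <- TRUE
  }
  per_call <- do.call(rbind, lapply(seq_along(callsets), function(k) {
    cs <- callsets[[k]]
    ag <- agree[[k]]
    data.frame(set = nm[k], id = cs$id,
               agree_n = if (nrow(cs)) rowSums(ag) else integer(0),
               agree_with = if (nrow(cs))
                 apply(ag, 1, function(r) paste(nm[r], collapse = ","))
               else character(0),
               stringsAsFactors = FALSE)
  }))
  rownames(per_call) <- NULL
  list(per_call = per_call,
       histogram = table(set = per_call$set, agree_n = per_call$agree_n))
}
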