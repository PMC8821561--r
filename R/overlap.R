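# Reciprocal-overlap interval algebra and greedy one-to-one matching.

#' Reciprocal overlap of two genomic intervals
#'
#' The reciprocal overlap (RO) of intervals a and b is
#' \code{min(o/len(a), o/len(b))} where \code{o} is the length of their
#' intersection; equivalently \code{o / max(len(a), len(b))}.  It is 1
#' for identical intervals, 0 for disjoint intervals or intervals on
#' different contigs, and symmetric in its arguments.  Two calls are
#' conventionally considered shared when their RO exceeds 0.5; the
#' stricter 0.75 threshold drives pair intersection and the delamp
#' filter.
#'
#' Vectorized over all arguments (recycled to a common length).
#'
#' @param chrom_a,start_a,end_a first interval (0-based half-open).
#' @param chrom_b,start_b,end_b second interval.
#' @return numeric vector of RO fractions in [0,1].
#' @examples
#' reciprocal_overlap("1", 0, 1000, "1", 500, 2500)  # 0.25
#' @export
reciprocal_overlap <- function(chrom_a, start_a, end_a,
                               chrom_b, start_b, end_b) {
  n <- max(length(start_a), length(start_b))
  chrom_a <- rep_len(as.character(chrom_a), n)
  chrom_b <- rep_len(as.character(chrom_b), n)
  start_a <- rep_len(as.numeric(start_a), n); end_a <- rep_len(as.numeric(end_a), n)
  start_b <- rep_len(as.numeric(start_b), n); end_b <- rep_len(as.numeric(end_b), n)
  if (any(end_a <= start_a) || any(end_b <= start_b))
    stop("reciprocal_overlap: invalid interval (end <= start)")
  o <- pmin(end_a, end_b) - pmax(start_a, start_b)
  ro <- pmax(0, o) / pmax(end_a - start_a, end_b - start_b)
  ro[chrom_a != chrom_b] <- 0
  ro
}

# GRanges view of a call-row data frame (shift +1: GRanges is 1-based closed)
calls_gr <- function(df) {
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Build an interval index over a call set
#'
#' Wraps the call set in a \code{GRanges}-backed index supporting overlap
#' queries.  \code{query_index()} returns the rows of the call set whose
#' intervals intersect the query (by at least 1 bp).
#'
#' @param calls a \code{cnv_callset}.
#' @return an object of class \code{cnv_index}.
#' @export
build_index <- function(calls) {
  stopifnot(is_cnv_callset(calls))
  structure(list(calls = calls, gr = calls_gr(calls)), class = "cnv_index")
}

#' @rdname build_index
#' @param index a \code{cnv_index}.
#' @param chrom,start,end query interval (0-based half-open).
#' @return for \code{query_index}, the subset of the indexed call set
#'   overlapping the query.
#' @export
query_index <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "cnv_index"), end > start)
  if (length(index$gr) == 0) return(index$calls[integer(0), ])
  q <- GenomicRanges::GRanges(as.character(chrom),
                              IRanges::IRanges(start + 1, end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, index$gr))
  index$calls[sort(unique(S4Vectors::subjectHits(hits))), ]
}

#' @export
print.cnv_index <- function(x, ...) {
  cat(sprintf("interval index over %d call(s)\n", nrow(x$calls)))
  invisible(x)
}

# all candidate (i, j, ro) triples between two call-row frames with ro >= ro_min;
# same_type additionally requires equal svtype
candidate_pairs <- function(a, b, ro_min, same_type = TRUE) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(left = integer(), right = integer(), ro = numeric()))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(calls_gr(a), calls_gr(b)))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  if (!length(i))
    return(data.frame(left = integer(), right = integer(), ro = numeric()))
  o <- pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j])
  ro <- pmax(0, o) / pmax(a$end[i] - a$start[i], b$end[j] - b$start[j])
  keep <- ro >= ro_min
  if (same_type) keep <- keep & (a$svtype[i] == b$svtype[j])
  data.frame(left = i[keep], right = j[keep], ro = ro[keep])
}

# greedy one-to-one selection from candidate triples:
# decreasing ro, ties by left index then right index (call sets are sorted,
# so smaller index = leftmost call)
greedy_select <- function(cand, n_left, n_right) {
  if (!nrow(cand))
    return(cand)
  o <- order(-cand$ro, cand$left, cand$right)
  cand <- cand[o, , drop = FALSE]
  used_l <- logical(n_left); used_r <- logical(n_right)
  take <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$left[k]; j <- cand$right[k]
    if (!used_l[i] && !used_r[j]) {
      take[k] <- TRUE
      used_l[i] <- TRUE; used_r[j] <- TRUE
    }
  }
  out <- cand[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match two call sets by reciprocal overlap
#'
#' Greedy one-to-one matching: all candidate pairs with RO at or above
#' \code{ro_min} (and, when \code{same_type}, equal svtype) are accepted
#' in order of decreasing RO, ties broken by the leftmost left-side call
#' and then the leftmost right-side call.  Each call joins at most one
#' pair.  This mirrors reciprocal bedtools-style intersection while
#' remaining deterministic and oracle-checkable.
#'
#' @param A,B sorted \code{cnv_callset}s.  Samples may differ (a warning
#'   is emitted), which supports truth-set comparison.
#' @param ro_min minimum reciprocal overlap, in (0, 1].
#' @param same_type require equal svtype within a pair (default TRUE).
#' @return list with \code{pairs} (data frame \code{left}, \code{right}
#'   row indices into A and B, \code{left_id}, \code{right_id},
#'   \code{ro}), \code{unmatched_left} and \code{unmatched_right} (row
#'   indices).
#' @export
match_sets <- function(A, B, ro_min = 0.5, same_type = TRUE) {
  stopifnot(is_cnv_callset(A), is_cnv_callset(B),
            ro_min > 0, ro_min <= 1)
  assert_sorted(A, "left call set"); assert_sorted(B, "right call set")
  if (nrow(A) && nrow(B) &&
      !identical(callset_sample(A), callset_sample(B)))
    warning("match_sets: call sets come from different samples (",
            callset_sample(A), " vs ", callset_sample(B), ")")
  sel <- greedy_select(candidate_pairs(A, B, ro_min, same_type),
                       nrow(A), nrow(B))
  pairs <- data.frame(left = sel$left, right = sel$right,
                      left_id = A$id[sel$left], right_id = B$id[sel$right],
                      ro = sel$ro, stringsAsFactors = FALSE)
  list(pairs = pairs,
       unmatched_left = setdiff(seq_len(nrow(A)), sel$left),
       unmatched_right = setdiff(seq_len(nrow(B)), sel$right))
}
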