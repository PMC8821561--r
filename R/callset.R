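#' cnvensemble: ensemble combination and benchmarking of CNV call sets
#'
#' Copy-number variants (CNVs) -- deletions and duplications larger than
#' ~50 bp -- are called from whole-genome sequencing by tools that exploit
#' different signals: discordant read pairs and split reads (Delly, Manta)
#' or depth-of-coverage deviations in fixed bins (CNVnator, ERDS).  The
#' resulting call sets overlap poorly, and no single caller dominates.
#' This package implements the ensemble approach of combining four such
#' callers: each caller's output is normalized into a common call-set
#' representation, cleaned with per-caller filters, and merged either by a
#' plain union or by the intersection-union strategy (intersect the two
#' paired-end callers and the two coverage callers separately at 75%
#' reciprocal overlap, then pool the two intersections).  Either strategy
#' can be followed by a non-reference genotype filter applied to
#' regenotyped calls.  Benchmarking utilities compute contingency
#' statistics against labeled truth pools and detection rates against
#' reference call sets, and a seeded simulator generates truth sets and
#' per-caller observed call sets under configurable error models.
#'
#' All interval arithmetic is 0-based half-open internally; VCF
#' coordinates are converted at the I/O boundary.
#'
#' @keywords internal
#' @aliases cnvensemble-package
"_PACKAGE"

# -- internal coordinate conventions -----------------------------------------
# chrom: character, "chr" prefix stripped by default at I/O.
# start/end: 0-based half-open doubles (positions can exceed .Machine$integer.max
#            on concatenated genomes; doubles are exact below 2^53).

SVTYPES <- c("DEL", "DUP")
GENOTYPES <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")

#' Minimum structural-variant size
#'
#' Default lower bound on call length in base pairs.  Events at or above
#' 50 bp are structural variants by the usual definition; shorter records
#' are rejected at call-set construction.
#' @keywords internal
MIN_SV_SIZE <- 50

#' Construct a CNV call set
#'
#' A call set is the ordered collection of deletion/duplication calls for
#' one sample from one caller (or one combination strategy).  It is
#' represented as a data frame with one row per call, carrying class
#' \code{cnv_callset} and attributes \code{sample} and \code{origin}.
#'
#' Columns: \code{id}, \code{chrom}, \code{start}, \code{end} (0-based
#' half-open), \code{svtype} (\code{"DEL"}/\code{"DUP"}),
#' \code{caller}, \code{pe_frac}, \code{sr_frac} (paired-end / split-read
#' support fractions in [0,1] or \code{NA}), \code{adjusted_p}
#' (probability or \code{NA}), \code{genotype} (\code{"HOM_REF"},
#' \code{"HET"}, \code{"HOM_ALT"}, \code{"MISSING"} or \code{NA} when no
#' genotyping was attempted), and \code{sources}, a list column of
#' per-call provenance data frames (\code{caller}, \code{chrom},
#' \code{start}, \code{end}) recording every caller record merged into
#' the call.
#'
#' Calls are validated (\code{end > start}, \code{start >= 0}, length at
#' least \code{min_size}, known svtype) and sorted by
#' (\code{chrom}, \code{start}, \code{end}).
#'
#' @param calls data frame with at least \code{chrom}, \code{start},
#'   \code{end}, \code{svtype}; other columns optional.
#' @param sample sample identifier.
#' @param origin caller id or strategy name the set came from.
#' @param min_size minimum call length in bp (default 50).
#' @param strip_chr drop a leading \code{"chr"} from contig names
#'   (default \code{TRUE}; keeps mixed hg19 resources comparable).
#' @return a \code{cnv_callset}.
#' @examples
#' cs <- cnv_callset(data.frame(chrom = "1", start = 1000, end = 2000,
#'                              svtype = "DEL"),
#'                   sample = "S1", origin = "delly")
#' nrow(cs)
#' @export
cnv_callset <- function(calls, sample, origin,
                        min_size = MIN_SV_SIZE, strip_chr = TRUE) {
  stopifnot(is.data.frame(calls))
  need <- c("chrom", "start", "end", "svtype")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("cnv_callset: missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(calls)
  chrom <- as.character(calls$chrom)
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  start <- as.numeric(calls$start)
  end <- as.numeric(calls$end)
  svtype <- toupper(as.character(calls$svtype))
  if (n > 0) {
    if (anyNA(start) || anyNA(end))
      stop("cnv_callset: non-numeric coordinates")
    bad <- which(end <= start | start < 0)
    if (length(bad))
      stop("cnv_callset: invalid interval(s) (end <= start or start < 0) at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    small <- which(end - start < min_size)
    if (length(small))
      stop("cnv_callset: call(s) below the minimum SV size of ", min_size,
           " bp at row(s) ", paste(utils::head(small, 5), collapse = ", "))
    if (!all(svtype %in% SVTYPES))
      stop("cnv_callset: svtype must be one of ",
           paste(SVTYPES, collapse = "/"))
  }

  grab <- function(col, default = NA_real_) {
    if (col %in% names(calls)) as.numeric(calls[[col]]) else rep(default, n)
  }
  caller <- if ("caller" %in% names(calls))
    as.character(calls$caller) else rep(as.character(origin), n)
  genotype <- if ("genotype" %in% names(calls))
    as.character(calls$genotype) else rep(NA_character_, n)
  if (n > 0 && !all(is.na(genotype) | genotype %in% GENOTYPES))
    stop("cnv_callset: unknown genotype code")
  id <- if ("id" %in% names(calls) && !anyNA(calls$id))
    as.character(calls$id)
  else
    sprintf("%s_%s_%s_%d", origin, svtype, chrom, seq_len(n))
  if (anyDuplicated(id))
    id <- make.unique(id, sep = "_dup")

  sources <- if ("sources" %in% names(calls)) calls$sources else {
    lapply(seq_len(n), function(i)
      data.frame(caller = caller[i], chrom = chrom[i],
                 start = start[i], end = end[i],
                 stringsAsFactors = FALSE))
  }

  df <- data.frame(id = id, chrom = chrom, start = start, end = end,
                   svtype = svtype, caller = caller,
                   pe_frac = grab("pe_frac"),
                   sr_frac = grab("sr_frac"),
                   adjusted_p = grab("adjusted_p"),
                   genotype = genotype,
                   stringsAsFactors = FALSE)
  df$sources <- sources
  o <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            sample = as.character(sample),
            origin = as.character(origin),
            class = c("cnv_callset", "data.frame"))
}

#' Empty call set
#' @param sample,origin identifiers for the empty set.
#' @return a zero-row \code{cnv_callset}.
#' @export
empty_callset <- function(sample, origin) {
  cnv_callset(data.frame(chrom = character(), start = numeric(),
                         end = numeric(), svtype = character()),
              sample = sample, origin = origin)
}

#' @export
print.cnv_callset <- function(x, ...) {
  cat(sprintf("CNV call set: %d call(s), sample=%s, origin=%s\n",
              nrow(x), attr(x, "sample"), attr(x, "origin")))
  if (nrow(x)) {
    tab <- table(x$svtype)
    cat("  types: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    show <- utils::head(as.data.frame(x)[c("id", "chrom", "start", "end",
                                           "svtype", "caller")], 6)
    print(show)
    if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more\n")
  }
  invisible(x)
}

#' @export
summary.cnv_callset <- function(object, ...) {
  len <- object$end - object$start
  out <- list(sample = attr(object, "sample"),
              origin = attr(object, "origin"),
              n = nrow(object),
              by_type = table(object$svtype),
              size_quartiles = if (nrow(object)) stats::quantile(len) else NULL)
  class(out) <- "summary.cnv_callset"
  out
}

#' @export
print.summary.cnv_callset <- function(x, ...) {
  cat(sprintf("CNV call set %s / %s: %d calls\n", x$sample, x$origin, x$n))
  if (x$n) {
    print(x$by_type)
    cat("call length quartiles (bp):\n")
    print(x$size_quartiles)
  }
  invisible(x)
}

# subsetting keeps class + attributes; used pervasively by the filters
#' @export
`[.cnv_callset` <- function(x, i, ...) {
  df <- as.data.frame(x)
  out <- df[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, sample = attr(x, "sample"), origin = attr(x, "origin"),
            class = c("cnv_callset", "data.frame"))
}

#' @export
as.data.frame.cnv_callset <- function(x, ...) {
  class(x) <- "data.frame"
  attr(x, "sample") <- NULL
  attr(x, "origin") <- NULL
  x
}

#' @rdname cnv_callset
#' @param x object to test.
#' @export
is_cnv_callset <- function(x) inherits(x, "cnv_callset")

#' @rdname cnv_callset
#' @export
callset_sample <- function(x) attr(x, "sample")

#' @rdname cnv_callset
#' @export
callset_origin <- function(x) attr(x, "origin")

# re-wrap a plain data.frame of call rows as a callset without re-deriving ids
rewrap_callset <- function(df, sample, origin) {
  o <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, sample = sample, origin = origin,
            class = c("cnv_callset", "data.frame"))
}

assert_sorted <- function(x, what = "call set") {
  if (nrow(x) < 2) return(invisible(TRUE))
  o <- order(x$chrom, x$start, x$end, method = "radix")
  if (!identical(o, seq_len(nrow(x))))
    stop(what, " must be sorted by (chrom, start, end)")
  invisible(TRUE)
}

#' Caller profile
#'
#' Identity and signal class of a CNV caller.  The signal class governs
#' which filters apply (the opposite-type "delamp" filter is meaningful
#' only for paired-end/split-read callers; the adjusted-p filter only for
#' coverage callers that expose one) and which callers form a same-signal
#' pair in the intersection-union strategy.  \code{merge_priority} ranks
#' callers for choosing representative coordinates when calls are merged
#' (1 = highest; paired-end callers are base-pair precise so they
#' outrank coverage callers, whose precision is limited by bin size).
#'
#' @param id caller identifier.
#' @param signal_class \code{"paired_end"} or \code{"coverage"}.
#' @param breakpoint_precision_bp typical breakpoint uncertainty in bp
#'   (0 = exact).
#' @param merge_priority integer rank, 1 = preferred.
#' @return a \code{caller_profile} list.
#' @export
caller_profile <- function(id, signal_class = c("paired_end", "coverage"),
                           breakpoint_precision_bp = 0L,
                           merge_priority = 1L) {
  signal_class <- match.arg(signal_class)
  stopifnot(breakpoint_precision_bp >= 0)
  structure(list(id = as.character(id), signal_class = signal_class,
                 breakpoint_precision_bp = as.integer(breakpoint_precision_bp),
                 merge_priority = as.integer(merge_priority)),
            class = "caller_profile")
}

#' @export
print.caller_profile <- function(x, ...) {
  cat(sprintf("caller '%s' (%s signal, +/-%d bp, priority %d)\n",
              x$id, x$signal_class, x$breakpoint_precision_bp,
              x$merge_priority))
  invisible(x)
}

#' Default caller profiles for the four-caller ensemble
#'
#' Manta and Delly are paired-end/split-read callers with base-pair
#' breakpoint precision; ERDS and CNVnator are coverage callers whose
#' precision is tied to their bin size (100 bp).  The default merge
#' priority Manta > Delly > ERDS > CNVnator prefers the precise callers
#' for representative coordinates.
#'
#' @return named list of \code{caller_profile}s.
#' @export
default_caller_profiles <- function() {
  list(
    manta    = caller_profile("manta", "paired_end", 0L, 1L),
    delly    = caller_profile("delly", "paired_end", 0L, 2L),
    erds     = caller_profile("erds", "coverage", 100L, 3L),
    cnvnator = caller_profile("cnvnator", "coverage", 100L, 4L)
  )
}

# priority rank lookup: lower = preferred; unknown callers rank last
priority_rank <- function(caller, profiles = default_caller_profiles()) {
  pr <- vapply(profiles, function(p) p$merge_priority, integer(1))
  names(pr) <- vapply(profiles, function(p) p$id, character(1))
  r <- pr[caller]
  r[is.na(r)] <- max(pr, 0L) + 1L
  unname(r)
}
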