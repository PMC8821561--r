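# Per-call-set filters.  Each filter is contractive (output is a subset of
# the input), idempotent, and returns a FilterReport recording why every
# removed call went.

filter_report <- function(name, calls, keep, reason,
                          not_applicable = character(0)) {
  removed <- data.frame(id = calls$id[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  structure(list(filter = name,
                 n_input = nrow(calls),
                 n_retained = sum(keep),
                 n_removed = sum(!keep),
                 removed = removed,
                 not_applicable = not_applicable),
            class = "cnv_filter_report")
}

#' @export
print.cnv_filter_report <- function(x, ...) {
  cat(sprintf("filter '%s': %d in, %d retained, %d removed",
              x$filter, x$n_input, x$n_retained, x$n_removed))
  if (length(x$not_applicable))
    cat(sprintf(" (%d not applicable, retained)", length(x$not_applicable)))
  cat("\n")
  if (nrow(x$removed)) {
    tab <- table(x$removed$reason)
    cat("  reasons: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.cnv_filter_report <- function(x, ...) {
  data.frame(filter = x$filter, n_input = x$n_input,
             n_retained = x$n_retained, n_removed = x$n_removed,
             stringsAsFactors = FALSE)
}

filter_result <- function(calls, keep, name, reason, not_applicable = character(0)) {
  list(calls = calls[keep, ],
       report = filter_report(name, calls, keep, reason, not_applicable))
}

#' Remove opposite-type duplicated calls ("delamp")
#'
#' A paired-end caller occasionally reports the same locus both as a
#' deletion and as a duplication; a locus carrying both labels is
#' untrustworthy in either.  Every DEL matching a DUP of the same call
#' set at reciprocal overlap \code{ro_min} or above is removed together
#' with its partner, iterating until the output contains no cross-type
#' pair at or above the threshold.  Intended for paired-end caller
#' output (a warning is issued for coverage callers).
#'
#' @param calls single-caller \code{cnv_callset}.
#' @param ro_min reciprocal-overlap threshold (default 0.75).
#' @param profile optional \code{caller_profile} used to warn when the
#'   filter is applied outside its paired-end scope.
#' @return list with the filtered \code{calls} and a \code{report}.
#' @export
filter_delamp <- function(calls, ro_min = 0.75, profile = NULL) {
  stopifnot(is_cnv_callset(calls))
  if (!is.null(profile) && profile$signal_class != "paired_end")
    warning("filter_delamp: intended for paired-end callers; '",
            profile$id, "' is ", profile$signal_class)
  dels <- which(calls$svtype == "DEL")
  dups <- which(calls$svtype == "DUP")
  drop <- logical(nrow(calls))
  if (length(dels) && length(dups)) {
    a <- as.data.frame(calls)[dels, ]; b <- as.data.frame(calls)[dups, ]
    cand <- candidate_pairs(a, b, ro_min, same_type = FALSE)
    # every call participating in ANY cross-type overlap >= ro_min goes;
    # removing all participants (not a matching) makes one pass sufficient
    drop[dels[unique(cand$left)]] <- TRUE
    drop[dups[unique(cand$right)]] <- TRUE
  }
  filter_result(calls, !drop, "delamp",
                rep("opposite_type_overlap", nrow(calls)))
}

#' Filter on read-support fractions
#'
#' Retains a call iff its paired-end or split-read support fraction
#' exceeds \code{min_frac} (strict inequality).  Calls exposing neither
#' fraction are retained and flagged not-applicable: a quality filter
#' should not punish absent metadata.
#'
#' @param calls \code{cnv_callset} carrying \code{pe_frac}/\code{sr_frac}.
#' @param min_frac support-fraction threshold (default 0.3).
#' @return list with \code{calls} and \code{report}.
#' @export
filter_support_fraction <- function(calls, min_frac = 0.3) {
  stopifnot(is_cnv_callset(calls), min_frac >= 0, min_frac <= 1)
  pe <- calls$pe_frac; sr <- calls$sr_frac
  na_both <- is.na(pe) & is.na(sr)
  keep <- na_both | (!is.na(pe) & pe > min_frac) | (!is.na(sr) & sr > min_frac)
  filter_result(calls, keep, "support_fraction",
                rep("support_fraction_low", nrow(calls)),
                not_applicable = calls$id[na_both])
}

#' Filter on adjusted p value
#'
#' Retains a call iff its adjusted p value is below \code{max_p}
#' (coverage callers such as CNVnator expose one).  Calls without an
#' adjusted p are retained and flagged not-applicable.
#'
#' @param calls \code{cnv_callset}.
#' @param max_p exclusive upper bound (default 0.5).
#' @return list with \code{calls} and \code{report}.
#' @export
filter_adjusted_p <- function(calls, max_p = 0.5) {
  stopifnot(is_cnv_callset(calls), max_p >= 0, max_p <= 1)
  p <- calls$adjusted_p
  na <- is.na(p)
  keep <- na | p < max_p
  filter_result(calls, keep, "adjusted_p",
                rep("adjusted_p_high", nrow(calls)),
                not_applicable = calls$id[na])
}

#' Same-signal confirmation filter
#'
#' Retains a call iff it matches (same svtype, greedy one-to-one) a
#' call of the partner set at reciprocal overlap \code{ro_min} or above.
#' The partner should be the other caller of the same signal class
#' (Delly/Manta for paired-end; ERDS/CNVnator for coverage); a warning
#' is issued otherwise when profiles are supplied.
#'
#' @param calls \code{cnv_callset} to filter.
#' @param partner same-sample \code{cnv_callset} from the same-signal
#'   partner caller.
#' @param ro_min reciprocal-overlap threshold (0.5 or 0.75 are the
#'   conventional choices).
#' @param profile,partner_profile optional \code{caller_profile}s for the
#'   signal-class check.
#' @return list with \code{calls} and \code{report}.
#' @export
filter_same_signal_confirmation <- function(calls, partner, ro_min = 0.5,
                                            profile = NULL,
                                            partner_profile = NULL) {
  stopifnot(is_cnv_callset(calls), is_cnv_callset(partner))
  if (!is.null(profile) && !is.null(partner_profile) &&
      profile$signal_class != partner_profile$signal_class)
    warning("filter_same_signal_confirmation: partner '",
            partner_profile$id, "' uses a different signal class")
  m <- match_sets(calls, partner, ro_min = ro_min, same_type = TRUE)
  keep <- logical(nrow(calls))
  keep[m$pairs$left] <- TRUE
  filter_result(calls, keep, "same_signal_confirmation",
                rep("no_partner_match", nrow(calls)))
}

#' Non-reference genotype filter
#'
#' Retains calls whose (regenotyped) genotype is heterozygous or
#' homozygous-alternative.  Homozygous-reference calls are removed, and
#' missing genotypes are removed conservatively and counted separately:
#' a regenotyping filter exists precisely to demand genotype evidence.
#'
#' @param calls \code{cnv_callset} carrying genotypes (e.g. read from an
#'   SV2-regenotyped VCF).  Calls with no genotype at all (\code{NA},
#'   genotyping never attempted) are treated as MISSING.
#' @return list with \code{calls} and \code{report}.
#' @export
filter_genotype_nonref <- function(calls) {
  stopifnot(is_cnv_callset(calls))
  g <- calls$genotype
  g[is.na(g)] <- "MISSING"
  keep <- g %in% c("HET", "HOM_ALT")
  reason <- ifelse(g == "HOM_REF", "hom_ref", "genotype_missing")
  res <- filter_result(calls, keep, "genotype_nonref", reason)
  res$report$n_missing <- sum(g == "MISSING")
  res
}

#' Population allele-frequency filter
#'
#' Removes a call when the maximal allele frequency among population SV
#' records overlapping it at reciprocal overlap \code{ro_min} or above
#' (same svtype when \code{same_type}) exceeds \code{af_max}.  Calls
#' with no qualifying population overlap are retained.
#'
#' @param calls \code{cnv_callset}.
#' @param population an \code{sv_track} from
#'   \code{\link{read_population_sv}}.
#' @param af_max maximum tolerated population allele frequency
#'   (default 0.05).
#' @param ro_min reciprocal-overlap threshold for a qualifying overlap
#'   (default 0.5).
#' @param same_type restrict to same-svtype population records
#'   (default TRUE).
#' @return list with \code{calls} and \code{report}.
#' @export
filter_frequency <- function(calls, population, af_max = 0.05,
                             ro_min = 0.5, same_type = TRUE) {
  stopifnot(is_cnv_callset(calls))
  maxaf <- max_allele_frequency(calls, population, ro_min = ro_min,
                                same_type = same_type)
  keep <- is.na(maxaf) | maxaf <= af_max
  filter_result(calls, keep, "frequency",
                rep("population_af_high", nrow(calls)))
}

#' Size/type rule filter
#'
#' Applies an ordered list of (svtype, size range, keep/drop) rules; the
#' first rule matching a call decides its fate, and calls matching no
#' rule are retained.  The conventional use is dropping large gains
#' (coverage-caller duplications above 50 kb are rarely real), which is
#' why the helper \code{size_rule} exists, but the filter is off unless
#' rules are supplied.
#'
#' @param calls \code{cnv_callset}.
#' @param rules list of \code{size_rule()} entries.
#' @return list with \code{calls} and \code{report}.
#' @export
filter_size_and_type <- function(calls, rules = list()) {
  stopifnot(is_cnv_callset(calls))
  keep <- rep(TRUE, nrow(calls))
  reason <- rep("size_type_rule", nrow(calls))
  decided <- logical(nrow(calls))
  len <- calls$end - calls$start
  for (r in rules) {
    stopifnot(inherits(r, "cnv_size_rule"))
    hit <- !decided & calls$svtype == r$svtype & len >= r$min_size &
      len < r$max_size
    keep[hit] <- r$action == "keep"
    reason[hit] <- sprintf("rule_%s_%s", r$action, r$svtype)
    decided[hit] <- TRUE
  }
  filter_result(calls, keep, "size_and_type", reason)
}

#' @rdname filter_size_and_type
#' @param svtype \code{"DEL"} or \code{"DUP"}.
#' @param min_size,max_size half-open size range in bp the rule covers.
#' @param action \code{"drop"} or \code{"keep"}.
#' @export
size_rule <- function(svtype, min_size = 0, max_size = Inf,
                      action = c("drop", "keep")) {
  action <- match.arg(action)
  stopifnot(svtype %in% SVTYPES)
  if (min_size >= max_size)
    stop("size_rule: min_size must be below max_size")
  structure(list(svtype = svtype, min_size = min_size, max_size = max_size,
                 action = action), class = "cnv_size_rule")
}

#' Region inclusion/exclusion filter
#'
#' Removes (or requires) calls overlapping a genomic track --
#' blacklists, exon sets, and the like.  Overlap here is plain shared
#' bases (\code{min_bp} or more, bedtools-intersect semantics), not
#' reciprocal overlap.
#'
#' @param calls \code{cnv_callset}.
#' @param track an \code{interval_track} (or any data frame with
#'   \code{chrom}, \code{start}, \code{end}).
#' @param mode \code{"exclude_overlapping"} (blacklist semantics) or
#'   \code{"require_overlapping"} (e.g. exonic restriction).
#' @param min_bp minimum shared bases for an overlap (default 1).
#' @return list with \code{calls} and \code{report}.
#' @export
filter_region <- function(calls, track,
                          mode = c("exclude_overlapping",
                                   "require_overlapping"),
                          min_bp = 1) {
  mode <- match.arg(mode)
  stopifnot(is_cnv_callset(calls), min_bp >= 1)
  hits <- overlap_bp_per_call(calls, track)
  overlapping <- hits >= min_bp
  keep <- if (mode == "exclude_overlapping") !overlapping else overlapping
  filter_result(calls, keep, paste0("region_", mode),
                rep(if (mode == "exclude_overlapping") "in_excluded_region"
                    else "outside_required_region", nrow(calls)))
}

# maximum single-record shared bp between each call and the track records
overlap_bp_per_call <- function(calls, track) {
  n <- nrow(calls)
  if (n == 0 || nrow(track) == 0) return(numeric(n))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(calls_gr(calls), calls_gr(track)))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  o <- pmin(calls$end[i], track$end[j]) - pmax(calls$start[i], track$start[j])
  out <- numeric(n)
  if (length(i)) {
    agg <- tapply(o, i, max)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}
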