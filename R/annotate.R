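# Overlap annotation: pure decoration of call sets with genomic tracks and
# population SV references.  Nothing here mutates coordinates or drops calls.

#' Count track overlaps per call
#'
#' Many-to-many count of track records sharing at least \code{min_bp}
#' bases with each call (bedtools-intersect semantics, distinct from the
#' one-to-one reciprocal-overlap matching used for call-to-call
#' comparisons).
#'
#' @param calls \code{cnv_callset}.
#' @param track data frame with \code{chrom}, \code{start}, \code{end}
#'   (an \code{interval_track} or \code{sv_track}).
#' @param min_bp minimum shared bases (default 1).
#' @return integer vector, one count per call (in call-set order).
#' @export
count_overlaps <- function(calls, track, min_bp = 1) {
  stopifnot(is_cnv_callset(calls), min_bp >= 1)
  n <- nrow(calls)
  if (n == 0 || nrow(track) == 0) return(integer(n))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(calls_gr(calls), calls_gr(track)))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  o <- pmin(calls$end[i], track$end[j]) - pmax(calls$start[i], track$start[j])
  i <- i[o >= min_bp]
  out <- integer(n)
  if (length(i)) {
    tab <- table(i)
    out[as.integer(names(tab))] <- as.integer(tab)
  }
  out
}

#' Maximal population allele frequency per call
#'
#' The maximum allele frequency among population SV records overlapping
#' each call at reciprocal overlap \code{ro_min} or above (same svtype
#' when \code{same_type}); \code{NA} when no qualifying record overlaps.
#' Many-to-many: every qualifying population record contributes.
#'
#' @param calls \code{cnv_callset}.
#' @param population an \code{sv_track} with an \code{af} column.
#' @param ro_min reciprocal-overlap threshold (default 0.5).
#' @param same_type restrict to same-svtype records (default TRUE).
#' @return numeric vector of maximal AFs (NA = no qualifying overlap).
#' @export
max_allele_frequency <- function(calls, population, ro_min = 0.5,
                                 same_type = TRUE) {
  stopifnot(is_cnv_callset(calls), !is.null(population$af))
  n <- nrow(calls)
  out <- rep(NA_real_, n)
  if (n == 0 || nrow(population) == 0) return(out)
  cand <- candidate_pairs(as.data.frame(calls), as.data.frame(population),
                          ro_min = ro_min, same_type = same_type)
  cand$af <- population$af[cand$right]
  cand <- cand[!is.na(cand$af), , drop = FALSE]
  if (nrow(cand)) {
    agg <- tapply(cand$af, cand$left, max)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Annotate calls with named genomic tracks
#'
#' For each call and each track, whether the call overlaps the track
#' (at least \code{min_bp} shared bases with some record) and the total
#' shared bases across track records (overlapping track records are
#' counted per record, not flattened).
#'
#' @param calls \code{cnv_callset}.
#' @param tracks named list of interval tracks (duplicate names are a
#'   configuration error).
#' @param min_bp minimum shared bases for the boolean column.
#' @return data frame: \code{id}, then \code{<name>} (logical) and
#'   \code{<name>_bp} (numeric) per track, one row per call.
#' @export
annotate_regions <- function(calls, tracks, min_bp = 1) {
  stopifnot(is_cnv_callset(calls), length(tracks) > 0)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))) ||
      anyDuplicated(names(tracks)))
    stop("annotate_regions: tracks must have unique names")
  out <- data.frame(id = calls$id, stringsAsFactors = FALSE)
  for (nm in names(tracks)) {
    track <- tracks[[nm]]
    bp <- total_overlap_bp(calls, track)
    out[[nm]] <- bp >= min_bp
    out[[paste0(nm, "_bp")]] <- bp
  }
  out
}

# per-call total shared bases with all track records
total_overlap_bp <- function(calls, track) {
  n <- nrow(calls)
  if (n == 0 || nrow(track) == 0) return(numeric(n))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(calls_gr(calls), calls_gr(track)))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  o <- pmin(calls$end[i], track$end[j]) - pmax(calls$start[i], track$start[j])
  out <- numeric(n)
  if (length(i)) {
    agg <- tapply(o, i, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}
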