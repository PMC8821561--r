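# Combination strategies: union, intersection-union, and either followed by
# non-reference regenotype filtering.

#' Strategy configuration
#'
#' Holds the knobs of the combination strategies: which callers form the
#' paired-end and the coverage pair, the reciprocal-overlap threshold of
#' the within-pair intersection (default 0.75), of the final
#' deduplicating union (default 0.5, the conventional sharing
#' threshold), of the delamp pre-filter (default 0.75), and the caller
#' priority used to pick representative coordinates on merge.
#'
#' @param pe_pair character(2): the paired-end callers.
#' @param cov_pair character(2): the coverage callers.
#' @param intersect_ro within-pair intersection threshold.
#' @param dedup_ro union deduplication threshold.
#' @param delamp_ro delamp threshold.
#' @param profiles named list of \code{caller_profile}s supplying merge
#'   priorities.
#' @return a \code{strategy_config}.
#' @export
strategy_config <- function(pe_pair = c("delly", "manta"),
                            cov_pair = c("erds", "cnvnator"),
                            intersect_ro = 0.75, dedup_ro = 0.5,
                            delamp_ro = 0.75,
                            profiles = default_caller_profiles()) {
  callers <- c(pe_pair, cov_pair)
  if (length(callers) != 4 || anyDuplicated(callers))
    stop("strategy_config: need four distinct callers")
  stopifnot(intersect_ro > 0, intersect_ro <= 1,
            dedup_ro > 0, dedup_ro <= 1, delamp_ro > 0, delamp_ro <= 1)
  structure(list(pe_pair = pe_pair, cov_pair = cov_pair,
                 intersect_ro = intersect_ro, dedup_ro = dedup_ro,
                 delamp_ro = delamp_ro, profiles = profiles),
            class = "strategy_config")
}

#' @export
print.strategy_config <- function(x, ...) {
  cat(sprintf(
    "strategy config: PE pair %s; coverage pair %s; intersect RO %.2f; dedup RO %.2f; delamp RO %.2f\n",
    paste(x$pe_pair, collapse = "+"), paste(x$cov_pair, collapse = "+"),
    x$intersect_ro, x$dedup_ro, x$delamp_ro))
  invisible(x)
}

# merge partner rows into representative rows: union provenance, fill
# missing quality fields from the partner
merge_rows <- function(rep_df, partner_df) {
  rep_df$sources <- lapply(seq_len(nrow(rep_df)), function(k) {
    s <- rbind(rep_df$sources[[k]], partner_df$sources[[k]])
    s[!duplicated(s), , drop = FALSE]
  })
  for (col in c("pe_frac", "sr_frac", "adjusted_p")) {
    take <- is.na(rep_df[[col]]) & !is.na(partner_df[[col]])
    rep_df[[col]][take] <- partner_df[[col]][take]
  }
  take <- is.na(rep_df$genotype) & !is.na(partner_df$genotype)
  rep_df$genotype[take] <- partner_df$genotype[take]
  rep_df
}

#' Intersect a caller pair
#'
#' Greedy one-to-one same-type matching of two same-sample call sets at
#' reciprocal overlap \code{ro_min}; one output call per matched pair.
#' Coordinates (and id) come from the higher-merge-priority caller's
#' member; both source calls are recorded in the provenance, and quality
#' fields absent on the representative are carried over from the
#' partner.
#'
#' @param A,B same-sample \code{cnv_callset}s.
#' @param ro_min reciprocal-overlap threshold (default 0.75).
#' @param profiles caller profiles supplying merge priorities.
#' @param origin origin label of the result.
#' @return a \code{cnv_callset}.
#' @export
intersect_pair <- function(A, B, ro_min = 0.75,
                           profiles = default_caller_profiles(),
                           origin = NULL) {
  stopifnot(is_cnv_callset(A), is_cnv_callset(B))
  if (nrow(A) && nrow(B) &&
      !identical(callset_sample(A), callset_sample(B)))
    stop("intersect_pair: call sets from different samples")
  origin <- origin %||%
    paste0("intersect_", callset_origin(A), "_", callset_origin(B))
  m <- match_sets(A, B, ro_min = ro_min, same_type = TRUE)
  if (!nrow(m$pairs)) {
    out <- empty_callset(callset_sample(A), origin)
    return(out)
  }
  a <- as.data.frame(A)[m$pairs$left, , drop = FALSE]
  b <- as.data.frame(B)[m$pairs$right, , drop = FALSE]
  a_first <- priority_rank(a$caller, profiles) <=
    priority_rank(b$caller, profiles)
  rep_df <- a; partner <- b
  rep_df[!a_first, ] <- b[!a_first, ]
  rep_df$sources[!a_first] <- b$sources[!a_first]
  partner[!a_first, ] <- a[!a_first, ]
  partner$sources[!a_first] <- a$sources[!a_first]
  merged <- merge_rows(rep_df, partner)
  rewrap_callset(merged, callset_sample(A), origin)
}

#' Union of call sets with reciprocal-overlap deduplication
#'
#' Joins the calls of several same-sample call sets.  Same-type calls
#' matching at reciprocal overlap \code{dedup_ro} or above are collapsed
#' into one record whose coordinates come from the highest-priority
#' source and whose provenance lists every supporting caller.
#' Collapsing is iterative greedy: the input sets are taken in merge
#' priority order (of their origin caller), and at each step the running
#' merged set is matched against the next set; matched incoming calls
#' are folded into their running representative, unmatched ones are
#' appended.
#'
#' @param callsets list of same-sample \code{cnv_callset}s.
#' @param dedup_ro deduplication threshold (default 0.5).
#' @param profiles caller profiles supplying priorities.
#' @param origin origin label of the result (default \code{"union"}).
#' @return a \code{cnv_callset}.
#' @export
combine_union <- function(callsets, dedup_ro = 0.5,
                          profiles = default_caller_profiles(),
                          origin = "union") {
  if (!length(callsets))
    return(empty_callset("unknown", origin))
  stopifnot(all(vapply(callsets, is_cnv_callset, logical(1))))
  smp <- unique(vapply(callsets, callset_sample, character(1)))
  if (length(smp) > 1)
    stop("combine_union: call sets from different samples")
  ord <- order(vapply(callsets,
                      function(cs) min(priority_rank(callset_origin(cs),
                                                     profiles)),
                      numeric(1)))
  callsets <- callsets[ord]
  running <- as.data.frame(callsets[[1]])
  for (cs in callsets[-1]) {
    cur <- rewrap_callset(running, smp, origin)
    m <- match_sets(cur, cs, ro_min = dedup_ro, same_type = TRUE)
    running <- as.data.frame(cur)
    if (nrow(m$pairs)) {
      inc <- as.data.frame(cs)[m$pairs$right, , drop = FALSE]
      running[m$pairs$left, ] <- merge_rows(
        running[m$pairs$left, , drop = FALSE], inc)
    }
    if (length(m$unmatched_right))
      running <- rbind(running,
                       as.data.frame(cs)[m$unmatched_right, , drop = FALSE])
    running <- running[order(running$chrom, running$start, running$end,
                             method = "radix"), , drop = FALSE]
  }
  rewrap_callset(running, smp, origin)
}

#' Intersection-union combination
#'
#' The two-pool strategy: delamp-filter each paired-end caller's set,
#' intersect the paired-end pair and the coverage pair separately at
#' \code{cfg$intersect_ro}, then join the two pools with a deduplicating
#' union at \code{cfg$dedup_ro}.  Every output call therefore carries
#' provenance from both members of at least one same-signal pair.
#'
#' @param callsets named list of four same-sample \code{cnv_callset}s;
#'   names (or origins) must cover \code{cfg$pe_pair} and
#'   \code{cfg$cov_pair}.
#' @param cfg a \code{strategy_config}.
#' @return list with \code{calls} (the combined \code{cnv_callset}) and
#'   \code{reports} (delamp \code{FilterReport}s and stage counts).
#' @export
combine_intersection_union <- function(callsets, cfg = strategy_config()) {
  stopifnot(inherits(cfg, "strategy_config"))
  sets <- named_callsets(callsets, c(cfg$pe_pair, cfg$cov_pair))
  d1 <- filter_delamp(sets[[cfg$pe_pair[1]]], ro_min = cfg$delamp_ro,
                      profile = cfg$profiles[[cfg$pe_pair[1]]])
  d2 <- filter_delamp(sets[[cfg$pe_pair[2]]], ro_min = cfg$delamp_ro,
                      profile = cfg$profiles[[cfg$pe_pair[2]]])
  pe_pool <- intersect_pair(d1$calls, d2$calls, ro_min = cfg$intersect_ro,
                            profiles = cfg$profiles, origin = "pe_pool")
  cov_pool <- intersect_pair(sets[[cfg$cov_pair[1]]], sets[[cfg$cov_pair[2]]],
                             ro_min = cfg$intersect_ro,
                             profiles = cfg$profiles, origin = "cov_pool")
  out <- combine_union(list(pe_pool, cov_pool), dedup_ro = cfg$dedup_ro,
                       profiles = cfg$profiles,
                       origin = "intersection_union")
  list(calls = out,
       reports = list(delamp = list(d1$report, d2$report),
                      stage_counts = c(pe_pool = nrow(pe_pool),
                                       cov_pool = nrow(cov_pool),
                                       combined = nrow(out))))
}

named_callsets <- function(callsets, wanted) {
  if (is.null(names(callsets)) || any(!nzchar(names(callsets))))
    names(callsets) <- vapply(callsets, callset_origin, character(1))
  miss <- setdiff(wanted, names(callsets))
  if (length(miss))
    stop("missing call set(s) for caller(s): ", paste(miss, collapse = ", "))
  callsets[wanted]
}

#' Run a named combination strategy
#'
#' Compositions: \code{"union"} = deduplicating union of the four sets;
#' \code{"intersection_union"} = the two-pool strategy; the \code{_sv2}
#' variants additionally end with the non-reference genotype filter,
#' taking genotypes from an externally regenotyped call set (matched to
#' the candidates by id, falling back to best same-type reciprocal
#' overlap at 0.9).  Candidates with no genotype in the regenotyped set
#' count as MISSING and are removed.
#'
#' @param name one of \code{"union"}, \code{"intersection_union"},
#'   \code{"union_sv2"}, \code{"intersection_union_sv2"}.
#' @param callsets named list of the four per-caller call sets.
#' @param cfg a \code{strategy_config}.
#' @param genotyped regenotyped \code{cnv_callset} (required for the
#'   \code{_sv2} variants).
#' @return list with \code{calls} and \code{reports}.
#' @export
run_strategy <- function(name = c("union", "intersection_union",
                                  "union_sv2", "intersection_union_sv2"),
                         callsets, cfg = strategy_config(),
                         genotyped = NULL) {
  name <- match.arg(name)
  with_sv2 <- grepl("_sv2$", name)
  if (with_sv2 && is.null(genotyped))
    stop("run_strategy: strategy '", name,
         "' requires a regenotyped call set")
  base <- sub("_sv2$", "", name)
  if (base == "union") {
    sets <- named_callsets(callsets, c(cfg$pe_pair, cfg$cov_pair))
    calls <- combine_union(sets, dedup_ro = cfg$dedup_ro,
                           profiles = cfg$profiles)
    reports <- list(stage_counts = c(combined = nrow(calls)))
  } else {
    res <- combine_intersection_union(callsets, cfg)
    calls <- res$calls; reports <- res$reports
  }
  if (with_sv2) {
    calls <- assign_genotypes(calls, genotyped)
    gt <- filter_genotype_nonref(calls)
    calls <- gt$calls
    reports$genotype <- gt$report
  }
  attr(calls, "origin") <- name
  list(calls = calls, reports = reports)
}

#' Transfer genotypes from a regenotyped call set
#'
#' Matches candidate calls to a regenotyped call set by id, then by best
#' same-type reciprocal overlap (at 0.9 or above) for candidates whose
#' ids the regenotyper rewrote.  Unmatched candidates get genotype
#' \code{MISSING}.
#'
#' @param calls candidate \code{cnv_callset}.
#' @param genotyped regenotyped \code{cnv_callset}.
#' @return \code{calls} with the \code{genotype} column filled.
#' @export
assign_genotypes <- function(calls, genotyped) {
  stopifnot(is_cnv_callset(calls), is_cnv_callset(genotyped))
  df <- as.data.frame(calls)
  j <- match(df$id, genotyped$id)
  df$genotype <- ifelse(is.na(j), NA_character_, genotyped$genotype[j])
  rest <- which(is.na(j))
  if (length(rest)) {
    m <- match_sets(rewrap_callset(df[rest, , drop = FALSE],
                                   callset_sample(calls), "candidates"),
                    genotyped, ro_min = 0.9, same_type = TRUE)
    df$genotype[rest[m$pairs$left]] <- genotyped$genotype[m$pairs$right]
  }
  df$genotype[is.na(df$genotype)] <- "MISSING"
  rewrap_callset(df, callset_sample(calls), callset_origin(calls))
}
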