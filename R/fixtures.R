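# Emitting caller-dialect VCFs from simulated call sets.  These writers
# exist so the dialect readers can be exercised offline on realistic input:
# each one encodes the fields the corresponding reader expects.

#' Write a call set in a caller's VCF dialect
#'
#' Emits the dialect the matching reader consumes: \code{delly} encodes
#' support fractions as FORMAT \code{DV}/\code{DR}/\code{RV}/\code{RR}
#' integer counts (scaled to 20 reads), \code{manta} as FORMAT
#' \code{PR}/\code{SR} (ref, alt) pairs, \code{cnvnator} carries the
#' adjusted p value in INFO \code{natorP2}, \code{erds}/\code{generic}
#' plain SVTYPE/END records.  POS = internal start, END = internal end.
#'
#' @param calls a \code{cnv_callset}.
#' @param path output file.
#' @param dialect dialect name.
#' @return \code{path}, invisibly.
#' @export
write_caller_vcf <- function(calls, path,
                             dialect = c("delly", "manta", "cnvnator",
                                         "erds", "generic")) {
  dialect <- match.arg(dialect)
  stopifnot(is_cnv_callset(calls))
  smp <- callset_sample(calls)
  n <- nrow(calls)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(calls$chrom)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">")
  info <- sprintf("SVTYPE=%s;END=%.15g", calls$svtype, calls$end)
  format_col <- NULL; sample_col <- NULL
  if (dialect == "delly") {
    header <- c(header,
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DR,Number=1,Type=Integer,Description=\"Reference pairs\">",
      "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"Variant pairs\">",
      "##FORMAT=<ID=RR,Number=1,Type=Integer,Description=\"Reference junction reads\">",
      "##FORMAT=<ID=RV,Number=1,Type=Integer,Description=\"Variant junction reads\">")
    depth <- 20
    dv <- ifelse(is.na(calls$pe_frac), 0, round(depth * calls$pe_frac))
    rv <- ifelse(is.na(calls$sr_frac), 0, round(depth * calls$sr_frac))
    format_col <- rep("GT:DR:DV:RR:RV", n)
    sample_col <- sprintf("%s:%d:%d:%d:%d", genotype_to_gt(calls$genotype),
                          depth - dv, dv, depth - rv, rv)
  } else if (dialect == "manta") {
    header <- c(header,
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=PR,Number=.,Type=Integer,Description=\"Paired-read support for ref,alt\">",
      "##FORMAT=<ID=SR,Number=.,Type=Integer,Description=\"Split-read support for ref,alt\">")
    depth <- 20
    pr <- ifelse(is.na(calls$pe_frac), 0, round(depth * calls$pe_frac))
    srr <- ifelse(is.na(calls$sr_frac), 0, round(depth * calls$sr_frac))
    format_col <- rep("GT:PR:SR", n)
    sample_col <- sprintf("%s:%d,%d:%d,%d", genotype_to_gt(calls$genotype),
                          depth - pr, pr, depth - srr, srr)
  } else {
    if (dialect == "cnvnator") {
      header <- c(header,
        "##INFO=<ID=natorP2,Number=1,Type=Float,Description=\"e-val by t-test (adjusted)\">")
      has <- !is.na(calls$adjusted_p)
      info[has] <- sprintf("%s;natorP2=%.6g", info[has], calls$adjusted_p[has])
    }
    header <- c(header,
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    format_col <- rep("GT", n)
    sample_col <- genotype_to_gt(calls$genotype)
  }
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  body <- if (n) sprintf("%s\t%.15g\t%s\tN\t<%s>\t.\tPASS\t%s",
                         calls$chrom, calls$start, calls$id, calls$svtype,
                         info) else character(0)
  if (!is.null(format_col)) {
    cols <- c(cols, "FORMAT", smp)
    if (n) body <- paste0(body, "\t", format_col, "\t", sample_col)
  }
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Write a simulated cohort sample to disk
#'
#' Emits per-caller VCFs in their native dialects, one labels TSV per
#' caller, and the truth set as BED -- a complete labeled fixture for an
#' offline pipeline run.
#'
#' @param cohort result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_simulated_fixtures <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (nm in names(cohort$callsets)) {
    dialect <- if (nm %in% c("delly", "manta", "cnvnator", "erds")) nm
               else "generic"
    p <- file.path(dir, paste0(nm, ".vcf"))
    write_caller_vcf(cohort$callsets[[nm]], p, dialect)
    lp <- file.path(dir, paste0(nm, ".labels.tsv"))
    write_labels(cohort$labels[[nm]], lp)
    paths[[nm]] <- c(vcf = p, labels = lp)
  }
  tp <- file.path(dir, "truth.bed")
  write_callset(cohort$truth, tp, "bed")
  paths$truth <- c(bed = tp)
  invisible(paths)
}

#' Run manifest
#'
#' Machine-readable record of a pipeline stage: inputs, thresholds, and
#' counts per stage, written as JSON.
#'
#' @param stage stage name.
#' @param inputs named character vector of input paths/ids.
#' @param params named list of thresholds and flags.
#' @param counts named numeric vector of per-stage call counts.
#' @param path optional JSON output path.
#' @return the manifest list, invisibly when written.
#' @export
run_manifest <- function(stage, inputs = character(0), params = list(),
                         counts = numeric(0), path = NULL) {
  manifest <- list(tool = "cnv-ensemble",
                   version = as.character(utils::packageVersion("cnvensemble")),
                   stage = stage, inputs = as.list(inputs),
                   params = params, counts = as.list(counts))
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
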