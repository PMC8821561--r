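# Reading caller-specific VCF/BED dialects and writing normalized call sets.
#
# Coordinate convention at the VCF boundary: internal start = VCF POS and
# internal end = INFO END, so internal length = END - POS.  This matches the
# span a bedtools-style vcf-to-bed conversion produces for symbolic SV
# records, keeping reciprocal-overlap arithmetic consistent across sources.
# The conversion is a bijection: writing uses POS = start, END = end.

#' Describe a caller's VCF dialect
#'
#' A dialect tells the reader where a caller stores the fields the
#' toolkit needs: the svtype (INFO \code{SVTYPE} or the symbolic ALT),
#' the end coordinate (INFO \code{END}, or \code{POS + |SVLEN|} as a
#' fallback), how read-support is encoded, and which INFO key carries an
#' adjusted p value, if any.
#'
#' Support styles:
#' \describe{
#'   \item{\code{"none"}}{no support fields.}
#'   \item{\code{"delly"}}{FORMAT \code{DV}/\code{DR} (variant/reference
#'     read pairs) and \code{RV}/\code{RR} (variant/reference junction
#'     reads); fractions are computed as \code{DV/(DV+DR)} and
#'     \code{RV/(RV+RR)}, absent when the denominator is 0 or the fields
#'     are missing.}
#'   \item{\code{"manta"}}{FORMAT \code{PR} and \code{SR}, each a
#'     (ref, alt) count pair; fraction = alt/(ref+alt).}
#'   \item{\code{"native"}}{this package's own output: INFO \code{PEF}/
#'     \code{SRF} fractions, \code{PADJ}, and \code{CALLERS}/
#'     \code{SOURCES} provenance.}
#' }
#'
#' @param caller caller id recorded on the calls.
#' @param support one of \code{"none"}, \code{"delly"}, \code{"manta"},
#'   \code{"native"}.
#' @param padj_key INFO key holding an adjusted p value, or \code{NULL}.
#' @param genotypes read per-sample GT when present (default TRUE).
#' @return a \code{dialect_spec} list.
#' @export
dialect_spec <- function(caller,
                         support = c("none", "delly", "manta", "native"),
                         padj_key = NULL, genotypes = TRUE) {
  support <- match.arg(support)
  structure(list(caller = as.character(caller), support = support,
                 padj_key = padj_key, genotypes = isTRUE(genotypes)),
            class = "dialect_spec")
}

#' Built-in dialects for the four-caller ensemble
#'
#' \code{delly} and \code{manta} read their FORMAT-level read-support
#' encodings; \code{cnvnator} reads the \code{natorP2} INFO key as the
#' adjusted p value; \code{erds} and \code{generic} read plain
#' SVTYPE/END records; \code{native} round-trips this package's own
#' output including provenance.
#'
#' @param name one of \code{"delly"}, \code{"manta"}, \code{"cnvnator"},
#'   \code{"erds"}, \code{"generic"}, \code{"native"}.
#' @return a \code{dialect_spec}.
#' @export
builtin_dialect <- function(name = c("delly", "manta", "cnvnator", "erds",
                                     "generic", "native")) {
  name <- match.arg(name)
  switch(name,
    delly    = dialect_spec("delly", support = "delly"),
    manta    = dialect_spec("manta", support = "manta"),
    cnvnator = dialect_spec("cnvnator", support = "none",
                            padj_key = "natorP2"),
    erds     = dialect_spec("erds", support = "none"),
    generic  = dialect_spec("generic", support = "none"),
    native   = dialect_spec("native", support = "native")
  )
}

# pull an INFO column as a plain numeric/character vector (handles *List)
info_vec <- function(inf, key, n, mode = "numeric") {
  if (!key %in% names(inf))
    return(rep(if (mode == "numeric") NA_real_ else NA_character_, n))
  col <- inf[[key]]
  if (methods::is(col, "List") || is.list(col)) {
    col <- vapply(as.list(col), function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) if (mode == "numeric") NA_real_ else NA_character_
      else if (mode == "numeric") max(as.numeric(v)) else as.character(v[1])
    }, if (mode == "numeric") numeric(1) else character(1))
  }
  if (mode == "numeric") as.numeric(col) else as.character(col)
}

# (ref, alt) count pair lists -> alt fraction
pair_frac <- function(col, n) {
  if (is.null(col)) return(rep(NA_real_, n))
  vapply(seq_len(n), function(i) {
    v <- suppressWarnings(as.numeric(unlist(col[i])))
    v <- v[!is.na(v)]
    if (length(v) < 2 || sum(v[1:2]) == 0) NA_real_ else v[2] / (v[1] + v[2])
  }, numeric(1))
}

gt_to_genotype <- function(gt) {
  gt <- gsub("\\|", "/", gt)
  out <- rep(NA_character_, length(gt))
  out[gt %in% c("0/0")] <- "HOM_REF"
  out[gt %in% c("0/1", "1/0")] <- "HET"
  out[gt %in% c("1/1")] <- "HOM_ALT"
  out[gt %in% c("./.", ".")] <- "MISSING"
  out
}

genotype_to_gt <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == "HOM_REF"] <- "0/0"
  out[!is.na(g) & g == "HET"] <- "0/1"
  out[!is.na(g) & g == "HOM_ALT"] <- "1/1"
  out
}

# list of per-record character vectors for a Number=. INFO key
info_strlist <- function(inf, key, n) {
  if (!key %in% names(inf)) return(rep(list(character(0)), n))
  col <- inf[[key]]
  if (methods::is(col, "List") || is.list(col))
    lapply(as.list(col), as.character)
  else as.list(as.character(col))
}

decode_sources <- function(s) {
  # "caller|chrom|start|end" entries (comma-separated when in one string)
  parts <- strsplit(unlist(strsplit(s, ",", fixed = TRUE)), "|", fixed = TRUE)
  data.frame(caller = vapply(parts, `[`, "", 1),
             chrom = vapply(parts, `[`, "", 2),
             start = as.numeric(vapply(parts, `[`, "", 3)),
             end = as.numeric(vapply(parts, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

encode_sources <- function(src) {
  paste(sprintf("%s|%s|%.15g|%.15g", src$caller, src$chrom, src$start,
                src$end), collapse = ",")
}

#' Read a caller VCF into a call set
#'
#' Parses a (possibly caller-specific) SV VCF and returns the DEL/DUP
#' calls as a \code{cnv_callset}.  Records of other svtypes, records
#' with no resolvable end coordinate and records below the minimum SV
#' size are skipped and counted (or abort the read when
#' \code{strict = TRUE}); the skip counts are attached as attribute
#' \code{"skipped"}.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param dialect a \code{dialect_spec} or a built-in dialect name.
#' @param sample sample to read genotypes for; defaults to the first
#'   sample column.  A named sample absent from the file is a hard
#'   error.
#' @param origin origin recorded on the call set (default: the dialect's
#'   caller id).
#' @param strict abort on skippable records instead of counting them.
#' @param min_size minimum call length in bp.
#' @param strip_chr normalize contig names by dropping a "chr" prefix.
#' @return a \code{cnv_callset}.
#' @export
read_caller_vcf <- function(path, dialect = "generic", sample = NULL,
                            origin = NULL, strict = FALSE,
                            min_size = MIN_SV_SIZE, strip_chr = TRUE) {
  if (is.character(dialect)) dialect <- builtin_dialect(dialect)
  stopifnot(inherits(dialect, "dialect_spec"))
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  n <- length(rr)
  inf <- VariantAnnotation::info(v)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- as.numeric(GenomicRanges::start(rr))  # 1-based VCF POS
  ids <- names(rr)

  svtype <- info_vec(inf, "SVTYPE", n, "character")
  alt <- if (n) vapply(seq_len(n), function(i) {
    a <- rr$ALT[[i]]
    if (length(a)) as.character(a[1]) else NA_character_
  }, character(1)) else character(0)
  from_alt <- toupper(gsub("[<>]", "", alt))
  svtype[is.na(svtype) & from_alt %in% SVTYPES] <- from_alt[is.na(svtype) &
                                                            from_alt %in% SVTYPES]

  end <- info_vec(inf, "END", n)
  svlen <- info_vec(inf, "SVLEN", n)
  no_end <- is.na(end) & !is.na(svlen)
  end[no_end] <- pos[no_end] + abs(svlen[no_end])

  skipped <- c(bad_svtype = 0L, no_end = 0L, too_small = 0L)
  keep <- rep(TRUE, n)
  bad_type <- is.na(svtype) | !(svtype %in% SVTYPES)
  skipped["bad_svtype"] <- sum(bad_type); keep[bad_type] <- FALSE
  bad_end <- !bad_type & is.na(end)
  if (any(bad_end) && strict)
    stop("read_caller_vcf: record(s) with no resolvable END/SVLEN: ",
         paste(utils::head(ids[bad_end], 3), collapse = ", "))
  skipped["no_end"] <- sum(bad_end); keep[bad_end] <- FALSE
  small <- keep & (end - pos < min_size)
  if (any(small) && strict)
    stop("read_caller_vcf: record(s) below the minimum SV size")
  skipped["too_small"] <- sum(small); keep[small] <- FALSE

  # support fields
  pe <- rep(NA_real_, n); sr <- rep(NA_real_, n)
  g <- VariantAnnotation::geno(v)
  samples_in <- colnames(g$GT %||% matrix(nrow = 0, ncol = 0))
  pick_sample <- function() {
    if (is.null(sample)) return(1L)
    j <- match(sample, samples_in)
    if (is.na(j))
      stop("read_caller_vcf: sample '", sample, "' not present in ", path)
    j
  }
  if (dialect$support == "delly" && all(c("DV", "DR") %in% names(g))) {
    j <- pick_sample()
    dv <- as.numeric(g$DV[, j]); dr <- as.numeric(g$DR[, j])
    pe <- ifelse(!is.na(dv) & !is.na(dr) & dv + dr > 0, dv / (dv + dr), NA_real_)
    if (all(c("RV", "RR") %in% names(g))) {
      rv <- as.numeric(g$RV[, j]); rrf <- as.numeric(g$RR[, j])
      sr <- ifelse(!is.na(rv) & !is.na(rrf) & rv + rrf > 0, rv / (rv + rrf),
                   NA_real_)
    }
  } else if (dialect$support == "manta") {
    j <- pick_sample()
    if ("PR" %in% names(g)) pe <- pair_frac(g$PR[, j], n)
    if ("SR" %in% names(g)) sr <- pair_frac(g$SR[, j], n)
  } else if (dialect$support == "native") {
    pe <- info_vec(inf, "PEF", n)
    sr <- info_vec(inf, "SRF", n)
  }

  padj <- rep(NA_real_, n)
  if (dialect$support == "native") padj <- info_vec(inf, "PADJ", n)
  if (!is.null(dialect$padj_key)) padj <- info_vec(inf, dialect$padj_key, n)

  genotype <- rep(NA_character_, n)
  if (dialect$genotypes && "GT" %in% names(g) && ncol(g$GT) > 0) {
    j <- pick_sample()
    genotype <- gt_to_genotype(as.character(g$GT[, j]))
  }
  smp <- if (!is.null(sample)) sample
         else if (length(samples_in)) samples_in[1] else "unknown"

  sources <- NULL
  caller <- rep(dialect$caller, n)
  if (dialect$support == "native" && "SOURCES" %in% names(inf)) {
    srcs <- info_strlist(inf, "SOURCES", n)
    sources <- lapply(srcs, decode_sources)
    cl <- info_strlist(inf, "CALLERS", n)
    caller <- vapply(cl, function(v)
      if (length(v)) v[1] else dialect$caller, character(1))
  }

  df <- data.frame(id = ids, chrom = chrom, start = pos, end = end,
                   svtype = svtype, caller = caller, pe_frac = pe,
                   sr_frac = sr, adjusted_p = padj, genotype = genotype,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (!is.null(sources)) df$sources <- sources[keep]
  out <- cnv_callset(df, sample = smp,
                     origin = origin %||% dialect$caller,
                     min_size = min_size, strip_chr = strip_chr)
  attr(out, "skipped") <- skipped
  if (sum(skipped) > 0)
    message("read_caller_vcf: skipped ", sum(skipped), " record(s) (",
            paste(names(skipped), skipped, sep = "=", collapse = ", "), ")")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read calls or an interval track from BED
#'
#' BED is 0-based half-open, matching the internal convention; no
#' coordinate shift is applied.  With \code{svtype_col} set, the named
#' column supplies DEL/DUP labels and a \code{cnv_callset} is returned;
#' without it a plain interval track (data frame \code{chrom},
#' \code{start}, \code{end} of class \code{interval_track}) is returned.
#'
#' @param path BED file (3+ columns, tab-separated, no header; track
#'   and browser lines are ignored).
#' @param svtype_col 1-based column index of the svtype label, or
#'   \code{NULL}.
#' @param sample,origin identifiers for the resulting call set.
#' @param min_size minimum call length when building a call set.
#' @param strip_chr normalize contig names.
#' @return a \code{cnv_callset} or an \code{interval_track}.
#' @export
read_bed_calls <- function(path, svtype_col = NULL, sample = "unknown",
                           origin = "bed", min_size = MIN_SV_SIZE,
                           strip_chr = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) {
    if (is.null(svtype_col))
      return(structure(data.frame(chrom = character(), start = numeric(),
                                  end = numeric()),
                       class = c("interval_track", "data.frame")))
    return(empty_callset(sample, origin))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3) stop("read_bed_calls: fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("read_bed_calls: non-numeric coordinates at line ", bad[1])
  bad <- which(end <= start)
  if (length(bad))
    stop("read_bed_calls: end <= start at line ", bad[1])
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  if (is.null(svtype_col)) {
    df <- data.frame(chrom = chrom, start = start, end = end,
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start, df$end, method = "radix"), ]
    rownames(df) <- NULL
    return(structure(df, class = c("interval_track", "data.frame")))
  }
  if (svtype_col > ncol_min)
    stop("read_bed_calls: svtype_col beyond available columns")
  svtype <- vapply(fields, `[`, "", svtype_col)
  cnv_callset(data.frame(chrom = chrom, start = start, end = end,
                         svtype = svtype, stringsAsFactors = FALSE),
              sample = sample, origin = origin, min_size = min_size,
              strip_chr = FALSE)
}

#' Read a population SV reference with allele frequencies
#'
#' Loads a gnomAD-SV-style reference: DEL/DUP records with population
#' allele frequencies, used by the frequency filter and the maximal-AF
#' annotation.  VCF input takes the AF from \code{af_field} (list-valued
#' multi-allelic AFs are collapsed to their maximum); BED input takes
#' svtype and AF from the given column indices.  Records without an AF
#' keep \code{NA}; a file in which \code{af_field} resolves nowhere is a
#' configuration error.
#'
#' @param path VCF or BED file (sniffed by extension: \code{.vcf[.gz]}
#'   vs anything else).
#' @param af_field INFO key (VCF) holding the allele frequency.
#' @param svtype_col,af_col column indices for BED input.
#' @param strip_chr normalize contig names.
#' @return an \code{sv_track}: data frame \code{chrom}, \code{start},
#'   \code{end}, \code{svtype}, \code{af}, sorted.
#' @export
read_population_sv <- function(path, af_field = "AF", svtype_col = 4,
                               af_col = 5, strip_chr = TRUE) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) {
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    n <- length(rr)
    inf <- VariantAnnotation::info(v)
    if (!af_field %in% names(inf))
      stop("read_population_sv: INFO field '", af_field, "' not declared in ",
           path)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    if (strip_chr) chrom <- sub("^chr", "", chrom)
    start <- as.numeric(GenomicRanges::start(rr))
    svtype <- info_vec(inf, "SVTYPE", n, "character")
    end <- info_vec(inf, "END", n)
    af <- info_vec(inf, af_field, n)
    if (n > 0 && all(is.na(af)))
      stop("read_population_sv: '", af_field, "' resolves in no record")
    keep <- svtype %in% SVTYPES & !is.na(end)
    df <- data.frame(chrom = chrom, start = start, end = end,
                     svtype = svtype, af = af,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (length(fields) && min(lengths(fields)) < max(svtype_col, af_col))
      stop("read_population_sv: BED lacks the configured svtype/AF columns")
    chrom <- vapply(fields, `[`, "", 1)
    if (strip_chr) chrom <- sub("^chr", "", chrom)
    df <- data.frame(chrom = chrom,
                     start = as.numeric(vapply(fields, `[`, "", 2)),
                     end = as.numeric(vapply(fields, `[`, "", 3)),
                     svtype = toupper(vapply(fields, `[`, "", svtype_col)),
                     af = suppressWarnings(
                       as.numeric(vapply(fields, `[`, "", af_col))),
                     stringsAsFactors = FALSE)
    if (nrow(df) > 0 && all(is.na(df$af)))
      stop("read_population_sv: AF column resolves in no record")
    df <- df[df$svtype %in% SVTYPES, , drop = FALSE]
  }
  df <- df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("sv_track", "data.frame"))
}

#' Write a call set to VCF, BED or TSV
#'
#' VCF output (the package's native dialect) uses symbolic ALTs
#' (\code{<DEL>}/\code{<DUP>}), \code{POS = start}, INFO \code{END},
#' \code{SVTYPE}, \code{CALLERS} (all supporting callers) and
#' \code{SOURCES} (per-source intervals), plus \code{PEF}/\code{SRF}/
#' \code{PADJ} where set, and a GT column when any call carries a
#' genotype.  Reading the file back with the \code{"native"} dialect
#' reproduces intervals, svtypes and provenance exactly.  BED output is
#' a documented lossy subset (\code{chrom start end id svtype caller});
#' TSV carries all scalar columns plus encoded provenance.
#'
#' @param calls a \code{cnv_callset}.
#' @param path output file.
#' @param format \code{"vcf"}, \code{"bed"} or \code{"tsv"} (default:
#'   from the file extension).
#' @return \code{path}, invisibly.
#' @export
write_callset <- function(calls, path, format = NULL) {
  stopifnot(is_cnv_callset(calls))
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     vcf = "vcf", bed = "bed", tsv = "tsv",
                     stop("write_callset: cannot infer format from '", path, "'"))
  format <- match.arg(tolower(format), c("vcf", "bed", "tsv"))
  n <- nrow(calls)
  if (format == "bed") {
    lines <- if (n) sprintf("%s\t%.15g\t%.15g\t%s\t%s\t%s", calls$chrom,
                            calls$start, calls$end, calls$id, calls$svtype,
                            calls$caller) else character(0)
    writeLines(lines, path)
    return(invisible(path))
  }
  if (format == "tsv") {
    enc <- vapply(calls$sources, encode_sources, character(1))
    df <- as.data.frame(calls)
    df$sources <- enc
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  # native VCF
  smp <- callset_sample(calls)
  num <- function(x) ifelse(is.na(x), NA, sprintf("%.10g", x))
  info <- sprintf("SVTYPE=%s;END=%.15g;CALLERS=%s;SOURCES=%s",
                  calls$svtype, calls$end,
                  vapply(calls$sources,
                         function(s) paste(unique(s$caller), collapse = ","),
                         character(1)),
                  vapply(calls$sources, encode_sources, character(1)))
  add <- function(info, key, val) {
    has <- !is.na(val)
    info[has] <- paste0(info[has], ";", key, "=", val[has])
    info
  }
  info <- add(info, "PEF", num(calls$pe_frac))
  info <- add(info, "SRF", num(calls$sr_frac))
  info <- add(info, "PADJ", num(calls$adjusted_p))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(calls$chrom)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (POS-based span, length = END - POS)\">",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Supporting callers\">",
    "##INFO=<ID=SOURCES,Number=.,Type=String,Description=\"Provenance caller|chrom|start|end entries (internal half-open coordinates)\">",
    "##INFO=<ID=PEF,Number=1,Type=Float,Description=\"Paired-end support fraction\">",
    "##INFO=<ID=SRF,Number=1,Type=Float,Description=\"Split-read support fraction\">",
    "##INFO=<ID=PADJ,Number=1,Type=Float,Description=\"Adjusted p value\">"
  )
  with_gt <- any(!is.na(calls$genotype))
  if (with_gt)
    header <- c(header,
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (with_gt) cols <- c(cols, "FORMAT", smp)
  body <- if (n) {
    line <- sprintf("%s\t%.15g\t%s\tN\t<%s>\t.\tPASS\t%s", calls$chrom,
                    calls$start, calls$id, calls$svtype, info)
    if (with_gt)
      line <- paste0(line, "\tGT\t", genotype_to_gt(calls$genotype))
    line
  } else character(0)
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}
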