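#' @importFrom GenomicRanges GRanges findOverlaps seqnames start
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom VariantAnnotation readVcf info geno
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom jsonlite write_json
#' @importFrom stats runif rnorm rpois rbeta quantile setNames
#' @importFrom utils head read.table write.table packageVersion
#' @importFrom methods is
NULL
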