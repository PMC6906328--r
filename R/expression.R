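#' Build an expression SummarizedExperiment
#'
#' Wraps a genes-by-samples abundance matrix (TPM-like, non-negative) in a
#' [SummarizedExperiment::SummarizedExperiment] whose `colData` carries the
#' sampling design: one `subject` and one `timepoint` per column. Each
#' (subject, timepoint) pair must be unique — the design is one sample per
#' subject per timepoint, as in a longitudinal blood-draw series.
#'
#' @param values numeric matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns; all values must be non-negative and finite.
#' @param subject character vector, one subject id per column.
#' @param timepoint character vector, one timepoint label per column.
#' @return A `SummarizedExperiment` with assay `abundance`, column names
#'   `<subject>_<timepoint>`.
#' @examples
#' m <- matrix(rlnorm(12), 3, 4,
#'             dimnames = list(c("g1", "g2", "g3"), NULL))
#' se <- ExpressionSE(m, rep(c("case", "ctrl"), each = 2),
#'                    rep(c("t1", "t2"), 2))
#' SummarizedExperiment::colData(se)
#' @export
ExpressionSE <- function(values, subject, timepoint) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("expression matrix needs gene ids as rownames")
    if (anyDuplicated(rownames(values)))
        stop("duplicate gene ids in expression matrix")
    if (any(!is.finite(values)) || any(values < 0))
        stop("expression values must be finite and non-negative")
    if (length(subject) != ncol(values) || length(timepoint) != ncol(values))
        stop("subject and timepoint must have one entry per sample column")
    key <- paste(subject, timepoint, sep = "_")
    if (anyDuplicated(key))
        stop("each (subject, timepoint) pair must be unique")
    colnames(values) <- key
    SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = values),
        colData = S4Vectors::DataFrame(subject = as.character(subject),
                                       timepoint = as.character(timepoint),
                                       row.names = key))
}

## column index of a (subject, timepoint) cell; errors on unknown keys
sampleColumn <- function(se, subject, timepoint) {
    cd <- SummarizedExperiment::colData(se)
    idx <- which(cd$subject == subject & cd$timepoint == timepoint)
    if (length(idx) != 1L)
        stop(sprintf("no unique sample for subject '%s' at timepoint '%s'",
                     subject, timepoint))
    idx
}

#' Extract one sample's abundance vector
#'
#' @param se expression `SummarizedExperiment` from [ExpressionSE()].
#' @param subject,timepoint the sample key.
#' @return Named numeric vector of abundances (names = gene ids).
#' @export
sampleValues <- function(se, subject, timepoint) {
    m <- SummarizedExperiment::assay(se, "abundance")
    v <- m[, sampleColumn(se, subject, timepoint), drop = FALSE]
    setNames(as.numeric(v), rownames(m))
}
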