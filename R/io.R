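#' Read an expression TSV
#'
#' Format: header `gene_id<TAB><subject>_<timepoint>...`, one row per gene.
#' The subject/timepoint design is recovered by splitting each sample
#' column name at the last underscore.
#'
#' @param path file path.
#' @return Expression `SummarizedExperiment` (see [ExpressionSE()]).
#' @export
readExpression <- function(path) {
    if (!file.exists(path)) stop("expression file not found: ", path)
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "gene_id")
        stop("expression TSV must start with a gene_id column: ", path)
    gid <- trimws(tab$gene_id)
    if (anyDuplicated(gid)) stop("duplicate gene id in expression file: ", path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- gid
    keys <- colnames(m)
    pos <- regexpr("_[^_]*$", keys)
    if (any(pos < 0)) stop("sample columns must be named <subject>_<timepoint>")
    ExpressionSE(m, substr(keys, 1, pos - 1), substring(keys, pos + 1))
}

#' Write an expression TSV
#' @param se expression `SummarizedExperiment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(se, path) {
    m <- SummarizedExperiment::assay(se, "abundance")
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    writeTsv(df, path)
}

#' Read an extended GMT pathway file
#'
#' Format per line: `pathway_id<TAB>name|category<TAB>gene1<TAB>gene2...`
#' — the category label rides in the GMT description field after a `|`.
#' Lines with fewer than three fields are rejected with their line number;
#' pathways with an empty gene list are skipped with a warning.
#'
#' @param path file path.
#' @return A [PathwayDB-class].
#' @export
readPathwayGMT <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 1L) < 3L)
    if (length(bad))
        stop(sprintf("malformed GMT line(s) %s in %s: need id, name|category and >= 1 gene",
                     paste(head(bad, 5), collapse = ", "), path))
    ids <- character(); nms <- character(); cts <- character(); gns <- list()
    for (i in seq_along(fields)) {
        f <- trimws(fields[[i]])
        desc <- strsplit(f[2], "|", fixed = TRUE)[[1]]
        if (length(desc) != 2L)
            stop(sprintf("GMT line %d in %s: description must be name|category", i, path))
        genes <- unique(f[-(1:2)])
        genes <- genes[nzchar(genes)]
        if (length(genes) == 0L) {
            warning(sprintf("GMT line %d (%s): empty pathway skipped", i, f[1]))
            next
        }
        ids <- c(ids, f[1]); nms <- c(nms, desc[1]); cts <- c(cts, desc[2])
        gns[[length(gns) + 1L]] <- genes
    }
    PathwayDB(ids, nms, cts, gns)
}

#' Write a PathwayDB as extended GMT
#' @param db a [PathwayDB-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePathwayGMT <- function(db, path) {
    lines <- vapply(seq_len(length(db)), function(i)
        paste(c(db@pathwayId[i],
                paste0(db@pathwayName[i], "|", db@category[i]),
                db@genes[[i]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read an undirected PPI edge list
#'
#' Two-column TSV `geneA<TAB>geneB` (no header required; a `geneA`/`gene_a`
#' header line is tolerated). Self-loops are dropped; duplicate edges —
#' including reversed duplicates — are merged, with a message reporting how
#' many were removed.
#'
#' @param path file path.
#' @return An undirected `igraph` with vertex names = gene ids.
#' @export
readPPIEdgeList <- function(path) {
    if (!file.exists(path)) stop("PPI edge list not found: ", path)
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("PPI edge list needs two columns: ", path)
    if (tolower(gsub("_", "", tab[1, 1])) %in% c("genea", "source", "from"))
        tab <- tab[-1, , drop = FALSE]
    a <- trimws(tab[[1]]); b <- trimws(tab[[2]])
    keep <- a != b
    g <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]),
                                     directed = FALSE)
    before <- igraph::ecount(g)
    g <- igraph::simplify(g)
    dropped <- before - igraph::ecount(g) + sum(!keep)
    if (dropped > 0)
        message(dropped, " duplicate/self-loop edge(s) removed from ", path)
    g
}

#' Write a PPI network as a two-column edge list
#' @param ppi an `igraph` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePPIEdgeList <- function(ppi, path) {
    el <- igraph::as_edgelist(ppi, names = TRUE)
    writeTsv(data.frame(gene_a = el[, 1], gene_b = el[, 2]), path,
             col.names = FALSE)
}

#' Read hypothesis seed lists from a directory
#'
#' One plain-text file per hypothesis, one gene id per line; the filename
#' stem is the hypothesis name.
#'
#' @param dir directory containing `*.txt` seed files.
#' @return Named list of character vectors.
#' @export
readSeedLists <- function(dir) {
    if (!dir.exists(dir)) stop("seed directory not found: ", dir)
    files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
    if (length(files) == 0L) stop("no .txt seed list in ", dir)
    seeds <- lapply(files, function(f) {
        g <- trimws(readLines(f))
        unique(g[nzchar(g)])
    })
    names(seeds) <- sub("\\.txt$", "", basename(files))
    seeds
}

#' Write hypothesis seed lists
#' @param seeds named list of gene-id vectors.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSeedLists <- function(seeds, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(seeds))
        writeLines(seeds[[nm]], file.path(dir, paste0(nm, ".txt")))
    invisible(dir)
}

#' Write a simulated dataset to disk
#'
#' Emits every pipeline input in its interchange format: `expression.tsv`,
#' `pathways.gmt` (extended GMT), `ppi_edges.tsv`, `seeds/<name>.txt`, and
#' `ground_truth.json`. All files round-trip losslessly through the
#' matching readers.
#'
#' @param dataset result of [simulateGraftLossDataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeGraftLossDataset <- function(dataset, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(expression = file.path(dir, "expression.tsv"),
               pathways = file.path(dir, "pathways.gmt"),
               ppi = file.path(dir, "ppi_edges.tsv"),
               seeds = file.path(dir, "seeds"),
               truth = file.path(dir, "ground_truth.json"))
    writeExpression(dataset$expression, paths["expression"])
    writePathwayGMT(dataset$pathways, paths["pathways"])
    writePPIEdgeList(dataset$ppi, paths["ppi"])
    writeSeedLists(dataset$seeds, paths["seeds"])
    jsonlite::write_json(
        list(activated_pathways = dataset$truth$activated_pathways,
             causal_hypothesis = dataset$truth$causal_hypothesis,
             de_genes = dataset$truth$de_genes),
        paths["truth"], auto_unbox = TRUE, pretty = TRUE)
    invisible(paths)
}

writeTsv <- function(df, path, col.names = TRUE) {
    ok <- tryCatch({
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = col.names)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
        stop("failed to write ", path, ": ", conditionMessage(ok))
    invisible(path)
}

#' Validate pipeline output tables against the bundled schema
#'
#' Checks that each result table written by [runPipeline()] has exactly the
#' column set declared in `inst/schema/tables.json`.
#'
#' @param dir pipeline output directory.
#' @return `TRUE` invisibly; errors describe the first mismatch.
#' @export
checkTableSchemas <- function(dir) {
    schema <- jsonlite::read_json(
        system.file("schema", "tables.json", package = "glpapnet"),
        simplifyVector = TRUE)
    for (file in names(schema)) {
        p <- file.path(dir, file)
        if (!file.exists(p)) stop("missing output table: ", p)
        got <- names(read.delim(p, check.names = FALSE, nrows = 1))
        if (!identical(got, schema[[file]]))
            stop(sprintf("schema mismatch in %s: got [%s], expected [%s]",
                         file, paste(got, collapse = ", "),
                         paste(schema[[file]], collapse = ", ")))
    }
    invisible(TRUE)
}
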