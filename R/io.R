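#' Read and write intensity matrices as tab-separated text
#'
#' The dialect is: header row of sample ids, first column protein ids,
#' remaining cells log2 intensities. Empty cells, `NA` and `NaN` are missing;
#' with `zeroIsMissing = TRUE`, exact zeros are missing too. Write-then-read
#' round-trips reproduce the matrix including its missingness pattern.
#'
#' @param path file path.
#' @param zeroIsMissing treat 0 as not quantified (default `FALSE`).
#' @return `readIntensityTsv`: numeric matrix with `NA` for missing entries.
#' @export
readIntensityTsv <- function(path, zeroIsMissing = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    if (length(lines) < 2L) stop("parse error: no data rows in ", path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L)
        stop("parse error at line 1: malformed header (need id + samples)")
    samples <- header[-1]
    nc <- length(header)
    ids <- character(length(lines) - 1L)
    vals <- matrix(NA_real_, length(lines) - 1L, nc - 1L)
    for (i in seq_along(ids)) {
        f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
        length(f) <- nc   # pad trailing empty fields
        ids[i] <- f[1]
        cells <- f[-1]
        miss <- is.na(cells) | cells %in% c("", "NA", "NaN")
        num <- suppressWarnings(as.numeric(cells))
        bad <- !miss & is.na(num)
        if (any(bad))
            stop(sprintf("parse error at line %d: non-numeric cell '%s'",
                         i + 1L, cells[which(bad)[1]]))
        num[miss] <- NA_real_
        vals[i, ] <- num
    }
    if (anyDuplicated(ids))
        stop(sprintf("parse error: duplicate protein id '%s'",
                     ids[duplicated(ids)][1]))
    dimnames(vals) <- list(ids, samples)
    if (zeroIsMissing) vals[!is.na(vals) & vals == 0] <- NA_real_
    vals
}

#' @rdname readIntensityTsv
#' @param matrix numeric matrix with row and column names.
#' @export
writeIntensityTsv <- function(matrix, path) {
    df <- data.frame(protein_id = rownames(matrix), matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read and write study designs as tab-separated text
#'
#' Columns: `sample`, `group`, `batch`.
#'
#' @param path file path.
#' @return `readDesignTsv`: data.frame with those three character columns.
#' @export
readDesignTsv <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("sample", "group", "batch")
    if (!all(need %in% colnames(d)))
        stop("design table lacks columns: ",
             paste(setdiff(need, colnames(d)), collapse = ", "))
    if (anyDuplicated(d$sample)) stop("duplicate sample ids in design")
    d[, need]
}

#' @rdname readDesignTsv
#' @param se a `SummarizedExperiment` whose colData holds group and batch.
#' @export
writeDesignTsv <- function(se, path) {
    d <- data.frame(sample = colnames(se),
                    group = as.character(.groups(se)),
                    batch = as.character(.batches(se)),
                    stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Rebuild an experiment from matrix + design files
#'
#' @param matrixPath,designPath paths written by [writeIntensityTsv()] and
#'   [writeDesignTsv()].
#' @param zeroIsMissing passed to [readIntensityTsv()].
#' @return a `SummarizedExperiment`.
#' @export
readExperiment <- function(matrixPath, designPath, zeroIsMissing = FALSE) {
    m <- readIntensityTsv(matrixPath, zeroIsMissing)
    d <- readDesignTsv(designPath)
    if (!setequal(colnames(m), d$sample))
        stop("samples in matrix and design do not match")
    d <- d[match(colnames(m), d$sample), ]
    ProteomicsExperiment(m, d$group, d$batch)
}

#' Read and write GMT category files
#'
#' One category per line: id, description, then tab-separated member ids.
#' Duplicate members within a category are deduplicated with a warning;
#' duplicate category ids are an error.
#'
#' @param path file path.
#' @return `readGmt`: a [CategorySets-class] object.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("validation error: empty GMT file")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop(sprintf("parse error at line %d: GMT lines need >= 3 fields",
                     short[1]))
    ids <- vapply(fields, `[`, character(1), 1)
    if (anyDuplicated(ids))
        stop(sprintf("duplicate category id '%s'", ids[duplicated(ids)][1]))
    desc <- vapply(fields, `[`, character(1), 2)
    sets <- lapply(fields, function(f) f[-(1:2)])
    dup <- vapply(sets, anyDuplicated, integer(1)) > 0
    if (any(dup)) {
        warning(sprintf("deduplicated members in: %s",
                        paste(ids[dup], collapse = ", ")))
        sets <- lapply(sets, unique)
    }
    names(sets) <- ids
    new("CategorySets", sets = sets, descriptions = desc)
}

#' @rdname readGmt
#' @param sets a [CategorySets-class] object.
#' @export
writeGmt <- function(sets, path) {
    desc <- categoryDescriptions(sets)
    lines <- vapply(names(sets), function(id) {
        paste(c(id, desc[[id]], categoryMembers(sets)[[id]]),
              collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read and write gene-level differential-expression tables
#'
#' Columns: `gene`, `logfc`, `p` (tab-separated).
#'
#' @param path file path.
#' @return `readGeneTable`: data.frame with those columns.
#' @export
readGeneTable <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "logfc", "p")
    if (!all(need %in% colnames(d)))
        stop("gene table lacks columns: ",
             paste(setdiff(need, colnames(d)), collapse = ", "))
    if (anyDuplicated(d$gene)) stop("duplicate gene symbols")
    d
}

#' @rdname readGeneTable
#' @param geneTable data.frame with columns `gene`, `logfc`, `p`.
#' @export
writeGeneTable <- function(geneTable, path) {
    utils::write.table(geneTable[, c("gene", "logfc", "p")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Bundled worked example: published differential-abundance summary
#'
#' Per-protein fold change (DM/NDM), q-value and imputation pass rate for the
#' 23 proteins reported as differentially abundant in a published label-free
#' proteomic comparison of visceral adipose tissue from diabetic (DM) and
#' non-diabetic (NDM) subjects (10 per group, 50 imputation rounds,
#' significance at q < 0.1 in at least 30 rounds). Used as a small worked
#' example for the stability decision rule.
#'
#' @return data.frame with columns `accession`, `gene`, `fold_change`,
#'   `q_value`, `pass_rate`.
#' @examples
#' da <- exampleDAProteins()
#' table(applyStabilityRule(da$fold_change, da$pass_rate)$direction)
#' @export
exampleDAProteins <- function() {
    path <- system.file("extdata", "vat_da_proteins.tsv",
                        package = "lfqStability", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}
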