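# TSV input/output with provenance headers. Every file written by the
# package starts with commented "#" header lines recording the package
# version, seed, stage and a config hash, so a run can be traced back to
# its configuration; readers skip them.

# small djb2-style hash over a deparsed object, for provenance headers
configHash <- function(x) {
    s <- paste(deparse(x), collapse = "")
    h <- 5381
    for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
    sprintf("%08x", as.integer(h))
}

provenanceHeader <- function(stage, seed = NA, config = NULL) {
    c(sprintf("# multiRppa %s", as.character(packageVersion("multiRppa"))),
      sprintf("# stage: %s", stage),
      sprintf("# seed: %s", seed),
      sprintf("# config_hash: %s",
              if (is.null(config)) "none" else configHash(config)))
}

writeTsv <- function(df, path, stage = "export", seed = NA,
                     config = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenanceHeader(stage, seed, config), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write / read a raw spot table as TSV
#'
#' The spot table schema is `sample_id`, `antibody_id`, `dilution_step`,
#' `technical_replicate`, `intensity`. The reader validates the schema:
#' missing columns raise a schema error naming them, non-numeric
#' intensities are reported with their line numbers, and duplicated
#' (sample, antibody, dilution, replicate) keys are rejected with line
#' numbers.
#'
#' @param spots spot table data.frame.
#' @param path file path.
#' @param stage,seed,config provenance header fields.
#'
#' @return `writeSpotTable()` the path, invisibly; `readSpotTable()` the
#'   validated data.frame.
#' @export
writeSpotTable <- function(spots, path, stage = "simulate", seed = NA,
                           config = NULL) {
    df <- as.data.frame(spots)
    need <- c("sample_id", "antibody_id", "dilution_step",
              "technical_replicate", "intensity")
    stopifnot(all(need %in% names(df)))
    writeTsv(df[, need], path, stage = stage, seed = seed, config = config)
}

#' @rdname writeSpotTable
#' @export
readSpotTable <- function(path) {
    df <- read.delim(path, comment.char = "#", sep = "\t",
                     stringsAsFactors = FALSE, colClasses = "character")
    need <- c("sample_id", "antibody_id", "dilution_step",
              "technical_replicate", "intensity")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("schema error: spot table lacks column(s): ",
             paste(miss, collapse = ", "))
    val <- suppressWarnings(as.numeric(df$intensity))
    bad <- which(is.na(val) & !is.na(df$intensity) & df$intensity != "NA")
    if (length(bad))
        stop("non-numeric intensity on data row(s): ",
             paste(head(bad, 10), collapse = ", "))
    df$intensity <- val
    df$dilution_step <- as.integer(df$dilution_step)
    df$technical_replicate <- as.integer(df$technical_replicate)
    key <- paste(df$sample_id, df$antibody_id, df$dilution_step,
                 df$technical_replicate)
    dup <- which(duplicated(key))
    if (length(dup))
        stop("duplicated (sample, antibody, dilution, replicate) key on ",
             "data row(s): ", paste(head(dup, 10), collapse = ", "))
    if (any(df$intensity < 0, na.rm = TRUE))
        stop("negative intensities are invalid")
    df
}

#' Write / read a processed intensity matrix as TSV
#'
#' Samples as rows, antibodies as columns, first column `sample_id`.
#'
#' @param x matrix (antibodies x samples, e.g. an assay) or a
#'   [SummarizedExperiment-class].
#' @param path file path.
#' @param stage,seed,config provenance header fields.
#'
#' @return `writeIntensityMatrix()` the path, invisibly;
#'   `readIntensityMatrix()` an antibodies x samples matrix.
#' @export
writeIntensityMatrix <- function(x, path, stage = "process", seed = NA,
                                 config = NULL) {
    m <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x) else as.matrix(x)
    df <- data.frame(sample_id = colnames(m), t(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    writeTsv(df, path, stage = stage, seed = seed, config = config)
}

#' @rdname writeIntensityMatrix
#' @export
readIntensityMatrix <- function(path) {
    df <- read.delim(path, comment.char = "#", sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(df))
        stop("schema error: intensity matrix lacks 'sample_id' column")
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id rows")
    m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric intensity values")
    rownames(m) <- df$sample_id
    t(m)
}
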