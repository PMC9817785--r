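#' Write a feature-by-sample matrix as TSV
#'
#' First column is the feature id (`id_col`), remaining columns are
#' samples.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the feature-id column (default `"gene"`).
#' @export
write_matrix_tsv <- function(mat, path, id_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample TSV matrix
#'
#' @param path TSV written by [write_matrix_tsv()] (first column =
#'   feature id).
#' @param integer Coerce the values to integer (for count matrices).
#' @return Numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path, integer = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (integer) storage.mode(mat) <- "integer"
  mat
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member
#' genes.  The description field is interpreted as the collection tag.
#'
#' @param path Path to a `.gmt` file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad))
    stop("malformed GMT line(s) (need name, description, >=1 gene): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  gene_set_collection(sets, vapply(fields, `[[`, character(1), 2))
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], collection$info$collection[i],
            collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a GSEA result table as TSV
#'
#' The `leading_edge` list-column is flattened to a comma-joined string.
#'
#' @param records Result of [run_gsea_collection()].
#' @param path Output path.
#' @export
write_gsea_tsv <- function(records, path) {
  flat <- records
  flat$leading_edge <- vapply(records$leading_edge, paste,
                              character(1), collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GSEA result table written by [write_gsea_tsv()]
#'
#' @param path TSV path.
#' @return Data frame with the `leading_edge` list-column restored.
#' @export
read_gsea_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$leading_edge <- strsplit(df$leading_edge, ",", fixed = TRUE)
  df
}

#' Write a sample metadata table as TSV
#' @param samples Data frame (e.g. from [gen_cohort_metadata()]).
#' @param path Output path.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#' @param path TSV path.
#' @return Data frame.
#' @export
read_sample_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
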