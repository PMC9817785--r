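#' Gene-set collection
#'
#' A lightweight container for named gene sets, each tagged with an
#' MSigDB-style collection label (C2, C5-BP, C5-MF, C6, C7 or any other
#' tag).  Set names must be unique across the collection (the generators
#' embed the collection tag in the name, which guarantees uniqueness
#' within each tag as well).
#'
#' @param sets Named list of character vectors (gene ids); all sets
#'   non-empty, names unique.
#' @param collections Character vector of collection tags, recycled to
#'   `length(sets)`.
#' @return An object of class `"gene_set_collection"`: a list with
#'   `sets` (named list) and `info` (data frame `name`, `collection`,
#'   `size`).
#' @examples
#' gsc <- gene_set_collection(list(A = c("G1", "G2"), B = c("G2", "G3")),
#'                            c("C2", "C6"))
#' gsc$info
#' @export
gene_set_collection <- function(sets, collections = "C2") {
  if (length(sets) == 0)
    return(structure(list(sets = stats::setNames(list(), character(0)),
                          info = data.frame(name = character(0),
                                            collection = character(0),
                                            size = integer(0),
                                            stringsAsFactors = FALSE)),
                     class = "gene_set_collection"))
  if (is.null(names(sets)) || anyNA(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop("gene set names must be unique")
  if (any(lengths(sets) == 0))
    stop("gene sets must be non-empty")
  collections <- rep_len(as.character(collections), length(sets))
  structure(
    list(
      sets = sets,
      info = data.frame(name = names(sets), collection = collections,
                        size = lengths(sets), stringsAsFactors = FALSE)
    ),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets,",
      "sizes", if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-",
      "\n")
  if (nrow(x$info)) print(table(x$info$collection))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Paired linear- and log2-scale probe matrices
#'
#' Holds the two probe-level normalizations consumed by the adaptive
#' probe filter: a linear-scale presence-oriented matrix (MAS5-like) and a
#' log2-scale background-adjusted matrix (GCRMA-like).  Both matrices must
#' share the same probe and sample ids in the same order.
#'
#' @param linear Numeric probe-by-sample matrix, positive, linear scale.
#' @param log2 Numeric probe-by-sample matrix, log2 scale.
#' @return An object of class `"probe_matrix_pair"` with elements
#'   `linear` and `log2`.
#' @export
probe_matrix_pair <- function(linear, log2) {
  if (!is.matrix(linear) || !is.matrix(log2))
    stop("linear and log2 must be matrices")
  if (is.null(rownames(linear)) || is.null(colnames(linear)))
    stop("matrices need probe rownames and sample colnames")
  if (!identical(dimnames(linear), dimnames(log2)))
    stop("linear and log2 matrices must share identical probe and sample ids")
  if (any(!is.finite(linear)) || any(!is.finite(log2)))
    stop("matrices must be finite")
  if (any(linear <= 0))
    stop("linear-scale matrix must be strictly positive")
  structure(list(linear = linear, log2 = log2), class = "probe_matrix_pair")
}

#' @export
print.probe_matrix_pair <- function(x, ...) {
  cat("probe_matrix_pair:", nrow(x$linear), "probes x",
      ncol(x$linear), "samples\n")
  invisible(x)
}
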