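#' Assign HER2 status from immunohistochemistry scores
#'
#' Applies the diagnostic score rule used for membranous HER2 staining:
#' scores on the 4-point scale 0 / 1+ / 2+ / 3+ are classified positive
#' when the score is >= 2 and negative otherwise (0 and 1+ intensities are
#' taken to be HER2-negative).  The equivocal 2+ score is treated as
#' positive with no reflex test.
#'
#' @param scores Integer vector of scores in `{0, 1, 2, 3}`; names (if
#'   present) are used to identify offending samples in error messages.
#' @return Character vector of `"positive"` / `"negative"`, same length
#'   and order as `scores`, names preserved.
#' @examples
#' classify_ihc(c(0, 1, 2, 3))
#' @export
classify_ihc <- function(scores) {
  if (length(scores) == 0) return(character(0))
  if (anyNA(scores) || !all(scores %in% 0:3)) {
    bad <- which(is.na(scores) | !(scores %in% 0:3))
    lab <- if (!is.null(names(scores))) names(scores)[bad] else bad
    stop("IHC scores must be in {0, 1, 2, 3}; offending sample(s): ",
         paste(lab, collapse = ", "))
  }
  out <- ifelse(scores >= 2, "positive", "negative")
  names(out) <- names(scores)
  out
}

#' Assign HER2 status by comparison with the cohort-mean marker expression
#'
#' Labels a sample positive when its marker (ERBB2 mRNA) expression is
#' strictly greater than the arithmetic mean over all samples in the
#' cohort, including the sample itself.  Samples exactly at the mean are
#' negative (positives must exceed the cohort average), so a constant
#' expression vector yields an all-negative cohort.  The rule is invariant
#' to positive affine transforms of the expression vector.
#'
#' @param expr Numeric vector of finite, non-negative marker expression
#'   values, one per sample; length >= 2.  Names preserved.
#' @return Character vector of `"positive"` / `"negative"`.
#' @examples
#' classify_by_cohort_mean(c(2, 4, 6, 8))  # mean 5
#' @export
classify_by_cohort_mean <- function(expr) {
  if (length(expr) < 2)
    stop("cohort-mean stratification needs at least 2 samples")
  if (anyNA(expr) || any(!is.finite(expr)))
    stop("marker expression must be finite")
  if (any(expr < 0))
    stop("marker expression must be non-negative")
  out <- ifelse(expr > mean(expr), "positive", "negative")
  names(out) <- names(expr)
  out
}

# shared label validation used by the DE and ranking stages
.check_labels <- function(labels, n_samples, min_per_group = 2L) {
  if (length(labels) != n_samples)
    stop("need one label per sample column (got ", length(labels),
         " labels for ", n_samples, " samples)")
  if (!all(labels %in% c("negative", "positive")))
    stop("labels must be 'negative' or 'positive'")
  tab <- table(factor(labels, levels = c("negative", "positive")))
  if (any(tab < min_per_group))
    stop("each group needs at least ", min_per_group, " samples (got ",
         tab[["negative"]], " negative, ", tab[["positive"]], " positive)")
  invisible(labels)
}
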