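## Classification of nearly diagnostic SNPs by geographic-cline coincidence
## (with the hybrid-index or morphological cline centre) crossed with
## genomic-cline outlier status, and the chi-square association test with
## per-cell contributions.

GEO_CLASSES <- c("overlap_Q", "overlap_morph", "neither")
ALPHA_CLASSES <- c("positive", "negative", "none")

#' Classify per-SNP geographic cline centres
#'
#' Exclusion first: loci for which the no-cline null won model selection
#' (`excluded_null`) or whose centre MLE exceeds the transect length
#' (`excluded_offtransect`). Remaining loci are `overlap_Q` when the centre
#' lies within the hybrid-index (Q-score) centre 2-LLU interval,
#' `overlap_morph` when within the union of the morphological trait
#' intervals, and `neither` otherwise. A centre falling in both the Q and
#' morphological intervals (possible only when those intervals overlap) is
#' assigned to the nearer centre, with a warning.
#'
#' @param fits data frame with columns `locus`, `is_null` (logical),
#'   `centre` (km).
#' @param q_centre,q_interval hybrid-index cline centre and its 2-LLU
#'   interval `c(lower, upper)`.
#' @param morph_centres,morph_intervals trait cline centres and a list (or
#'   2-column matrix) of their 2-LLU intervals.
#' @param transect_length transect length (km) for the off-transect rule.
#' @return `fits` with a `geo_class` column (`overlap_Q`, `overlap_morph`,
#'   `neither`, `excluded_null`, `excluded_offtransect`).
#' @export
classify_geo <- function(fits, q_centre, q_interval, morph_centres,
                         morph_intervals, transect_length) {
  stopifnot(all(c("locus", "is_null", "centre") %in% names(fits)))
  if (is.matrix(morph_intervals)) {
    morph_intervals <- lapply(seq_len(nrow(morph_intervals)),
                              function(i) morph_intervals[i, ])
  }
  in_q <- function(x) !is.na(x) & x >= q_interval[1] & x <= q_interval[2]
  in_m <- function(x) {
    hit <- rep(FALSE, length(x))
    for (iv in morph_intervals) hit <- hit | (!is.na(x) & x >= iv[1] & x <= iv[2])
    hit
  }
  cls <- rep(NA_character_, nrow(fits))
  cls[fits$is_null] <- "excluded_null"
  off <- !fits$is_null & fits$centre > transect_length
  cls[off] <- "excluded_offtransect"
  live <- is.na(cls)
  hq <- in_q(fits$centre) & live
  hm <- in_m(fits$centre) & live
  both <- hq & hm
  if (any(both)) {
    warning(sprintf("%d loci overlap both the Q and morphological intervals; assigned to the nearer centre", sum(both)))
    dq <- abs(fits$centre - q_centre)
    dm <- vapply(fits$centre, function(x) min(abs(x - morph_centres)), 0)
    hq[both] <- dq[both] <= dm[both]
    hm[both] <- !hq[both]
  }
  cls[hq] <- "overlap_Q"
  cls[hm & is.na(cls)] <- "overlap_morph"
  cls[is.na(cls)] <- "neither"
  fits$geo_class <- cls
  fits
}

#' Build the 3x3 geographic x genomic classification table
#'
#' Rows are geographic classes (`overlap_Q`, `overlap_morph`, `neither`),
#' columns genomic-cline outlier classes (`positive`, `negative`, `none`).
#' Excluded loci (`excluded_*`) are not counted.
#'
#' @param classes data frame with `geo_class` and `outlier_class`.
#' @return 3x3 integer matrix.
#' @export
build_table <- function(classes) {
  stopifnot(all(c("geo_class", "outlier_class") %in% names(classes)))
  keep <- classes$geo_class %in% GEO_CLASSES
  if (!any(keep)) abort("no non-excluded loci to tabulate")
  tab <- table(factor(classes$geo_class[keep], GEO_CLASSES),
               factor(classes$outlier_class[keep], ALPHA_CLASSES))
  m <- matrix(as.integer(tab), 3, 3, dimnames = dimnames(tab))
  m
}

#' Pearson chi-square test with per-cell contributions
#'
#' Pearson chi-square without continuity correction, degrees of freedom
#' `(r - 1)(c - 1)`, plus each cell's percentage contribution to the
#' statistic (`100 (O - E)^2 / E / X2`) and the sign of its deviation from
#' the expected count.
#'
#' @param tab contingency table (matrix of counts); all row and column
#'   totals must be positive.
#' @return list with `statistic`, `df`, `p_value`, `expected`,
#'   `contribution_pct` (matrix summing to 100) and `deviation_sign`.
#' @export
chisq_with_contributions <- function(tab) {
  tab <- as.matrix(tab)
  rt <- rowSums(tab); ct <- colSums(tab); n <- sum(tab)
  if (any(rt == 0) || any(ct == 0)) {
    bad <- c(names(rt)[rt == 0], names(ct)[ct == 0])
    abort(sprintf("zero expected count: empty margin(s) %s",
                  paste(bad, collapse = ", ")))
  }
  E <- outer(rt, ct) / n
  X2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  contrib <- if (X2 > 0) 100 * (tab - E)^2 / E / X2 else (tab - E) * 0
  list(statistic = X2, df = df,
       p_value = pchisq(X2, df, lower.tail = FALSE),
       expected = E,
       contribution_pct = contrib,
       deviation_sign = sign(tab - E))
}
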