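#' Great-circle transect distances from the southernmost population
#'
#' Computes haversine great-circle distances (sphere of radius 6371 km) from
#' the southernmost sampled population to every population, defining the
#' one-dimensional transect coordinate used by all cline analyses. The
#' southernmost population is the one with minimum latitude (ties broken by
#' minimum longitude) and receives distance 0.
#'
#' @param pops data frame with columns `pop_id`, `lat`, `lon` (decimal
#'   degrees) and optionally `group`.
#' @return `pops` with a `distance_km` column added (or overwritten), sorted
#'   by increasing `distance_km`.
#' @examples
#' pops <- data.frame(pop_id = c("a", "b"), lat = c(0, 1), lon = c(0, 0))
#' great_circle_distances(pops)$distance_km  # 0, 111.195
#' @export
great_circle_distances <- function(pops) {
  stopifnot(is.data.frame(pops), all(c("pop_id", "lat", "lon") %in% names(pops)))
  if (any(abs(pops$lat) > 90) || any(abs(pops$lon) > 180)) {
    abort("invalid coordinates: require |lat| <= 90 and |lon| <= 180")
  }
  if (anyDuplicated(pops$pop_id)) abort("duplicate pop_id")
  origin <- order(pops$lat, pops$lon)[1L]
  d <- geosphere::distHaversine(
    cbind(pops$lon[origin], pops$lat[origin]),
    cbind(pops$lon, pops$lat),
    r = 6371000
  ) / 1000
  pops$distance_km <- d
  pops[order(pops$distance_km), , drop = FALSE]
}

# internal pairwise haversine (km) between two coordinate tables
pairwise_km <- function(a, b) {
  out <- matrix(NA_real_, nrow(a), nrow(b))
  for (j in seq_len(nrow(b))) {
    out[, j] <- geosphere::distHaversine(
      cbind(a$lon, a$lat), cbind(b$lon[j], b$lat[j]), r = 6371000) / 1000
  }
  out
}

#' Pair genetic populations with nearby morphological populations
#'
#' Each genetic population is paired with the average of the morphological
#' summaries from all morphological populations within `radius_km`
#' (great-circle). Populations with no morphological neighbour within the
#' radius remain unpaired and are flagged. Boundary equality merges
#' (distance == radius counts as within).
#'
#' @param genetic_pops data frame with `pop_id`, `lat`, `lon`.
#' @param morph_pops data frame with `lat`, `lon` and numeric summary columns
#'   (e.g. per-trait means); every numeric column other than the coordinates
#'   is averaged across the in-radius populations.
#' @param radius_km merge radius, default 5 km.
#' @return `genetic_pops` with the averaged morphological columns appended,
#'   plus `n_morph` (number of contributing morphological populations) and
#'   `paired` (logical).
#' @export
merge_within_radius <- function(genetic_pops, morph_pops, radius_km = 5) {
  stopifnot(all(c("lat", "lon") %in% names(genetic_pops)),
            all(c("lat", "lon") %in% names(morph_pops)))
  val_cols <- setdiff(names(morph_pops)[vapply(morph_pops, is.numeric, TRUE)],
                      c("lat", "lon", "distance_km"))
  d <- pairwise_km(genetic_pops, morph_pops)
  out <- genetic_pops
  for (v in val_cols) out[[v]] <- NA_real_
  out$n_morph <- 0L
  for (i in seq_len(nrow(genetic_pops))) {
    hit <- which(d[i, ] <= radius_km)
    out$n_morph[i] <- length(hit)
    if (length(hit)) {
      for (v in val_cols) out[[v]][i] <- mean(morph_pops[[v]][hit])
    }
  }
  out$paired <- out$n_morph > 0L
  out
}

#' Per-group allele frequencies
#'
#' Frequency of the counted allele per locus per group, computed over
#' non-missing genotypes; the denominator is twice the number of non-missing
#' individuals. Loci with all genotypes missing in a group get `NA`.
#'
#' @param g a [genotype_matrix] (or plain loci x individuals 0/1/2 matrix
#'   with `groups` supplied).
#' @param groups character/factor of group membership per individual;
#'   defaults to `g$ind$group`.
#' @return matrix loci x groups of allele frequencies.
#' @export
group_allele_freqs <- function(g, groups = NULL) {
  geno <- if (inherits(g, "genotype_matrix")) g$geno else g
  if (is.null(groups)) {
    if (!inherits(g, "genotype_matrix")) abort("groups must be supplied")
    groups <- g$ind$group
  }
  stopifnot(length(groups) == ncol(geno))
  groups <- as.character(groups)
  lev <- unique(groups)
  out <- matrix(NA_real_, nrow(geno), length(lev), dimnames = list(rownames(geno), lev))
  for (gr in lev) {
    sub <- geno[, groups == gr, drop = FALSE]
    nn <- rowSums(!is.na(sub))
    out[, gr] <- ifelse(nn > 0, rowSums(sub, na.rm = TRUE) / (2 * nn), NA_real_)
  }
  out
}

#' Select nearly diagnostic SNPs
#'
#' Retains loci whose absolute parental allele-frequency difference is at or
#' above the stated empirical quantile (type-7 interpolation) of the |dp|
#' distribution over all loci; ties at the threshold are kept.
#'
#' @param freqA,freqB parental allele-frequency vectors on the same loci
#'   (names used as locus ids when present).
#' @param quantile empirical quantile defining the diagnostic threshold
#'   (default 0.90, i.e. the top 10 percent tail).
#' @return object of class `diagnostic_set`: a list with `table` (locus,
#'   freqA, freqB, absdiff, retained), `threshold`, `quantile`, and `loci`
#'   (retained locus ids).
#' @export
select_diagnostic <- function(freqA, freqB, quantile = 0.90) {
  stopifnot(length(freqA) == length(freqB), quantile >= 0, quantile <= 1)
  ids <- names(freqA)
  if (is.null(ids)) ids <- paste0("L", seq_along(freqA))
  ok <- !is.na(freqA) & !is.na(freqB)
  if (sum(ok) < 10) abort("fewer than 10 loci with defined parental frequencies")
  absdiff <- abs(freqA - freqB)
  thr <- stats::quantile(absdiff[ok], probs = quantile, type = 7, names = FALSE)
  retained <- ok & absdiff >= thr
  tab <- data.frame(locus = ids, freqA = freqA, freqB = freqB,
                    absdiff = absdiff, retained = retained,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, threshold = thr, quantile = quantile,
                 loci = ids[retained]),
            class = "diagnostic_set")
}

#' @export
print.diagnostic_set <- function(x, ...) {
  cat(sprintf("diagnostic_set: %d of %d loci retained (|dp| >= %.4f, q = %.2f)\n",
              length(x$loci), nrow(x$table), x$threshold, x$quantile))
  invisible(x)
}

#' Write a diagnostic set as TSV
#' @param x a `diagnostic_set`
#' @param path output file
#' @export
write_diagnostic_tsv <- function(x, path) {
  stopifnot(inherits(x, "diagnostic_set"))
  write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
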