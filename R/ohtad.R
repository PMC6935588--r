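## Ohta's D-statistics: partitioning of squared two-locus disequilibrium in
## a subdivided population into within-subpopulation (D2_IS, D2'_IS) and
## among-subpopulation (D2_ST, D2'_ST) variance components, with total
## D2_IT. Components are defined on gamete (haplotype) frequencies with
## unweighted subpopulation means, so the identity
## D2_IT = D2'_IS + D2'_ST holds exactly.

#' Overlapping window sets of populations along the transect
#'
#' Tiles populations ordered by transect distance into sets of `set_size`
#' consecutive populations, consecutive sets sharing `overlap` populations.
#' A final partial window (when `(n - set_size)` is not divisible by
#' `(set_size - overlap)`) is truncated and flagged.
#'
#' @param pops population table with `pop_id` and `distance_km` (ordering
#'   key), or a character vector of ordered pop ids.
#' @param set_size populations per set (default 4).
#' @param overlap populations shared by consecutive sets (default 1).
#' @return list of window sets, each a list with `pop_ids`, `indices`,
#'   `midpoint_km` (NA when distances are unavailable) and `partial`.
#' @examples
#' length(window_sets(paste0("p", 1:34)))  # 11
#' @export
window_sets <- function(pops, set_size = 4, overlap = 1) {
  stopifnot(set_size > overlap, overlap >= 0)
  if (is.data.frame(pops)) {
    ord <- order(pops$distance_km)
    ids <- pops$pop_id[ord]
    dist <- pops$distance_km[ord]
  } else {
    ids <- pops
    dist <- rep(NA_real_, length(ids))
  }
  n <- length(ids)
  if (n < set_size) abort("fewer populations than set_size")
  step <- set_size - overlap
  starts <- seq(1L, n, by = step)
  out <- list()
  for (s in starts) {
    if (s > 1L && s + set_size - 1L > n && (s - step) + set_size - 1L >= n) break
    idx <- s:min(s + set_size - 1L, n)
    out[[length(out) + 1L]] <- list(
      pop_ids = ids[idx], indices = idx,
      midpoint_km = mean(dist[idx]),
      partial = length(idx) < set_size)
    if (max(idx) == n) break
  }
  out
}

#' Ohta's variance components for one locus pair
#'
#' Given per-subpopulation gamete (haplotype) frequency tables
#' `g[i, j]` (allele i at locus 1, allele j at locus 2, each summing to 1),
#' computes, with `x`, `y` the subpopulation allele frequencies and bars
#' denoting unweighted means over subpopulations:
#' \itemize{
#' \item `d2_is`: mean over subpops of `sum_ij (g_ij - x_i y_j)^2`
#' \item `d2_st`: mean over subpops of `sum_ij (x_i y_j - xbar_i ybar_j)^2`
#' \item `d2p_is`: mean over subpops of `sum_ij (g_ij - gbar_ij)^2`
#' \item `d2p_st`: `sum_ij (gbar_ij - xbar_i ybar_j)^2`
#' \item `d2_it`: mean over subpops of `sum_ij (g_ij - xbar_i ybar_j)^2`
#' }
#'
#' @param gametes list (one per subpopulation) of gamete frequency matrices
#'   with identical dimensions.
#' @param tol tolerance for the sum-to-one validation.
#' @return list with the five components and `n_subpops`.
#' @export
ohta_components <- function(gametes, tol = 1e-8) {
  K <- length(gametes)
  if (K < 2) abort("need >= 2 subpopulations")
  d <- dim(gametes[[1]])
  for (g in gametes) {
    if (!identical(dim(g), d)) abort("gamete tables differ in dimension")
    if (abs(sum(g) - 1) > tol) abort("gamete frequencies must sum to 1")
  }
  arr <- array(unlist(gametes), dim = c(d, K))
  x <- apply(arr, c(1, 3), sum)   # A1 x K allele freqs locus 1
  y <- apply(arr, c(2, 3), sum)   # A2 x K allele freqs locus 2
  gbar <- apply(arr, c(1, 2), mean)
  xbar <- rowMeans(x); ybar <- rowMeans(y)
  xy_bar <- outer(xbar, ybar)
  d2_is <- d2_st <- d2p_is <- d2_it <- 0
  for (k in seq_len(K)) {
    gk <- arr[, , k]
    xyk <- outer(x[, k], y[, k])
    d2_is <- d2_is + sum((gk - xyk)^2)
    d2_st <- d2_st + sum((xyk - xy_bar)^2)
    d2p_is <- d2p_is + sum((gk - gbar)^2)
    d2_it <- d2_it + sum((gk - xy_bar)^2)
  }
  list(d2_is = d2_is / K, d2_st = d2_st / K, d2p_is = d2p_is / K,
       d2p_st = sum((gbar - xy_bar)^2), d2_it = d2_it / K, n_subpops = K)
}

# EM estimate of 2x2 gamete frequencies from unphased 0/1/2 genotypes at
# two loci (random-mating assumption); fallback for empirical data without
# haplotypes.
em_gamete_freqs <- function(g1, g2, max_iter = 100, tol = 1e-10) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (!n) abort("no complete genotype pairs")
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  # gamete freqs: f11, f10, f01, f00 for alleles (1,1),(1,0),(0,1),(0,0)
  f <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  dh <- g1 == 1 & g2 == 1  # double heterozygotes: ambiguous phase
  # fixed gamete counts from unambiguous individuals
  base <- c(sum((g1 == 2) * (g2 == 2) * 2 + (g1 == 2) * (g2 == 1) + (g1 == 1) * (g2 == 2)),
            sum((g1 == 2) * (g2 == 0) * 2 + (g1 == 2) * (g2 == 1) + (g1 == 1) * (g2 == 0)),
            sum((g1 == 0) * (g2 == 2) * 2 + (g1 == 0) * (g2 == 1) + (g1 == 1) * (g2 == 2)),
            sum((g1 == 0) * (g2 == 0) * 2 + (g1 == 0) * (g2 == 1) + (g1 == 1) * (g2 == 0)))
  base[1] <- base[1] - sum(dh & g1 == 1 & g2 == 2) * 0  # counts above exclude dh already
  ndh <- sum(dh)
  for (it in seq_len(max_iter)) {
    pc <- f[1] * f[4]; pr <- f[2] * f[3]
    w <- if (pc + pr > 0) pc / (pc + pr) else 0.5
    cnt <- base + ndh * c(w, 1 - w, 1 - w, w)
    fnew <- cnt / (2 * n)
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  matrix(c(f[4], f[3], f[2], f[1]), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# Gamete matrices (2n x L, 0/1) per subpopulation for given loci
subpop_gametes <- function(g, pop_ids, loci) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(g$hapA)) abort("genotype matrix carries no haplotypes")
  li <- match(loci, rownames(g$geno))
  lapply(pop_ids, function(p) {
    ind <- which(g$ind$pop_id == p)
    rbind(t(g$hapA[li, ind, drop = FALSE]), t(g$hapB[li, ind, drop = FALSE]))
  })
}

#' Within- vs among-population LD profile along the transect
#'
#' For each window set, averages the Ohta components over a seeded uniform
#' subsample of locus pairs and reports the ratio of
#' within-population to among-population LD (`mean d2_is / mean d2_st`,
#' ratio of means; `NA` when the denominator is below `1e-12`). Loci that
#' are monomorphic across the window's pooled gametes are dropped; sets
#' with no polymorphic pair are omitted with a warning.
#'
#' @param g a [genotype_matrix] with haplotypes.
#' @param pops population table with `pop_id`, `distance_km`.
#' @param sets window sets from [window_sets()].
#' @param loci locus ids to use (e.g. the diagnostic set).
#' @param max_pairs maximum locus pairs per set (uniform subsample without
#'   replacement, seeded).
#' @param seed RNG seed for the pair subsample.
#' @param ratio_of_means if `FALSE`, report the mean of per-pair ratios
#'   instead of the (default, stabler) ratio of means.
#' @return data frame: `set`, `midpoint_km`, `n_pairs`, `d2_is`, `d2_st`,
#'   `d2p_is`, `d2p_st`, `d2_it`, `ratio`.
#' @export
dis_dst_profile <- function(g, pops, sets, loci, max_pairs = 50000,
                            seed = 1, ratio_of_means = TRUE) {
  rows <- list()
  for (si in seq_along(sets)) {
    set <- sets[[si]]
    gam <- subpop_gametes(g, set$pop_ids, loci)
    K <- length(gam)
    pooled_p <- colMeans(do.call(rbind, gam))
    poly <- which(pooled_p > 0 & pooled_p < 1)
    if (length(poly) < 2) {
      warning(sprintf("window set %d: no polymorphic locus pair; omitted", si))
      next
    }
    ids <- loci[poly]
    L <- length(poly)
    P11 <- vector("list", K); pa <- vector("list", K)
    for (k in seq_len(K)) {
      Gk <- gam[[k]][, poly, drop = FALSE]
      P11[[k]] <- crossprod(Gk) / nrow(Gk)
      pa[[k]] <- colMeans(Gk)
    }
    set.seed(seed + si)
    ut <- which(upper.tri(matrix(0, L, L)))
    distinct <- ut[ids[((ut - 1) %/% L) + 1] != ids[((ut - 1) %% L) + 1]]
    if (!length(distinct)) {
      warning(sprintf("window set %d: no distinct locus pair; omitted", si))
      next
    }
    pick <- if (length(distinct) > max_pairs) sample(distinct, max_pairs) else distinct
    comp <- ohta_components_matrix(P11, pa, pick)
    d2is <- comp$d2_is; d2st <- comp$d2_st
    ratio <- if (ratio_of_means) {
      if (mean(d2st) < 1e-12) NA_real_ else mean(d2is) / mean(d2st)
    } else {
      ok <- d2st >= 1e-12
      if (!any(ok)) NA_real_ else mean(d2is[ok] / d2st[ok])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      set = si, midpoint_km = set$midpoint_km, n_pairs = length(pick),
      d2_is = mean(d2is), d2_st = mean(d2st),
      d2p_is = mean(comp$d2p_is), d2p_st = mean(comp$d2p_st),
      d2_it = mean(comp$d2_it), ratio = ratio)
  }
  if (!length(rows)) abort("no window set produced a defined profile")
  do.call(rbind, rows)
}

# Vectorised biallelic Ohta components for selected pairs, from per-subpop
# P11 (L x L crossproducts) and allele frequency vectors.
ohta_components_matrix <- function(P11, pa, pick) {
  K <- length(P11)
  L <- length(pa[[1]])
  pbar <- Reduce(`+`, pa) / K
  G11bar <- Reduce(`+`, P11) / K
  acc <- function() numeric(length(pick))
  d2_is <- acc(); d2_st <- acc(); d2p_is <- acc(); d2_it <- acc()
  # precompute index vectors
  arow <- ((pick - 1) %% L) + 1
  bcol <- ((pick - 1) %/% L) + 1
  xb_a <- pbar[arow]; xb_b <- pbar[bcol]
  gb11 <- G11bar[pick]
  gb10 <- xb_a - gb11; gb01 <- xb_b - gb11; gb00 <- 1 - xb_a - xb_b + gb11
  e11 <- xb_a * xb_b; e10 <- xb_a * (1 - xb_b); e01 <- (1 - xb_a) * xb_b
  e00 <- (1 - xb_a) * (1 - xb_b)
  d2p_st <- (gb11 - e11)^2 + (gb10 - e10)^2 + (gb01 - e01)^2 + (gb00 - e00)^2
  for (k in seq_len(K)) {
    p11 <- P11[[k]][pick]
    a <- pa[[k]][arow]; b <- pa[[k]][bcol]
    Dk <- p11 - a * b
    d2_is <- d2_is + 4 * Dk^2
    x11 <- a * b; x10 <- a * (1 - b); x01 <- (1 - a) * b; x00 <- (1 - a) * (1 - b)
    d2_st <- d2_st + (x11 - e11)^2 + (x10 - e10)^2 + (x01 - e01)^2 + (x00 - e00)^2
    g10 <- a - p11; g01 <- b - p11; g00 <- 1 - a - b + p11
    d2p_is_k <- (p11 - gb11)^2 + (g10 - gb10)^2 + (g01 - gb01)^2 + (g00 - gb00)^2
    d2p_is <- d2p_is + d2p_is_k
    d2_it <- d2_it + (p11 - e11)^2 + (g10 - e10)^2 + (g01 - e01)^2 + (g00 - e00)^2
  }
  list(d2_is = d2_is / K, d2_st = d2_st / K, d2p_is = d2p_is / K,
       d2p_st = d2p_st, d2_it = d2_it / K)
}

#' Bootstrap LD profiles over non-diagnostic loci
#'
#' Draws `n_sets` resamples (with replacement) of size `set_size` from the
#' supplied (typically non-diagnostic) loci and computes the
#' [dis_dst_profile()] for each; self-pairs of a resampled duplicate locus
#' are never formed. Reports per-window mean and standard deviation of the
#' ratio across resamples.
#'
#' @inheritParams dis_dst_profile
#' @param n_sets number of bootstrap resamples (default 20).
#' @param set_size loci per resample (default: all supplied loci). When
#'   larger than the available loci, sampling with replacement proceeds and
#'   a warning is logged.
#' @return list with `profiles` (one data frame per resample) and `summary`
#'   (per window: mean and sd of the ratio and of `d2_is`, `d2_st`).
#' @export
bootstrap_neutral <- function(g, pops, sets, loci, n_sets = 20,
                              set_size = length(loci), max_pairs = 50000,
                              seed = 1) {
  if (set_size > length(loci)) {
    warning("set_size exceeds available loci; sampling with replacement proceeds")
  }
  profiles <- vector("list", n_sets)
  for (b in seq_len(n_sets)) {
    set.seed(seed * 1000L + b)
    pickl <- sample(loci, set_size, replace = TRUE)
    profiles[[b]] <- dis_dst_profile(g, pops, sets, pickl,
                                     max_pairs = max_pairs, seed = seed + b)
    profiles[[b]]$resample <- b
  }
  all <- do.call(rbind, profiles)
  agg <- aggregate(cbind(ratio, d2_is, d2_st) ~ set + midpoint_km, data = all,
                   FUN = function(v) c(mean = mean(v), sd = sd(v)),
                   na.action = stats::na.omit)
  list(profiles = profiles, summary = do.call(data.frame, agg))
}
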