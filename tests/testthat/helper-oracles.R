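# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as plain loops over definitions, not via
# the package's own code paths.

# per-locus per-group allele frequency by explicit counting
slow_group_freqs <- function(geno, groups) {
  lev <- unique(groups)
  out <- matrix(NA_real_, nrow(geno), length(lev), dimnames = list(NULL, lev))
  for (l in seq_len(nrow(geno))) {
    for (g in lev) {
      vals <- geno[l, groups == g]
      vals <- vals[!is.na(vals)]
      out[l, g] <- if (length(vals)) sum(vals) / (2 * length(vals)) else NA_real_
    }
  }
  out
}

# Ohta components by explicit loops over gamete cells and subpopulations
slow_ohta <- function(gametes) {
  K <- length(gametes)
  d <- dim(gametes[[1]])
  x <- lapply(gametes, rowSums)
  y <- lapply(gametes, colSums)
  gbar <- Reduce(`+`, gametes) / K
  xbar <- Reduce(`+`, x) / K
  ybar <- Reduce(`+`, y) / K
  d2is <- d2st <- d2pis <- d2it <- 0
  for (k in seq_len(K)) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      g <- gametes[[k]][i, j]
      xy <- x[[k]][i] * y[[k]][j]
      xyb <- xbar[i] * ybar[j]
      d2is <- d2is + (g - xy)^2
      d2st <- d2st + (xy - xyb)^2
      d2pis <- d2pis + (g - gbar[i, j])^2
      d2it <- d2it + (g - xyb)^2
    }
  }
  d2pst <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    d2pst <- d2pst + (gbar[i, j] - xbar[i] * ybar[j])^2
  }
  list(d2_is = d2is / K, d2_st = d2st / K, d2p_is = d2pis / K,
       d2p_st = d2pst, d2_it = d2it / K)
}

# random valid gamete frequency tables for K subpops
random_gamete_tables <- function(K = 3, a1 = 2, a2 = 2) {
  lapply(seq_len(K), function(k) {
    m <- matrix(rexp(a1 * a2), a1, a2)
    m / sum(m)
  })
}

# Pearson chi-square by explicit expected-count computation
slow_chisq <- function(tab) {
  rt <- rowSums(tab); ct <- colSums(tab); n <- sum(tab)
  X2 <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- rt[i] * ct[j] / n
    X2 <- X2 + (tab[i, j] - e)^2 / e
  }
  unname(X2)
}

# nested variance components from raw 0/1 allele vectors, by explicit
# sums of squares over the three levels
slow_varcomp <- function(alleles, pop, group) {
  pops <- unique(pop)
  N <- length(alleles)
  P <- length(pops)
  grp_of <- vapply(pops, function(p) unique(group[pop == p]), "")
  G <- length(unique(grp_of))
  ybar <- mean(alleles)
  ss_w <- ss_b <- ss_a <- 0
  ng <- setNames(numeric(G), unique(grp_of))
  pg <- setNames(numeric(G), unique(grp_of))
  for (gname in unique(grp_of)) {
    yg <- alleles[group == gname]
    ng[gname] <- length(yg)
    pg[gname] <- mean(yg)
    ss_a <- ss_a + length(yg) * (mean(yg) - ybar)^2
  }
  npop <- setNames(numeric(P), pops)
  for (p in pops) {
    yp <- alleles[pop == p]
    npop[p] <- length(yp)
    ss_w <- ss_w + sum((yp - mean(yp))^2)
    gname <- grp_of[p]
    ss_b <- ss_b + length(yp) * (mean(yp) - pg[gname])^2
  }
  ms_w <- ss_w / (N - P)
  ms_b <- ss_b / (P - G)
  ms_a <- ss_a / (G - 1)
  s2g <- vapply(unique(grp_of), function(gname)
    sum(npop[pops[grp_of == gname]]^2) / ng[gname], 0)
  nb <- (N - sum(s2g)) / (P - G)
  nbp <- (sum(s2g) - sum(npop^2) / N) / (G - 1)
  na <- (N - sum(ng^2) / N) / (G - 1)
  sw <- ms_w
  sb <- (ms_b - ms_w) / nb
  sa <- (ms_a - ms_w - nbp * sb) / na
  c(sa = sa, sb = sb, sw = sw)
}

# small synthetic spec used across tests
tiny_spec <- function(...) {
  synthetic_spec(n_pops_speciesA = 3, n_pops_hybrid = 6, n_pops_speciesB = 3,
                 inds_per_pop = c(4, 6), n_loci = 60, frac_diagnostic = 0.2,
                 transect_extent_km = 1000, cline_centre_km = 500,
                 cline_width_km = 150, seed = 99, ...)
}
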