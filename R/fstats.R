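## Hierarchical F-statistics via three-level nested ANOVA on allele
## indicators (groups / populations within groups / alleles within
## populations), the standard variance-components estimator for
## hierarchically structured samples. Components are summed across loci
## for multi-locus estimates.

# Per-locus variance components from population allele frequencies.
# p: frequencies per population; n: allele sample sizes (2 x individuals);
# group: group label per population. Returns c(sa, sb, sw).
locus_varcomp <- function(p, n, group) {
  keep <- n > 0 & !is.na(p)
  p <- p[keep]; n <- n[keep]; group <- group[keep]
  G <- length(unique(group))
  P <- length(p)
  if (G < 2 || P <= G) return(c(sa = NA_real_, sb = NA_real_, sw = NA_real_))
  N <- sum(n)
  ng <- tapply(n, group, sum)
  pg <- tapply(n * p, group, sum) / ng
  pbar <- sum(n * p) / N
  ss_w <- sum(n * p * (1 - p))
  ss_b <- sum(n * (p - pg[group])^2)
  ss_a <- sum(ng * (pg - pbar)^2)
  ms_w <- ss_w / (N - P)
  ms_b <- ss_b / (P - G)
  ms_a <- ss_a / (G - 1)
  sum_np2_g <- tapply(n^2, group, sum) / ng
  nb <- (N - sum(sum_np2_g)) / (P - G)
  nbp <- (sum(sum_np2_g) - sum(n^2) / N) / (G - 1)
  na <- (N - sum(ng^2) / N) / (G - 1)
  sw <- ms_w
  sb <- (ms_b - ms_w) / nb
  sa <- (ms_a - ms_w - nbp * sb) / na
  c(sa = sa, sb = sb, sw = sw)
}

#' Hierarchical F-statistics (F_ST and F_CT)
#'
#' Partitions allelic variance among groups, among populations within
#' groups, and within populations, with multi-locus estimates obtained by
#' summing the per-locus variance components. Following the hierarchical
#' convention used for group-structured hybrid-zone data:
#' `F_CT = sigma2_groups / (sigma2_groups + sigma2_pops + sigma2_within)`
#' (differentiation among groups) and
#' `F_ST = sigma2_pops / (sigma2_pops + sigma2_within)` (differentiation
#' among populations within groups).
#'
#' @param g a [genotype_matrix] or plain loci x individuals 0/1/2 matrix.
#' @param pop,group per-individual population and group labels (default
#'   from `g$ind`); at least 2 groups with at least 2 populations each.
#' @return list with `F_ST`, `F_CT`, the summed variance components and the
#'   number of loci used; statistics are `NA` (flagged `undefined`) for a
#'   monomorphic dataset.
#' @export
hierarchical_fstats <- function(g, pop = NULL, group = NULL) {
  geno <- if (inherits(g, "genotype_matrix")) g$geno else g
  if (is.null(pop)) pop <- g$ind$pop_id
  if (is.null(group)) group <- g$ind$group
  stopifnot(length(pop) == ncol(geno), length(group) == ncol(geno))
  pg <- unique(data.frame(pop = pop, group = group, stringsAsFactors = FALSE))
  if (anyDuplicated(pg$pop)) abort("a population belongs to more than one group")
  if (length(unique(pg$group)) < 2) abort("need >= 2 groups")
  if (any(table(pg$group) < 2)) abort("need >= 2 populations per group")
  pop <- factor(pop, levels = pg$pop)
  cnt <- rowsum(t(geno), pop, na.rm = TRUE)                # pops x loci
  nonmiss <- rowsum(t(!is.na(geno)) + 0, pop)
  n_alleles <- 2 * nonmiss
  p <- as.matrix(ifelse(n_alleles > 0, cnt / n_alleles, NA_real_))
  comp <- matrix(NA_real_, ncol(p), 3, dimnames = list(NULL, c("sa", "sb", "sw")))
  for (l in seq_len(ncol(p))) {
    comp[l, ] <- locus_varcomp(p[, l], n_alleles[, l], pg$group)
  }
  ok <- complete.cases(comp)
  sa <- sum(comp[ok, "sa"]); sb <- sum(comp[ok, "sb"]); sw <- sum(comp[ok, "sw"])
  # negative summed components indicate absence of variance at that level;
  # they are truncated at zero in the ratios (raw sums are still reported)
  sa_t <- max(sa, 0); sb_t <- max(sb, 0); sw_t <- max(sw, 0)
  tot <- sa_t + sb_t + sw_t
  undefined <- !any(ok) || tot <= 0
  list(F_ST = if (undefined || (sb_t + sw_t) <= 0) NA_real_ else sb_t / (sb_t + sw_t),
       F_CT = if (undefined) NA_real_ else sa_t / tot,
       sigma2_groups = sa, sigma2_pops = sb, sigma2_within = sw,
       n_loci = sum(ok), undefined = undefined)
}
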