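test_that("window sets tile ordered populations with the stated overlap", {
  expect_length(window_sets(paste0("p", 1:34)), 11L)
  expect_length(window_sets(paste0("p", 1:4)), 1L)
  w7 <- window_sets(paste0("p", 1:7))
  expect_length(w7, 2L)
  expect_equal(w7[[1]]$pop_ids, paste0("p", 1:4))
  expect_equal(w7[[2]]$pop_ids, paste0("p", 4:7))
  expect_false(any(vapply(w7, `[[`, TRUE, "partial")))
  # consecutive sets share exactly one population
  w <- window_sets(paste0("p", 1:34))
  for (i in seq_len(length(w) - 1)) {
    expect_length(intersect(w[[i]]$pop_ids, w[[i + 1]]$pop_ids), 1L)
  }
  # non-divisible counts: trailing partial window flagged
  w6 <- window_sets(paste0("p", 1:6))
  expect_true(w6[[length(w6)]]$partial)
  expect_error(window_sets(paste0("p", 1:3)), "fewer")
  # ordering by distance when a population table is given
  tab <- data.frame(pop_id = c("b", "a", "d", "c"),
                    distance_km = c(10, 0, 30, 20))
  expect_equal(window_sets(tab)[[1]]$pop_ids, c("a", "b", "c", "d"))
  expect_equal(window_sets(tab)[[1]]$midpoint_km, 15)
})

test_that("the two-subpopulation worked example is exact", {
  g1 <- matrix(c(0.5, 0, 0, 0.5), 2, 2)   # AB / ab coupling gametes
  g2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)   # Ab / aB repulsion gametes
  comp <- ohta_components(list(g1, g2))
  expect_equal(comp$d2_is, 0.25)
  expect_equal(comp$d2_st, 0)
  expect_equal(comp$d2p_is, 0.25)
  expect_equal(comp$d2p_st, 0)
  expect_equal(comp$d2_it, 0.25)
})

test_that("degenerate structures zero the right components", {
  # identical subpops in linkage equilibrium: everything is zero
  le <- outer(c(0.3, 0.7), c(0.6, 0.4))
  z <- ohta_components(list(le, le, le))
  expect_true(all(abs(unlist(z[1:5])) < 1e-12))
  # identical subpops with LD: among-subpop allele-frequency variance is
  # absent (D2_ST = 0) and subpop gametes equal their mean (D'2_IS = 0),
  # while the within-subpop disequilibrium appears in D2_IS and, because
  # the mean gamete table itself is out of equilibrium, in D'2_ST
  ld <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  s <- ohta_components(list(ld, ld))
  expect_equal(s$d2_st, 0)
  expect_equal(s$d2p_is, 0)
  expect_gt(s$d2_is, 0)
  expect_gt(s$d2p_st, 0)
  expect_equal(s$d2_is, s$d2p_st)
  expect_error(ohta_components(list(ld)), ">= 2")
  expect_error(ohta_components(list(ld, ld * 2)), "sum to 1")
})

test_that("the partition identity and non-negativity hold on random tables", {
  set.seed(19)
  for (rep in seq_len(1000)) {
    K <- sample(2:5, 1)
    gam <- random_gamete_tables(K)
    comp <- ohta_components(gam)
    expect_lt(abs(comp$d2_it - (comp$d2p_is + comp$d2p_st)), 1e-10)
    expect_true(all(unlist(comp[1:5]) >= -1e-14))
  }
})

test_that("components match the brute-force double-loop oracle", {
  set.seed(23)
  for (rep in 1:50) {
    gam <- random_gamete_tables(sample(2:4, 1),
                                a1 = sample(2:3, 1), a2 = sample(2:3, 1))
    fast <- ohta_components(gam)
    slow <- slow_ohta(gam)
    for (nm in names(slow)) expect_equal(fast[[nm]], slow[[nm]], tolerance = 1e-12)
  }
})

test_that("the matrix profile path agrees with per-pair gamete tables", {
  spec <- tiny_spec()
  pl <- generate_landscape(spec)
  g <- generate_genotypes(spec, pl)
  loci <- g$loci$locus_id[g$loci$divergent]
  sets <- window_sets(pl)
  prof <- dis_dst_profile(g, pl, sets, loci, max_pairs = 10000, seed = 3)
  # recompute one window by explicit gamete tables
  set1 <- sets[[prof$set[1]]]
  gam <- hzmove:::subpop_gametes(g, set1$pop_ids, loci)
  pooled <- colMeans(do.call(rbind, gam))
  poly <- which(pooled > 0 & pooled < 1)
  pair_vals <- c()
  n_found <- 0
  for (a in seq_along(poly)) for (b in seq_along(poly)) {
    if (a >= b) next
    tabs <- lapply(gam, function(G) {
      ga <- G[, poly[a]]; gb <- G[, poly[b]]
      m <- matrix(0, 2, 2)
      for (i in 0:1) for (j in 0:1) m[i + 1, j + 1] <- mean(ga == i & gb == j)
      m
    })
    comp <- ohta_components(tabs)
    pair_vals <- rbind(pair_vals, c(comp$d2_is, comp$d2_st))
    n_found <- n_found + 1
  }
  expect_equal(prof$n_pairs[1], n_found)
  expect_equal(prof$d2_is[1], mean(pair_vals[, 1]), tolerance = 1e-10)
  expect_equal(prof$d2_st[1], mean(pair_vals[, 2]), tolerance = 1e-10)
})

test_that("profiles are deterministic under a fixed seed and flag no-variance sets", {
  spec <- tiny_spec()
  pl <- generate_landscape(spec)
  g <- generate_genotypes(spec, pl)
  loci <- g$loci$locus_id[g$loci$divergent]
  sets <- window_sets(pl)
  p1 <- dis_dst_profile(g, pl, sets, loci, max_pairs = 20, seed = 5)
  p2 <- dis_dst_profile(g, pl, sets, loci, max_pairs = 20, seed = 5)
  expect_identical(p1, p2)
  p3 <- dis_dst_profile(g, pl, sets, loci, max_pairs = 20, seed = 6)
  expect_false(identical(p1$d2_is, p3$d2_is))

  # one panmictic population duplicated four times: among-population LD
  # vanishes exactly and the ratio is flagged undefined
  set.seed(77)
  hapA <- matrix(rbinom(40 * 5, 1, 0.5), 40, 5)
  hapB <- matrix(rbinom(40 * 5, 1, 0.5), 40, 5)
  g1 <- structure(list(
    geno = cbind(hapA, hapA, hapA, hapA) + cbind(hapB, hapB, hapB, hapB),
    hapA = cbind(hapA, hapA, hapA, hapA),
    hapB = cbind(hapB, hapB, hapB, hapB),
    ind = data.frame(ind_id = paste0("i", 1:20),
                     pop_id = rep(paste0("P", 1:4), each = 5),
                     group = "hybrid", stringsAsFactors = FALSE)),
    class = "genotype_matrix")
  rownames(g1$geno) <- rownames(g1$hapA) <- rownames(g1$hapB) <- paste0("L", 1:40)
  colnames(g1$geno) <- colnames(g1$hapA) <- colnames(g1$hapB) <- g1$ind$ind_id
  pops1 <- data.frame(pop_id = paste0("P", 1:4), distance_km = c(0, 10, 20, 30))
  sets1 <- window_sets(pops1)
  pr <- dis_dst_profile(g1, pops1, sets1, paste0("L", 1:40), seed = 1)
  expect_equal(pr$d2_st[1], 0, tolerance = 1e-12)
  expect_true(is.na(pr$ratio[1]))
})

test_that("EM gamete frequencies recover the phased truth under random mating", {
  set.seed(41)
  f <- c(`00` = 0.35, `01` = 0.15, `10` = 0.1, `11` = 0.4)  # gametes with LD
  n <- 400
  draw <- sample(names(f), 2 * n, replace = TRUE, prob = f)
  h1 <- draw[1:n]; h2 <- draw[(n + 1):(2 * n)]
  g1 <- as.integer(substr(h1, 1, 1)) + as.integer(substr(h2, 1, 1))
  g2 <- as.integer(substr(h1, 2, 2)) + as.integer(substr(h2, 2, 2))
  est <- hzmove:::em_gamete_freqs(g1, g2)
  emp <- table(factor(c(h1, h2), names(f))) / (2 * n)
  expect_equal(est["0", "0"], unname(emp["00"]), tolerance = 0.05)
  expect_equal(est["1", "1"], unname(emp["11"]), tolerance = 0.05)
  expect_equal(sum(est), 1, tolerance = 1e-8)
})

test_that("neutral bootstrap resamples reproduce the plain profile in the limit", {
  spec <- tiny_spec()
  pl <- generate_landscape(spec)
  g <- generate_genotypes(spec, pl)
  loci <- g$loci$locus_id[!g$loci$divergent][1:20]
  sets <- window_sets(pl)[1:3]
  plain <- dis_dst_profile(g, pl, sets, loci, seed = 2)
  bs <- bootstrap_neutral(g, pl, sets, loci, n_sets = 3, max_pairs = 1000,
                          seed = 2)
  expect_length(bs$profiles, 3L)
  expect_true(all(c("ratio.mean", "ratio.sd") %in% names(bs$summary)))
  # resamples differ from each other but share the window structure
  expect_equal(bs$profiles[[1]]$midpoint_km, plain$midpoint_km)
  expect_warning(bootstrap_neutral(g, pl, sets, loci, n_sets = 1,
                                   set_size = 40, seed = 1),
                 "replacement")
})
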