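test_that("the landscape places ordered group bands at increasing latitude", {
  spec <- synthetic_spec(seed = 2)
  pl <- generate_landscape(spec)
  expect_equal(nrow(pl), 34L)
  expect_true(all(diff(pl$lat) > 0))
  expect_equal(rle(pl$group)$values, c("speciesA", "hybrid", "speciesB"))
  expect_equal(sum(pl$distance_km == 0), 1L)

  one <- synthetic_spec(n_pops_speciesA = 1, n_pops_hybrid = 1,
                        n_pops_speciesB = 1, seed = 5)
  pl1 <- generate_landscape(one)
  expect_equal(nrow(pl1), 3L)
  expect_true(all(diff(pl1$lat) > 0))

  expect_error(synthetic_spec(n_pops_hybrid = 0), "> 0")
})

test_that("fixing the seed fixes every emitted value", {
  spec <- synthetic_spec(n_loci = 80, seed = 31)
  a <- generate_landscape(spec); b <- generate_landscape(spec)
  expect_identical(a, b)
  ga <- generate_genotypes(spec, a); gb <- generate_genotypes(spec, b)
  expect_identical(ga$geno, gb$geno)
  expect_identical(ga$hapA, gb$hapA)
  ta <- generate_traits(spec, a); tb <- generate_traits(spec, b)
  expect_identical(ta, tb)
  # a different seed changes the data
  spec2 <- synthetic_spec(n_loci = 80, seed = 32)
  expect_false(identical(generate_genotypes(spec2, generate_landscape(spec2))$geno,
                         ga$geno))
})

test_that("parental individuals carry near-pure ancestry at divergent loci", {
  # centre mid-zone and a narrow width, so both parental bands are far
  # from the transition and effectively pure
  spec <- synthetic_spec(n_loci = 200, fst_noise = 0.05,
                         admix_concentration = 50, cline_centre_km = 1000,
                         cline_width_km = 100, seed = 12)
  pl <- generate_landscape(spec)
  g <- generate_genotypes(spec, pl)
  div <- g$loci$divergent
  # orient doses to the species-B allele using the generator's truth
  doseB <- g$geno[div, , drop = FALSE]
  flip <- g$loci$pA[div] > g$loci$pB[div]
  doseB[flip, ] <- 2 - doseB[flip, ]
  a_ind <- g$ind$group == "speciesA"
  b_ind <- g$ind$group == "speciesB"
  expect_lt(mean(doseB[, a_ind]) / 2, 0.05)
  expect_gt(mean(doseB[, b_ind]) / 2, 0.95)
})

test_that("expected diagnostic dose follows the ancestry sigmoid", {
  # near-deterministic limit: tiny divergence noise, huge admixture
  # concentration, so the dose expectation is 2 x sigmoid(position)
  spec <- synthetic_spec(n_loci = 400, fst_noise = 0.01,
                         admix_concentration = 2000,
                         inds_per_pop = c(10, 10), seed = 8)
  pl <- generate_landscape(spec)
  g <- generate_genotypes(spec, pl)
  div <- which(g$loci$divergent)
  doseB <- g$geno[div, , drop = FALSE]
  flip <- g$loci$pA[div] > g$loci$pB[div]
  doseB[flip, ] <- 2 - doseB[flip, ]
  mid <- which(abs(g$ind$distance_km - spec$cline_centre_km) <
                 0.5 * spec$cline_width_km)
  expect_gt(length(mid), 0)
  expected <- 2 * (1 + tanh(2 * (g$ind$distance_km[mid] - spec$cline_centre_km) /
                              spec$cline_width_km)) / 2
  expect_equal(mean(doseB[, mid]), mean(expected), tolerance = 0.1)
})

test_that("the diagnostic filter recovers the planted divergent loci", {
  spec <- synthetic_spec(n_loci = 2000, frac_diagnostic = 0.1, seed = 7)
  pl <- generate_landscape(spec)
  g <- generate_genotypes(spec, pl)
  gf <- group_allele_freqs(g)
  ds <- select_diagnostic(setNames(gf[, "speciesA"], rownames(gf)),
                          setNames(gf[, "speciesB"], rownames(gf)))
  truth <- g$loci$locus_id[g$loci$divergent]
  recovery <- mean(truth %in% ds$loci)
  expect_gte(recovery, 0.9)
})

test_that("trait clines interpolate the parental means", {
  td <- data.frame(trait = "t", mean_A = 8, mean_B = 12, sd = 1)
  spec <- synthetic_spec(trait_defs = td, cline_centre_km = 1000,
                         trait_width_km = 400, trait_centre_offset_km = 0,
                         transect_extent_km = 2000, seed = 3)
  pl <- generate_landscape(spec)
  tr <- generate_traits(spec, pl)
  # tanh evaluation at x = 1200: 8 + 4 (1 + tanh(1)) / 2
  expect_equal(8 + 4 * (1 + tanh(1)) / 2, 11.523, tolerance = 1e-3)
  i <- which.min(abs(tr$distance_km - 1200))
  expect_equal(tr$true_mean[i],
               8 + 4 * (1 + tanh(2 * (tr$distance_km[i] - 1000) / 400)) / 2)
  # centre symmetry: the expected mean at the centre is the midpoint
  j <- which.min(abs(tr$distance_km - 1000))
  expect_equal(tr$true_mean[j], 10, tolerance = 0.4)

  # SD -> 0 collapses population means onto the cline
  td0 <- data.frame(trait = "t", mean_A = 8, mean_B = 12, sd = 1e-9)
  spec0 <- synthetic_spec(trait_defs = td0, cline_centre_km = 1000,
                          trait_width_km = 400, transect_extent_km = 2000,
                          seed = 3)
  tr0 <- generate_traits(spec0, generate_landscape(spec0))
  expect_equal(tr0$mean, tr0$true_mean, tolerance = 1e-6)

  expect_error(synthetic_spec(trait_defs = data.frame(
    trait = "t", mean_A = 1, mean_B = 2, sd = 0)), "SD")
  expect_error(synthetic_spec(trait_defs = data.frame(
    trait = "t", mean_A = 2, mean_B = 2, sd = 1)), "differ")
})

test_that("hybrid mosaics carry positive within-population LD on average", {
  # admixture variance within populations induces gametic association
  # between divergent loci; averaged over replicate data sets it is > 0
  d_vals <- numeric(30)
  for (r in seq_len(30)) {
    spec <- synthetic_spec(n_pops_speciesA = 2, n_pops_hybrid = 4,
                           n_pops_speciesB = 2, inds_per_pop = c(8, 8),
                           n_loci = 40, frac_diagnostic = 0.5,
                           admix_concentration = 3, fst_noise = 0.05,
                           transect_extent_km = 1000, cline_centre_km = 500,
                           cline_width_km = 400, seed = 1000 + r)
    pl <- generate_landscape(spec)
    g <- generate_genotypes(spec, pl)
    div <- which(g$loci$divergent)
    hyb_pop <- pl$pop_id[pl$group == "hybrid"][2]
    ind <- which(g$ind$pop_id == hyb_pop)
    ga <- t(cbind(g$hapA[div, ind], g$hapB[div, ind]))
    # orient to species-B allele so D > 0 means co-inherited ancestry
    flip <- g$loci$pA[div] > g$loci$pB[div]
    ga[, flip] <- 1 - ga[, flip]
    p <- colMeans(ga)
    keep <- p > 0 & p < 1
    ga <- ga[, keep, drop = FALSE]
    if (ncol(ga) < 2) { d_vals[r] <- NA; next }
    P11 <- crossprod(ga) / nrow(ga)
    D <- P11 - outer(colMeans(ga), colMeans(ga))
    d_vals[r] <- mean(D[upper.tri(D)])
  }
  expect_gt(mean(d_vals, na.rm = TRUE), 0)
})
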