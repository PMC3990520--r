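test_that("haploid pool generation is deterministic and polymorphic", {
  map <- uniform_map(1000)
  p1 <- generate_haploid_pool(20, map, seed = 71)
  p2 <- generate_haploid_pool(20, map, seed = 71)
  expect_identical(p1$haplotypes, p2$haplotypes)
  f <- colMeans(p1$haplotypes)
  expect_true(all(f > 0 & f < 1))
  # degenerate mosaic: one template, no mutation: all haplotypes identical
  p3 <- generate_haploid_pool(8, uniform_map(50), n_templates = 1,
                              mut_rate = 0, seed = 3)
  expect_equal(nrow(unique(p3$haplotypes)), 1)
  expect_error(generate_haploid_pool(3, map), "at least 4")
  expect_error(generate_haploid_pool(5, map), "even")
})

test_that("realised relatedness behaves like twice the kinship", {
  set.seed(73)
  L <- 5000
  p <- runif(L, 0.1, 0.9)
  g1 <- rbinom(L, 2, p); g2 <- rbinom(L, 2, p)
  expect_lt(abs(relatedness(g1, g2, p)), 0.05)
  expect_equal(relatedness(g1, g2, p), relatedness(g2, g1, p))
  expect_equal(relatedness(g1, g1, p), 1, tolerance = 0.1)
  expect_error(relatedness(c(0, 1), c(1, 0), c(0, 1)), "polymorphic")
})

test_that("founder construction respects pool capacity and rejection", {
  map <- uniform_map(300)
  pool <- generate_haploid_pool(464, map, seed = 79)
  f <- make_founders(pool, relatedness_threshold = 1, seed = 1)
  expect_equal(nrow(f$h1), 232)
  expect_false(any(duplicated(as.vector(f$sources))))
  expect_error(make_founders(pool, n_diploids = 300), "at most")
  # unsatisfiable threshold fails loudly after the attempt budget
  expect_error(make_founders(pool, relatedness_threshold = -2,
                             seed = 1, max_attempts = 3), "rejection")
})

test_that("meiosis follows the sex-scaled Poisson crossover process", {
  # map of length zero: gamete equals one parental haplotype
  pos <- seq(1e5, by = 1e4, length.out = 20)
  flat <- genetic_map(pos, cum_cM = rep(0, 20), chrom = "X")
  ph <- rbind(rep(0L, 20), rep(1L, 20))
  m0 <- simulate_meiosis(ph, flat, sex = "female", seed = 9)
  expect_equal(nrow(m0$crossovers), 0)
  expect_true(all(m0$gamete == 0L) || all(m0$gamete == 1L))
  # crossover counts: mean matches the map length in Morgans per sex
  map1 <- uniform_map(11, spacing = 1e6, cM_per_Mb = 10)  # 100 cM
  ph2 <- rbind(rep(0L, 11), rep(1L, 11))
  set.seed(81)
  n_f <- replicate(3000, nrow(simulate_meiosis(ph2, map1,
                                               sex = "female")$crossovers))
  n_m <- replicate(3000, nrow(simulate_meiosis(ph2, map1, sex = "male")$crossovers))
  expect_equal(mean(n_f), 1.0, tolerance = 0.06)
  expect_equal(mean(n_m) / mean(n_f), 0.605, tolerance = 0.12)
})

test_that("trio cohort arithmetic and truth reconstruction", {
  map <- uniform_map(400)
  pool <- generate_haploid_pool(8, map, seed = 83)
  cohort <- build_trio_cohort(pool, map, seed = 83)
  expect_equal(sum(startsWith(rownames(cohort$truth_h1), "CH")), 2)
  # every child's haplotypes reconstruct from parents + recorded crossovers
  for (row in seq_len(nrow(cohort$transmissions))) {
    tx <- cohort$transmissions[row, ]
    smap <- if (tx$parent_sex == "male") sex_scale(map, "male") else map
    cm <- interpolate_cM(smap, cohort$positions)
    xs <- sort(cohort$crossovers$cM[cohort$crossovers$parent == tx$parent &
                                      cohort$crossovers$child == tx$child])
    src <- 1L + (tx$start_hap - 1L + findInterval(cm, xs, left.open = TRUE)) %% 2L
    ph <- rbind(cohort$truth_h1[tx$parent, ], cohort$truth_h2[tx$parent, ])
    rec <- ph[cbind(src, seq_along(cm))]
    got <- if (tx$parent_sex == "male") cohort$truth_h1[tx$child, ]
    else cohort$truth_h2[tx$child, ]
    expect_equal(as.integer(rec), as.integer(got))
  }
  # genotypes are haplotype sums
  expect_equal(cohort$genotypes, cohort$truth_h1 + cohort$truth_h2,
               ignore_attr = TRUE)
})

test_that("pedigree-structure cohorts honour drop flags and reconstruct", {
  map <- uniform_map(300)
  pool <- generate_haploid_pool(16, map, seed = 89)
  structure <- pedigree(data.frame(
    family = "F", id = c("gp", "gm", "m2", "p", "c"),
    father = c(NA, NA, NA, "gp", "p"), mother = c(NA, NA, NA, "gm", "m2"),
    genotyped = c(FALSE, TRUE, TRUE, TRUE, TRUE), stringsAsFactors = FALSE))
  cohort <- build_pedigree_cohort(pool, list(structure), map,
                                  drop_ungenotyped_founders = TRUE, seed = 89)
  expect_false(cohort$ped$genotyped[cohort$ped$id == "gp"])
  haps <- cohort_haplotypes(cohort, genotyped_only = TRUE)
  expect_false("gp" %in% hap_samples(haps))
  expect_true("gp" %in% rownames(cohort$truth_h1))
  # grandchild truth reconstructible through two generations
  expect_equal(cohort$truth_h1["c", ] + cohort$truth_h2["c", ],
               cohort$genotypes["c", ], ignore_attr = TRUE)
})

test_that("confusion-matrix corruption matches the specified rates", {
  map <- uniform_map(500)
  pool <- generate_haploid_pool(80, map, seed = 97)
  cohort <- build_trio_cohort(pool, map, seed = 97)
  # identity matrix: unchanged
  ident <- diag(4)
  same <- apply_genotype_errors(cohort, ident, seed = 1)
  expect_equal(same$genotypes, cohort$genotypes)
  expect_equal(nrow(same$error_sites), 0)
  # 1% off-diagonal mass: observed error fraction close to 1%
  cm <- default_confusion_matrix(error = 0.01, missing_rate = 0)
  cor1 <- apply_genotype_errors(cohort, cm, seed = 2)
  n_g <- length(cohort$genotypes)
  frac <- nrow(cor1$error_sites) / n_g
  expect_equal(frac, 0.01, tolerance = 3 * sqrt(0.01 / n_g) / 0.01)
  # missing-only corruption: missingness rate matches the matrix column
  cm_miss <- default_confusion_matrix(error = 0, missing_rate = 0.02)
  cor2 <- apply_genotype_errors(cohort, cm_miss, seed = 3)
  expect_equal(mean(is.na(cor2$genotypes)), 0.02,
               tolerance = 3 * sqrt(0.02 / n_g) / 0.02)
  # observed haplotypes stay consistent with observed genotypes
  gsum <- cor1$obs_h1 + cor1$obs_h2
  expect_equal(gsum[!is.na(cor1$genotypes)],
               cor1$genotypes[!is.na(cor1$genotypes)])
  expect_error(apply_genotype_errors(cohort, matrix(1, 4, 4)), "sum to 1")
})

test_that("switch-error injection respects IBD support and id restriction", {
  map <- uniform_map(400)
  pool <- generate_haploid_pool(40, map, n_templates = 2, switch_rate = 0.02,
                                mut_rate = 0, seed = 101)
  cohort <- build_trio_cohort(pool, map, seed = 101)
  # a two-template zero-mutation pool shares long segments across families:
  # IBD-aware injection suppresses nearly all candidate errors
  aware <- inject_switch_errors(cohort, rate = 0.5, ibd_aware = TRUE,
                                window = 10, seed = 7)
  blind <- inject_switch_errors(cohort, rate = 0.5, ibd_aware = FALSE,
                                seed = 7)
  expect_lt(nrow(aware$switch_sites), 0.1 * nrow(blind$switch_sites))
  # non-IBD-aware injection hits only the requested individual
  het_counts <- rowSums(cohort$obs_h1 != cohort$obs_h2)
  target <- names(which.max(het_counts))
  some <- inject_switch_errors(cohort, rate = 0.2, ibd_aware = FALSE,
                               ids = target, seed = 7)
  expect_true(nrow(some$switch_sites) > 0)
  expect_equal(unique(some$switch_sites$id), target)
  # genotypes are preserved by switching
  expect_equal(some$obs_h1 + some$obs_h2, cohort$obs_h1 + cohort$obs_h2)
})
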