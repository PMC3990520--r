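test_that("switch error counts discordant adjacent heterozygote pairs", {
  set.seed(111)
  L <- 50
  truth <- rbind(sample(0:1, L, TRUE), sample(0:1, L, TRUE))
  expect_equal(as.numeric(switch_error(truth, truth)), 0)
  # single flip after the k-th heterozygote: 1/(H-1)
  het <- which(truth[1, ] != truth[2, ])
  est <- truth
  flip_at <- het[5]
  est[, flip_at:L] <- est[2:1, flip_at:L]
  expect_equal(as.numeric(switch_error(est, truth)), 1 / (length(het) - 1))
  # invariant to globally swapping the estimated haplotypes
  expect_equal(as.numeric(switch_error(est[2:1, ], truth)),
               as.numeric(switch_error(est, truth)))
  # random phase: about one half
  L2 <- 20001
  truth2 <- rbind(rep(0L, L2), rep(1L, L2))
  est2 <- apply(truth2, 2, sample)
  expect_equal(as.numeric(switch_error(est2, truth2)), 0.5, tolerance = 0.03)
  # fewer than two usable het sites: flagged undefined
  expect_warning(out <- switch_error(rbind(0, 1), rbind(0, 1)))
  expect_true(is.na(out))
})

test_that("crossover accuracy counts greedy one-to-one containment", {
  truth <- data.frame(pos = seq(100, 1000, by = 100))
  calls <- data.frame(left_pos = truth$pos[1:9] - 10,
                      right_pos = truth$pos[1:9] + 10,
                      posterior = 0.9)
  stray <- data.frame(left_pos = 5000, right_pos = 5010, posterior = 0.9)
  acc <- crossover_accuracy(rbind(calls, stray), truth, thresholds = 0)
  expect_equal(acc$tpr, 0.9)
  expect_equal(acc$fdr, 0.1)
  # perfect bracketing: TPR 1, FDR 0
  perf <- data.frame(left_pos = truth$pos - 1, right_pos = truth$pos + 1,
                     posterior = 1)
  acc2 <- crossover_accuracy(perf, truth, thresholds = 0)
  expect_equal(acc2$tpr, 1)
  expect_equal(acc2$fdr, 0)
  # no calls at all: TPR 0 and FDR 0 by convention
  acc3 <- crossover_accuracy(perf, truth, thresholds = 1.5)
  expect_equal(acc3$tpr, 0)
  expect_equal(acc3$fdr, 0)
  # one wide call cannot absorb two events
  wide <- data.frame(left_pos = 0, right_pos = 2000, posterior = 1)
  acc4 <- crossover_accuracy(wide, truth, thresholds = 0)
  expect_equal(acc4$tp, 1)
  # monotone: raising the threshold never increases TPR
  set.seed(113)
  calls5 <- data.frame(left_pos = runif(50, 0, 900),
                       posterior = runif(50))
  calls5$right_pos <- calls5$left_pos + 150
  acc5 <- crossover_accuracy(calls5, truth, thresholds = seq(0, 1, 0.1))
  expect_true(all(diff(acc5$tpr) <= 1e-12))
})

test_that("count calibration detects Poisson dispersion", {
  set.seed(115)
  counts <- rpois(5000, 42.81)
  out <- count_calibration(counts, 42.81)
  expect_equal(out$dispersion, 1, tolerance = 0.1)
  expect_lt(max(abs(out$qq$expected - out$qq$observed)), 6)
  expect_equal(count_calibration(rep(7L, 10), 7)$dispersion, 0)
  expect_error(count_calibration(integer(0), 5), "no counts")
  expect_error(count_calibration(c(-1L, 2L), 5))
})

test_that("BED hotspots convert to 1-based inclusive intervals", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("X\t100\t200", "X\t400\t500"), path)
  hs <- read_hotspots(path)
  expect_equal(hs$start, c(101, 401))
  expect_equal(hs$end, c(200, 500))
})

test_that("hotspot usage is chance-corrected against the genetic map", {
  map <- uniform_map(1001, spacing = 1e4, cM_per_Mb = 10)
  events <- data.frame(parent = rep(c("a", "b"), c(10, 5)),
                       left_pos = seq(2e5, by = 7e4, length.out = 15))
  events$right_pos <- events$left_pos + 1e4
  # hotspots covering everything: raw proportion 1 for every parent
  all_hs <- data.frame(start = 1, end = 2e7)
  hu <- hotspot_usage(events, all_hs, map, n_null_sims = 100, seed = 1)
  expect_equal(hu$raw, c(1, 1))
  # empty hotspot set: raw 0
  none <- hotspot_usage(events, data.frame(start = numeric(),
                                           end = numeric()),
                        map, n_null_sims = 50, seed = 1)
  expect_equal(none$raw, c(0, 0))
  expect_equal(none$y, c(0, 0))
  # uniform map: chance proportion matches the covered length fraction
  half <- data.frame(start = 1e5, end = 1e5 + (1e7 - 1e5) * 0.25)
  hu2 <- hotspot_usage(events, half, map, n_null_sims = 4000, seed = 2)
  expect_equal(hu2$chance[1], 0.25, tolerance = 3 * sqrt(0.25 * 0.75 / 4000) / 0.25)
  expect_true(all(hu2$y <= hu2$n))
})

test_that("binomial GLM association controls the null and detects effects", {
  set.seed(117)
  sim_pheno <- function(n, beta) {
    dosage <- rbinom(n, 2, 0.3)
    n_i <- rpois(n, 30)
    p <- plogis(qlogis(0.3) + beta * dosage)
    data.frame(parent = paste0("p", seq_len(n)), n = n_i,
               y = rbinom(n, n_i, p), dosage = dosage)
  }
  # strong effect: very small p-values at n = 500
  ps <- replicate(11, {
    d <- sim_pheno(500, 1)
    hotspot_association(d[c("parent", "n", "y")],
                        data.frame(id = d$parent, dosage = d$dosage))$p
  })
  expect_lt(median(ps), 1e-4)
  # boundary response is flagged
  d0 <- sim_pheno(100, 0)
  d0$y <- 0
  out <- hotspot_association(d0[c("parent", "n", "y")],
                             data.frame(id = d0$parent, dosage = d0$dosage))
  expect_true(out$flagged)
  expect_true(is.na(out$p))
  # degenerate dosage is flagged
  d1 <- sim_pheno(50, 0)
  d1$dosage <- 1
  expect_true(hotspot_association(d1[c("parent", "n", "y")],
                                  data.frame(id = d1$parent,
                                             dosage = d1$dosage))$flagged)
})
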