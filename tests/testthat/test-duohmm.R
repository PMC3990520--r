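test_that("transition matrix partitions into the four gene-flow sets", {
  sets <- transition_sets()
  expect_equal(as.vector(table(sets)), c(4L, 4L, 4L, 4L))
  A <- build_transition(0.01, 0.1, 0.2)
  q <- 0.1 * 0.99 + 0.01 * 0.9
  expect_equal(q, 0.108)
  expect_equal(unique(A[sets == "T1"]), (1 - q) * 0.8)
  expect_equal(unique(A[sets == "T2"]), q * 0.8)
  expect_equal(unique(A[sets == "T3"]), (1 - q) * 0.2)
  expect_equal(unique(A[sets == "T4"]), q * 0.2)
  expect_equal(rowSums(A), rep(1, 4), ignore_attr = TRUE)
  expect_equal(build_transition(0, 0, 0), diag(4), ignore_attr = TRUE)
  expect_error(build_transition(0.6, 0.1, 0.1))
  # any valid parameters: rows sum to 1
  for (i in 1:5) {
    A <- build_transition(runif(1, 0, 0.5), runif(1, 0, 0.5), runif(1, 0, 0.5))
    expect_equal(rowSums(A), rep(1, 4), ignore_attr = TRUE)
  }
})

test_that("emission probabilities follow the consistent/inconsistent rule", {
  expect_equal(emission_prob(c(0, 1), c(0, 1), "A", 0.01), 0.99)
  expect_equal(emission_prob(c(0, 1), c(1, 0), "A", 0.01), 0.01)
  expect_equal(emission_prob(c(0, 1), c(NA, 0), 1, 0.01), 1)
  expect_equal(emission_prob(c(NA, 1), c(0, 0), 1, 0.01), 1)
  # state D compares parent hap 2 with child hap 2
  expect_equal(emission_prob(c(0, 1), c(0, 1), "D", 0.05), 0.95)
})

test_that("forward-backward matches exhaustive enumeration", {
  set.seed(11)
  for (i in 1:25) {
    L <- sample(3:7, 1)
    duo <- random_duo(L, p_missing = ifelse(i %% 3 == 0, 0.2, 0))
    params <- random_params(L)
    fb <- forward_backward(duo, params)
    expect_equal(fb$loglik, oracle_loglik(duo, params), tolerance = 1e-12)
    expect_equal(fb$gamma, oracle_gamma(duo, params), tolerance = 1e-10)
    expect_equal(colSums(fb$gamma), rep(1, L), tolerance = 1e-9,
                 ignore_attr = TRUE)
    cnt <- oracle_transition_counts(duo, params)
    expect_equal(sum(fb$xi_parent), unname(cnt["parent"]), tolerance = 1e-10)
    expect_equal(sum(fb$xi_child), unname(cnt["child"]), tolerance = 1e-10)
  }
})

test_that("a perfect IBD copy concentrates posterior mass on one state", {
  # child hap 1 copies parent hap 1; every other pairing is discordant at
  # several loci (note a full complement copy would be indistinguishable)
  P <- rbind(c(0, 1, 0, 1, 0), c(1, 1, 1, 1, 1))
  C <- rbind(P[1, ], c(0, 0, 0, 0, 0))
  duo <- duo_haplotypes("p", "c", "male", P, C, pos = (1:5) * 1e6)
  params <- duohmm_params(1e-3, 1e-3, 0.01, rho = rep(1e-3, 4))
  fb <- forward_backward(duo, params)
  expect_true(all(fb$gamma[1, ] >= 0.95))
  expect_equal(which.max(rowSums(fb$gamma)), 1L)
})

test_that("all-missing data leaves the chain uninformative", {
  L <- 4
  duo <- duo_haplotypes("p", "c", "male", matrix(NA, 2, L), matrix(NA, 2, L),
                        pos = seq(1e6, by = 1e5, length.out = L))
  params <- duohmm_params(0.01, 0.01, 0.01, rho = rep(0.01, L - 1))
  fb <- forward_backward(duo, params)
  expect_equal(fb$gamma, matrix(0.25, 4, L), tolerance = 1e-12)
  expect_equal(fb$loglik, log(1), tolerance = 1e-12)
  expect_error(forward_backward(duo_haplotypes(
    "p", "c", "male", matrix(0, 2, 1), matrix(0, 2, 1), pos = 1), params),
    "at least 2")
})

test_that("viterbi path attains the enumeration maximum", {
  set.seed(13)
  for (i in 1:15) {
    L <- sample(3:8, 1)
    duo <- random_duo(L)
    params <- random_params(L)
    v <- viterbi(duo, params)
    expect_equal(attr(v, "logp"), oracle_viterbi_logp(duo, params),
                 tolerance = 1e-10)
  }
  # perfect single-IBD duo: constant path
  duo <- clean_duo(6, seed = 3)
  duo$P[2, ] <- 1 - duo$C[1, ]
  duo$C[2, ] <- 1 - duo$P[1, ]
  params <- duohmm_params(1e-3, 1e-3, 0.01, rho = rep(1e-3, 5))
  expect_equal(unique(as.integer(viterbi(duo, params))), 1L)
})

test_that("single-iteration estimation recovers injected switch rates", {
  # perfect duo, no events: estimates collapse to the lower clamp
  duo <- clean_duo(60, seed = 4)
  est <- estimate_params(duo, init = duohmm_params(0.01, 0.01, 0.01,
                                                   rho = rep(1e-4, 59)))
  # one update from the prior leaves only residual posterior mass
  expect_lt(est$theta_c, 1e-3)
  expect_lt(est$epsilon, 1e-3)
  # one injected child switch in a 100-marker duo: theta_c near 1/99
  set.seed(5)
  duo <- clean_duo(100, seed = 5)
  duo2 <- flip_child_from(duo, 50)
  est2 <- estimate_params(duo2, init = duohmm_params(0.01, 0.01, 0.01,
                                                     rho = rep(1e-4, 99)))
  expect_equal(est2$theta_c, 1 / 99, tolerance = 0.15)
  # rho is never re-estimated
  expect_equal(est2$rho, rep(1e-4, 99))
})

test_that("label symmetry: swapping a haplotype pair leaves likelihood unchanged", {
  set.seed(17)
  for (i in 1:5) {
    L <- 6
    duo <- random_duo(L)
    params <- random_params(L)
    ll <- forward_backward(duo, params)$loglik
    duo_p <- duo; duo_p$P <- duo$P[2:1, ]
    expect_equal(forward_backward(duo_p, params)$loglik, ll,
                 tolerance = 1e-12)
    duo_c <- duo; duo_c$C <- duo$C[2:1, ]
    expect_equal(forward_backward(duo_c, params)$loglik, ll,
                 tolerance = 1e-12)
  }
})

test_that("recombination posteriors match the joint enumeration oracle", {
  set.seed(19)
  n_checked <- 0
  for (i in 1:15) {
    L <- sample(4:7, 1)
    duo <- random_duo(L)
    params <- random_params(L)
    fb <- forward_backward(duo, params)
    rp <- recombination_posteriors(duo, fb, params)
    for (k in seq_len(nrow(rp))) {
      expect_equal(rp$posterior[k],
                   oracle_recomb_posterior(duo, params, rp$left_index[k],
                                           rp$right_index[k]),
                   tolerance = 1e-10)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("recombination interval structure and trivial cases", {
  # fully homozygous parent: no resolvable interval
  L <- 6
  duo <- duo_haplotypes("p", "c", "male", matrix(1, 2, L),
                        matrix(sample(0:1, 2 * L, TRUE), 2),
                        pos = seq(1e6, by = 1e5, length.out = L))
  params <- duohmm_params(0.01, 0.01, 0.01, rho = rep(0.01, L - 1))
  fb <- forward_backward(duo, params)
  expect_equal(nrow(recombination_posteriors(duo, fb, params)), 0)
  # clean duo with no IBD change: all posteriors stay near the map prior
  duo <- clean_duo(40, seed = 23)
  est <- estimate_params(duo, init = duohmm_params(0.01, 0.01, 0.01,
                                                   rho = rep(1e-3, 39)))
  rp <- recombination_posteriors(duo, attr(est, "fb"), est)
  expect_true(all(rp$posterior < 0.05))
  # interval endpoints are parent-heterozygous with only homozygous between
  het <- which(duo$P[1, ] != duo$P[2, ])
  expect_equal(rp$left_index, het[-length(het)])
  expect_equal(rp$right_index, het[-1])
})

test_that("a clean parental IBD change yields a confident localized call", {
  set.seed(29)
  L <- 120
  duo <- clean_duo(L, seed = 29)
  # recombination: child hap 1 switches from parent hap 1 to hap 2 at locus 60
  duo$C[1, 60:L] <- duo$P[2, 60:L]
  params <- duohmm_params(1e-5, 1e-5, 1e-3, rho = rep(5e-3, L - 1))
  fb <- forward_backward(duo, params)
  rp <- recombination_posteriors(duo, fb, params)
  containing <- rp[rp$left_index < 60 & rp$right_index >= 60, ]
  expect_equal(nrow(containing), 1)
  expect_gte(containing$posterior, 0.95)
  expect_true(all(rp$posterior[rp$right_index < 60 | rp$left_index >= 60] < 0.05))
})

test_that("thresholding keeps and orders calls correctly", {
  calls <- data.frame(parent = "p", child = "c", parent_sex = "male",
                      left_index = 1:3, right_index = 2:4,
                      left_pos = c(30, 10, 20), right_pos = c(35, 15, 25),
                      posterior = c(0.8, 0.65, 0.2))
  kept <- call_recombinations(calls, 0.7)
  expect_equal(kept$posterior, 0.8)
  expect_equal(nrow(call_recombinations(calls, 1)), 0)
  expect_equal(nrow(call_recombinations(calls, 1e-6)), 3)
  expect_equal(call_recombinations(calls, 1e-6)$left_pos, c(10, 20, 30))
  expect_error(call_recombinations(calls, 0), "threshold")
})

test_that("genotype error posteriors flag isolated inconsistencies", {
  set.seed(31)
  for (i in 1:5) {
    L <- sample(4:7, 1)
    duo <- random_duo(L)
    params <- random_params(L)
    fb <- forward_backward(duo, params)
    ep <- genotype_error_posteriors(duo, fb)
    expect_equal(ep$posterior, oracle_error_posterior(duo, params),
                 tolerance = 1e-10)
  }
  # single mismatching locus inside a long perfect IBD stretch
  L <- 40
  duo <- clean_duo(L, seed = 37)
  duo$P[2, ] <- 1 - duo$C[1, ]
  duo$C[2, ] <- 1 - duo$P[1, ]
  duo$C[1, 20] <- 1 - duo$C[1, 20]
  duo$C[2, 20] <- 1 - duo$C[2, 20]
  params <- duohmm_params(1e-4, 1e-4, 0.01, rho = rep(1e-4, L - 1))
  fb <- forward_backward(duo, params)
  ep <- genotype_error_posteriors(duo, fb)
  expect_gte(ep$posterior[20], 0.9)
  expect_true(all(ep$posterior[-20] < 0.05))
  # all-missing locus has zero observable inconsistency
  duo$P[, 10] <- NA; duo$C[, 10] <- NA
  fb <- forward_backward(duo, params)
  expect_equal(genotype_error_posteriors(duo, fb)$posterior[10], 0)
})

test_that("runtime scales roughly linearly in the number of markers", {
  duo1 <- clean_duo(2000, seed = 41)
  duo2 <- clean_duo(8000, seed = 43)
  params1 <- duohmm_params(0.01, 0.01, 0.01, rho = rep(1e-4, 1999))
  params2 <- duohmm_params(0.01, 0.01, 0.01, rho = rep(1e-4, 7999))
  t1 <- system.time(for (r in 1:3) forward_backward(duo1, params1))[["elapsed"]]
  t2 <- system.time(for (r in 1:3) forward_backward(duo2, params2))[["elapsed"]]
  # 4x the markers should cost clearly less than quadratic growth
  expect_lt(t2, max(16 * t1, 1.0))
})

test_that("recombination posteriors are calibrated on model-generated duos", {
  # simulate duos from the generative model itself with known per-interval
  # recombination indicators, then check that among intervals with posterior
  # near p the fraction with a true recombination is near p
  set.seed(47)
  L <- 250
  tp <- 0.02; tc <- 0.01; eps <- 0.005
  band <- c(0.65, 0.75)
  hits <- total <- 0
  n_band <- 0
  post_all <- numeric(0)
  true_all <- logical(0)
  for (rep in 1:120) {
    rho <- exp(runif(L - 1, log(5e-3), log(0.12)))
    P <- matrix(sample(0:1, 2 * L, TRUE), 2)
    i_idx <- integer(L); j_idx <- integer(L)
    i_idx[1] <- sample(1:2, 1); j_idx[1] <- sample(1:2, 1)
    rec <- runif(L - 1) < rho
    pse <- runif(L - 1) < tp
    cse <- runif(L - 1) < tc
    for (l in 2:L) {
      i_idx[l] <- if (xor(rec[l - 1], pse[l - 1]))
        3L - i_idx[l - 1] else i_idx[l - 1]
      j_idx[l] <- if (cse[l - 1]) 3L - j_idx[l - 1] else j_idx[l - 1]
    }
    C <- matrix(sample(0:1, 2 * L, TRUE), 2)
    transmitted <- P[cbind(i_idx, 1:L)]
    err <- runif(L) < eps
    C[cbind(j_idx, 1:L)] <- ifelse(err, 1 - transmitted, transmitted)
    duo <- duo_haplotypes("p", "c", "male", P, C,
                          pos = seq(1e6, by = 1e4, length.out = L))
    params <- duohmm_params(tp, tc, eps, rho = rho)
    fb <- forward_backward(duo, params)
    rp <- recombination_posteriors(duo, fb, params)
    if (!nrow(rp)) next
    truth <- vapply(seq_len(nrow(rp)), function(k)
      any(rec[rp$left_index[k]:(rp$right_index[k] - 1)]), logical(1))
    post_all <- c(post_all, rp$posterior)
    true_all <- c(true_all, truth)
  }
  sel <- post_all >= band[1] & post_all <= band[2]
  expect_gt(sum(sel), 150)
  expect_equal(mean(true_all[sel]), mean(post_all[sel]), tolerance = 0.1)
})
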