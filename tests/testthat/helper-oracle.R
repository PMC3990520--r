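# Exhaustive-enumeration oracles for the four-state gene-flow HMM.
# These enumerate all 4^L state paths directly and stay independent of the
# forward-backward / Viterbi implementations they check.

oracle_tables <- function(duo, params) {
  L <- length(duo$pos)
  E <- kinphase:::emission_matrix(duo, params$epsilon)
  rho <- kinphase:::duo_rho(params, L)
  q <- kinphase:::parent_change_prob(rho, params$theta_p, params$q_mode)
  paths <- as.matrix(expand.grid(rep(list(1:4), L)))
  probs <- rep(0.25, nrow(paths)) * E[cbind(paths[, 1], 1)]
  for (l in 2:L) {
    A <- kinphase:::build_transition_q(q[l - 1], params$theta_c)
    probs <- probs * A[cbind(paths[, l - 1], paths[, l])] *
      E[cbind(paths[, l], l)]
  }
  list(paths = paths, probs = probs, E = E, q = q, rho = rho)
}

oracle_loglik <- function(duo, params) {
  log(sum(oracle_tables(duo, params)$probs))
}

oracle_gamma <- function(duo, params) {
  ot <- oracle_tables(duo, params)
  L <- ncol(ot$paths)
  g <- sapply(seq_len(L), function(l)
    sapply(1:4, function(s) sum(ot$probs[ot$paths[, l] == s])))
  sweep(g, 2, colSums(g), "/")
}

oracle_viterbi_logp <- function(duo, params) {
  log(max(oracle_tables(duo, params)$probs))
}

# posterior of >= 1 recombination among elementary intervals l..m-1, by
# enumerating paths jointly with the per-interval recombination indicator
oracle_recomb_posterior <- function(duo, params, l, m) {
  ot <- oracle_tables(duo, params)
  tp <- params$theta_p
  SP <- c(1, 1, 2, 2)
  pnorec <- rep(1, nrow(ot$paths))
  for (e in l:(m - 1)) {
    r <- ot$rho[e]
    chg <- SP[ot$paths[, e]] != SP[ot$paths[, e + 1]]
    pnr <- if (params$q_mode == "additive") {
      ifelse(chg, tp / ot$q[e], (1 - tp - r) / (1 - ot$q[e]))
    } else {
      ifelse(chg, tp * (1 - r) / ot$q[e],
             (1 - tp) * (1 - r) / (1 - ot$q[e]))
    }
    pnorec <- pnorec * pnr
  }
  sum(ot$probs * (1 - pnorec)) / sum(ot$probs)
}

# per-locus posterior mass on states whose IBD pair mismatches
oracle_error_posterior <- function(duo, params) {
  ot <- oracle_tables(duo, params)
  L <- ncol(ot$paths)
  M <- kinphase:::mismatch_matrix(duo)
  vapply(seq_len(L), function(l) {
    sum(ot$probs * M[cbind(ot$paths[, l], l)]) / sum(ot$probs)
  }, numeric(1))
}

# expected parent-index / child-index change counts from path posteriors
oracle_transition_counts <- function(duo, params) {
  ot <- oracle_tables(duo, params)
  L <- ncol(ot$paths)
  SP <- c(1, 1, 2, 2); SC <- c(1, 2, 1, 2)
  w <- ot$probs / sum(ot$probs)
  np <- nc <- 0
  for (e in seq_len(L - 1)) {
    np <- np + sum(w[SP[ot$paths[, e]] != SP[ot$paths[, e + 1]]])
    nc <- nc + sum(w[SC[ot$paths[, e]] != SC[ot$paths[, e + 1]]])
  }
  c(parent = np, child = nc)
}

random_duo <- function(L, p_missing = 0) {
  P <- matrix(sample(0:1, 2 * L, replace = TRUE), 2)
  C <- matrix(sample(0:1, 2 * L, replace = TRUE), 2)
  if (p_missing > 0) {
    P[runif(2 * L) < p_missing] <- NA
    C[runif(2 * L) < p_missing] <- NA
  }
  duo_haplotypes("p1", "c1", sample(c("male", "female"), 1), P, C,
                 pos = seq(1e6, by = 1e5, length.out = L))
}

random_params <- function(L) {
  duohmm_params(runif(1, 0.01, 0.3), runif(1, 0.01, 0.3),
                runif(1, 0.005, 0.2), rho = runif(L - 1, 1e-4, 0.3))
}
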