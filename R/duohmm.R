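# Four-state HMM over parent-child gene flow.
#
# Hidden state S_l = (i, j) asserts that parent haplotype i and child
# haplotype j are identical by descent at locus l. State order is
# A = (1,1), B = (1,2), C = (2,1), D = (2,2). Transitions factorize into a
# parent-index change (probability q_l, the exclusive-or of a parental
# switch error theta_p and a recombination rho_l) and a child-index change
# (probability theta_c, a child switch error). Emissions compare the IBD
# pair of alleles, allowing genotyping error epsilon.

STATE_NAMES <- c("A", "B", "C", "D")
STATE_PARENT <- c(1L, 1L, 2L, 2L)
STATE_CHILD <- c(1L, 2L, 1L, 2L)

#' HMM parameters for a parent-child duo
#'
#' @param theta_p per-interval parental switch-error probability.
#' @param theta_c per-interval child switch-error probability.
#' @param epsilon per-locus emission (genotyping) error probability.
#' @param rho per-interval recombination probabilities (length L - 1); a
#'   scalar is recycled at use.
#' @param q_mode how a parental switch error and a recombination combine into
#'   the parent-index change probability: `"xor"` (default; coincident events
#'   cancel) or `"additive"`.
#' @return an object of class `duohmm_params`.
#' @export
duohmm_params <- function(theta_p = 1e-3, theta_c = 1e-3, epsilon = 1e-3,
                          rho = 1e-4, q_mode = c("xor", "additive")) {
  q_mode <- match.arg(q_mode)
  for (v in list(theta_p = theta_p, theta_c = theta_c, epsilon = epsilon)) {
    if (length(v) != 1L || is.na(v) || v < 0 || v > 0.5)
      stop("theta_p, theta_c and epsilon must be single values in [0, 0.5]")
  }
  if (any(is.na(rho)) || any(rho < 0) || any(rho > 0.5))
    stop("rho must lie in [0, 0.5]")
  structure(list(theta_p = theta_p, theta_c = theta_c, epsilon = epsilon,
                 rho = rho, q_mode = q_mode), class = "duohmm_params")
}

#' @export
print.duohmm_params <- function(x, ...) {
  cat(sprintf(
    "duohmm_params: theta_p=%.3g theta_c=%.3g epsilon=%.3g mean(rho)=%.3g (%s)\n",
    x$theta_p, x$theta_c, x$epsilon, mean(x$rho), x$q_mode))
  invisible(x)
}

# parent-index change probability per interval
parent_change_prob <- function(rho, theta_p, q_mode = "xor") {
  if (q_mode == "additive") pmin(theta_p + rho, 1 - 1e-12)
  else theta_p * (1 - rho) + rho * (1 - theta_p)
}

#' Build the 4x4 transition matrix for one interval
#'
#' Entries fall into four transition sets: T1 (no change in gene flow),
#' T2 (parent IBD index changes), T3 (child index changes), T4 (both change),
#' with probabilities (1-q)(1-theta_c), q(1-theta_c), (1-q)theta_c and
#' q theta_c, where q combines theta_p and rho_l.
#'
#' @param rho_l recombination probability for the interval.
#' @param theta_p,theta_c switch-error probabilities.
#' @param q_mode see [duohmm_params()].
#' @return 4x4 row-stochastic matrix with dimnames A-D.
#' @export
build_transition <- function(rho_l, theta_p, theta_c, q_mode = "xor") {
  if (any(c(rho_l, theta_p, theta_c) < 0) || any(c(rho_l, theta_p, theta_c) > 0.5))
    stop("transition parameters must lie in [0, 0.5]")
  q <- parent_change_prob(rho_l, theta_p, q_mode)
  pc <- ifelse(outer(STATE_PARENT, STATE_PARENT, "=="), 1 - q, q)
  cc <- ifelse(outer(STATE_CHILD, STATE_CHILD, "=="), 1 - theta_c, theta_c)
  A <- pc * cc
  dimnames(A) <- list(STATE_NAMES, STATE_NAMES)
  A
}

#' Transition-set membership of the 4x4 transition matrix
#'
#' @return 4x4 character matrix with entries "T1".."T4".
#' @export
transition_sets <- function() {
  pchg <- outer(STATE_PARENT, STATE_PARENT, "!=")
  cchg <- outer(STATE_CHILD, STATE_CHILD, "!=")
  out <- matrix("T1", 4L, 4L, dimnames = list(STATE_NAMES, STATE_NAMES))
  out[pchg & !cchg] <- "T2"
  out[!pchg & cchg] <- "T3"
  out[pchg & cchg] <- "T4"
  out
}

#' Emission probability for one locus and state
#'
#' Probability of the observed parent/child alleles given the inheritance
#' state: `1 - epsilon` when the state's IBD pair of alleles matches,
#' `epsilon` when it mismatches, and 1 when either allele is missing
#' (uninformative).
#'
#' @param parent_alleles length-2 vector (parent haplotypes 1, 2).
#' @param child_alleles length-2 vector (child haplotypes 1, 2).
#' @param state state index 1-4 or label "A"-"D".
#' @param epsilon emission error probability.
#' @return emission probability.
#' @export
emission_prob <- function(parent_alleles, child_alleles, state, epsilon) {
  if (is.character(state)) state <- match(state, STATE_NAMES)
  p <- parent_alleles[STATE_PARENT[state]]
  c_ <- child_alleles[STATE_CHILD[state]]
  if (is.na(p) || is.na(c_)) return(1)
  if (p == c_) 1 - epsilon else epsilon
}

# 4 x L emission matrix for a duo (vectorized over loci)
emission_matrix <- function(duo, epsilon) {
  L <- length(duo$pos)
  E <- matrix(1, nrow = 4L, ncol = L)
  for (s in 1:4) {
    p <- duo$P[STATE_PARENT[s], ]
    ch <- duo$C[STATE_CHILD[s], ]
    m <- p == ch
    E[s, ] <- ifelse(is.na(m), 1, ifelse(m, 1 - epsilon, epsilon))
  }
  E
}

# 4 x L indicator of emission mismatch (0 where missing)
mismatch_matrix <- function(duo) {
  L <- length(duo$pos)
  M <- matrix(0, nrow = 4L, ncol = L)
  for (s in 1:4) {
    m <- duo$P[STATE_PARENT[s], ] != duo$C[STATE_CHILD[s], ]
    M[s, ] <- ifelse(is.na(m), 0, as.numeric(m))
  }
  M
}

# recycle rho to length L-1
duo_rho <- function(params, L) {
  rho <- params$rho
  if (length(rho) == 1L) rho <- rep(rho, L - 1L)
  if (length(rho) != L - 1L)
    stop("rho must have length L - 1 (", L - 1L, "), got ", length(rho))
  rho
}

#' Forward-Backward algorithm for a duo
#'
#' Computes the exact log-likelihood, per-locus state posteriors gamma and
#' per-interval expected transition masses under the four-state gene-flow
#' model, with per-locus scaling for numerical stability. The initial state
#' distribution is uniform (1/4).
#'
#' @param duo a [duo_haplotypes()] object with L >= 2 markers.
#' @param params a [duohmm_params()].
#' @return a list of class `duohmm_fb` with elements `loglik`, `gamma`
#'   (4 x L), `alpha`, `beta` (scaled tables), `scale`, `xi_parent` and
#'   `xi_child` (per-interval expected probability of a parent-index /
#'   child-index change), and `mismatch_post` (per-locus posterior emission
#'   mismatch mass).
#' @export
forward_backward <- function(duo, params) {
  L <- length(duo$pos)
  if (L < 2L) stop("forward_backward needs at least 2 markers")
  rho <- duo_rho(params, L)
  q <- parent_change_prob(rho, params$theta_p, params$q_mode)
  tc <- params$theta_c
  E <- emission_matrix(duo, params$epsilon)
  alpha <- matrix(0, 4L, L)
  beta <- matrix(0, 4L, L)
  scale <- numeric(L)
  a <- 0.25 * E[, 1L]
  scale[1L] <- sum(a)
  alpha[, 1L] <- a / scale[1L]
  for (l in 2:L) {
    a <- alpha[, l - 1L]
    ql <- q[l - 1L]
    # parent-index mixing (states A<->C, B<->D), then child mixing (A<->B, C<->D)
    bA <- (1 - ql) * a[1L] + ql * a[3L]
    bC <- ql * a[1L] + (1 - ql) * a[3L]
    bB <- (1 - ql) * a[2L] + ql * a[4L]
    bD <- ql * a[2L] + (1 - ql) * a[4L]
    v <- c((1 - tc) * bA + tc * bB, tc * bA + (1 - tc) * bB,
           (1 - tc) * bC + tc * bD, tc * bC + (1 - tc) * bD) * E[, l]
    scale[l] <- sum(v)
    alpha[, l] <- v / scale[l]
  }
  beta[, L] <- 1
  for (l in (L - 1L):1L) {
    w <- E[, l + 1L] * beta[, l + 1L] / scale[l + 1L]
    ql <- q[l]
    # child mixing applied backwards, then parent mixing
    cA <- (1 - tc) * w[1L] + tc * w[2L]
    cB <- tc * w[1L] + (1 - tc) * w[2L]
    cC <- (1 - tc) * w[3L] + tc * w[4L]
    cD <- tc * w[3L] + (1 - tc) * w[4L]
    beta[, l] <- c((1 - ql) * cA + ql * cC, (1 - ql) * cB + ql * cD,
                   ql * cA + (1 - ql) * cC, ql * cB + (1 - ql) * cD)
  }
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2L, colSums(gamma), "/")
  # expected transition masses per interval (vectorized over intervals).
  # With a = alpha[, l] and w = E[, l+1] beta[, l+1] / scale[l+1], the
  # expected mass of parent-index-changing transitions is
  # q [ (1-tc) (aA wC + aC wA + aB wD + aD wB) + tc (aA wD + aD wA + aB wC + aC wB) ]
  # and symmetrically for child-index changes.
  W <- E[, -1L, drop = FALSE] * beta[, -1L, drop = FALSE] /
    rep(scale[-1L], each = 4L)
  Aa <- alpha[1L, -L]; Ab <- alpha[2L, -L]; Ac <- alpha[3L, -L]; Ad <- alpha[4L, -L]
  Wa <- W[1L, ]; Wb <- W[2L, ]; Wc <- W[3L, ]; Wd <- W[4L, ]
  cross_p <- Aa * Wc + Ac * Wa + Ab * Wd + Ad * Wb       # parent only
  cross_c <- Aa * Wb + Ab * Wa + Ac * Wd + Ad * Wc       # child only
  cross_b <- Aa * Wd + Ad * Wa + Ab * Wc + Ac * Wb       # both
  xi_parent <- q * ((1 - tc) * cross_p + tc * cross_b)
  xi_child <- tc * ((1 - q) * cross_c + q * cross_b)
  M <- mismatch_matrix(duo)
  structure(list(loglik = sum(log(scale)), gamma = gamma, alpha = alpha,
                 beta = beta, scale = scale, xi_parent = xi_parent,
                 xi_child = xi_child, mismatch_post = colSums(gamma * M),
                 E = E, q = q),
            class = "duohmm_fb")
}

# 4x4 transition from precomputed q (no validation; hot path)
build_transition_q <- function(q, tc) {
  pc <- ifelse(outer(STATE_PARENT, STATE_PARENT, "=="), 1 - q, q)
  cc <- ifelse(outer(STATE_CHILD, STATE_CHILD, "=="), 1 - tc, tc)
  pc * cc
}

#' One-iteration parameter estimation for a duo
#'
#' Runs a single E-step/M-step update from `init`: theta_c is the mean
#' expected child-index change per interval; theta_p is the mean expected
#' parent-index change in excess of the map expectation (mean rho); epsilon
#' is the mean posterior emission-mismatch mass per locus. rho is fixed by
#' the genetic map and never re-estimated. Estimates are clamped to
#' \[1e-7, 0.5\]. There is little uncertainty in the state path, so a single
#' iteration suffices for convergence; estimation is per duo, never pooled.
#'
#' @param duo a [duo_haplotypes()].
#' @param map optional [genetic_map()] used to derive rho when the duo
#'   carries no genetic positions.
#' @param init initial [duohmm_params()].
#' @param map_function map function for rho (see [interval_recomb_prob()]).
#' @return updated [duohmm_params()] (with `fb` attribute holding the
#'   forward-backward result at `init`).
#' @export
estimate_params <- function(duo, map = NULL, init = duohmm_params(),
                            map_function = "haldane") {
  L <- length(duo$pos)
  rho <- init$rho
  if (!is.null(duo$cM)) {
    rho <- interval_recomb_prob(diff(duo$cM) / 100, map_function)
  } else if (!is.null(map)) {
    rho <- marker_recomb_probs(map, duo$pos, map_function)
  }
  rho <- pmin(pmax(rho, 1e-12), 0.5)
  init <- duohmm_params(init$theta_p, init$theta_c, init$epsilon, rho,
                        q_mode = init$q_mode)
  fb <- forward_backward(duo, init)
  clamp <- function(x) min(max(x, 1e-7), 0.5)
  theta_c <- clamp(sum(fb$xi_child) / (L - 1L))
  theta_p <- clamp(sum(fb$xi_parent) / (L - 1L) - mean(rho))
  epsilon <- clamp(sum(fb$mismatch_post) / L)
  out <- duohmm_params(theta_p, theta_c, epsilon, rho, q_mode = init$q_mode)
  attr(out, "fb") <- fb
  out
}

#' Viterbi decoding of the gene-flow state path
#'
#' Maximum-probability state sequence; ties are broken deterministically in
#' favour of the earlier state in the order A < B < C < D.
#'
#' @param duo a [duo_haplotypes()].
#' @param params a [duohmm_params()].
#' @return integer vector of length L with states 1-4 (A-D), with attribute
#'   `logp` holding the path log-probability.
#' @export
viterbi <- function(duo, params) {
  L <- length(duo$pos)
  if (L < 2L) stop("viterbi needs at least 2 markers")
  rho <- duo_rho(params, L)
  q <- parent_change_prob(rho, params$theta_p, params$q_mode)
  tc <- params$theta_c
  E <- emission_matrix(duo, params$epsilon)
  logE <- log(E)
  pchg <- (outer(STATE_PARENT, STATE_PARENT, "!=")) * 1
  cchg <- (outer(STATE_CHILD, STATE_CHILD, "!=")) * 1
  ltc <- log(tc); l1tc <- log1p(-tc)
  logC <- cchg * ltc + (1 - cchg) * l1tc
  delta <- log(0.25) + logE[, 1L]
  psi <- matrix(0L, 4L, L)
  for (l in 2:L) {
    lq <- log(q[l - 1L]); l1q <- log1p(-q[l - 1L])
    logA <- pchg * lq + (1 - pchg) * l1q + logC
    cand <- delta + logA  # rows: from-state, cols: to-state
    psi[, l] <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(psi[, l], 1:4)] + logE[, l]
  }
  path <- integer(L)
  path[L] <- which.max(delta)
  for (l in L:2L) path[l - 1L] <- psi[path[l], l]
  structure(path, logp = max(delta), names = NULL)
}
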