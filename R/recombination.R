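# Recombination-event and genotyping-error posteriors from the duo HMM.

#' Posterior probabilities of recombination between flanking heterozygous
#' markers
#'
#' A crossover in the parent can only be resolved to the interval between two
#' consecutive parent-heterozygous markers (the loci strictly between are
#' parent-homozygous, so their emissions do not discriminate the parental
#' index). For each such interval `(l, m]` the posterior probability that at
#' least one recombination occurred is computed exactly from the
#' forward-backward tables by propagating the transition mass split into its
#' recombination and switch-error components: across each elementary
#' interval, a parent-index change carries recombination mass
#' `rho (1 - theta_p)` and switch-error mass `theta_p (1 - rho)`, while a
#' retained parent index carries the coincident-event mass `rho theta_p`.
#'
#' @param duo a [duo_haplotypes()].
#' @param fb result of [forward_backward()] on the same duo and parameters.
#' @param params the [duohmm_params()] used for `fb`.
#' @return data frame of class `recombination_calls` with columns `parent`,
#'   `child`, `parent_sex`, `left_index`, `right_index`, `left_pos`,
#'   `right_pos`, `posterior`; empty when the parent has fewer than two
#'   heterozygous markers.
#' @export
recombination_posteriors <- function(duo, fb, params) {
  L <- length(duo$pos)
  het <- which(duo$P[1L, ] != duo$P[2L, ] & !is.na(duo$P[1L, ]) &
                 !is.na(duo$P[2L, ]))
  empty <- data.frame(parent = character(), child = character(),
                      parent_sex = character(), left_index = integer(),
                      right_index = integer(), left_pos = numeric(),
                      right_pos = numeric(), posterior = numeric())
  class(empty) <- c("recombination_calls", "data.frame")
  if (length(het) < 2L) return(empty)
  rho <- duo_rho(params, L)
  tp <- params$theta_p
  tc <- params$theta_c
  additive <- params$q_mode == "additive"
  E <- fb$E
  scale <- fb$scale
  alpha <- fb$alpha
  beta <- fb$beta
  n_int <- length(het) - 1L
  post <- numeric(n_int)
  mix_p <- function(u, same, chg) {
    c(same * u[1L] + chg * u[3L], same * u[2L] + chg * u[4L],
      chg * u[1L] + same * u[3L], chg * u[2L] + same * u[4L])
  }
  mix_c <- function(u) {
    c((1 - tc) * u[1L] + tc * u[2L], tc * u[1L] + (1 - tc) * u[2L],
      (1 - tc) * u[3L] + tc * u[4L], tc * u[3L] + (1 - tc) * u[4L])
  }
  for (k in seq_len(n_int)) {
    l <- het[k]; m <- het[k + 1L]
    u_no <- alpha[, l]
    u_any <- c(0, 0, 0, 0)
    for (e in l:(m - 1L)) {
      r <- rho[e]
      if (additive) {
        ps_r <- 0; ps_n <- 1 - tp - r      # parent index retained
        pchg_r <- r; pchg_n <- tp           # parent index changed
      } else {
        ps_r <- tp * r; ps_n <- (1 - tp) * (1 - r)
        pchg_r <- r * (1 - tp); pchg_n <- tp * (1 - r)
      }
      w_any <- mix_p(u_any, ps_r + ps_n, pchg_r + pchg_n) +
        mix_p(u_no, ps_r, pchg_r)
      w_no <- mix_p(u_no, ps_n, pchg_n)
      f <- E[, e + 1L] / scale[e + 1L]
      u_any <- mix_c(w_any) * f
      u_no <- mix_c(w_no) * f
    }
    num <- sum(u_any * beta[, m])
    den <- sum((u_any + u_no) * beta[, m])
    post[k] <- if (den > 0) num / den else 0
  }
  out <- data.frame(parent = duo$parent, child = duo$child,
                    parent_sex = duo$parent_sex,
                    left_index = het[-length(het)], right_index = het[-1L],
                    left_pos = duo$pos[het[-length(het)]],
                    right_pos = duo$pos[het[-1L]],
                    posterior = pmin(pmax(post, 0), 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("recombination_calls", "data.frame")
  out
}

#' Threshold recombination posteriors into called events
#'
#' @param calls output of [recombination_posteriors()] (possibly row-bound
#'   over duos).
#' @param threshold posterior threshold in (0, 1\]; calls with posterior >=
#'   threshold are kept, sorted by position.
#' @return filtered calls.
#' @export
call_recombinations <- function(calls, threshold = 0.5) {
  if (length(threshold) != 1L || is.na(threshold) || threshold <= 0 ||
      threshold > 1)
    stop("threshold must be a single value in (0, 1]")
  out <- calls[calls$posterior >= threshold, , drop = FALSE]
  out <- out[order(out$left_pos, out$right_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Posterior probability of genotyping error per locus
#'
#' For each locus, sums the posterior probabilities of inheritance states
#' whose IBD allele pair is inconsistent with the observed haplotypes: the
#' probability of a genotyping error in at least one member of the duo.
#' Loci where either compared allele is missing contribute no inconsistency.
#'
#' @param duo a [duo_haplotypes()].
#' @param fb result of [forward_backward()] on the same duo.
#' @return data frame with columns `parent`, `child`, `marker`, `pos`,
#'   `posterior`.
#' @export
genotype_error_posteriors <- function(duo, fb) {
  M <- mismatch_matrix(duo)
  data.frame(parent = duo$parent, child = duo$child,
             marker = seq_along(duo$pos), pos = duo$pos,
             posterior = pmin(colSums(fb$gamma * M), 1),
             stringsAsFactors = FALSE)
}
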