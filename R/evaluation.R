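# Evaluation metrics: switch error, crossover detection accuracy, Poisson
# count calibration, and the hotspot-usage association statistic.

#' Switch error rate between estimated and true haplotypes
#'
#' The fraction of adjacent heterozygote pairs whose relative phase differs
#' between the estimate and the truth, computed over sites heterozygous in
#' both. Invariant to globally swapping the two estimated haplotypes.
#'
#' @param est 2 x L matrix of estimated haplotypes.
#' @param truth 2 x L matrix of true haplotypes.
#' @return switch error rate in \[0, 1\], with attributes `switches` and
#'   `het_pairs`; `NA` (flagged by a warning) with fewer than two usable
#'   heterozygous sites.
#' @export
switch_error <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  stopifnot(nrow(est) == 2L, nrow(truth) == 2L, ncol(est) == ncol(truth))
  het <- which(est[1L, ] != est[2L, ] & truth[1L, ] != truth[2L, ] &
                 !is.na(est[1L, ]) & !is.na(est[2L, ]) &
                 !is.na(truth[1L, ]) & !is.na(truth[2L, ]))
  if (length(het) < 2L) {
    warning("fewer than 2 heterozygous sites; switch error undefined")
    return(structure(NA_real_, switches = NA_integer_, het_pairs = 0L))
  }
  # phase orientation of the estimate relative to the truth at each het site
  s <- est[1L, het] != truth[1L, het]
  switches <- sum(diff(s) != 0L)
  structure(switches / (length(het) - 1L), switches = switches,
            het_pairs = length(het) - 1L)
}

#' Crossover detection accuracy (TPR/FDR) by interval containment
#'
#' A called interval is a true positive when at least one not-yet-matched
#' truth event lies within it (greedy one-to-one matching left to right, so
#' a single wide call cannot absorb several truth events). TPR is the
#' fraction of truth events matched; FDR the fraction of calls left
#' unmatched (0 when there are no calls).
#'
#' @param calls data frame with `left_pos`, `right_pos`, `posterior` (as from
#'   [recombination_posteriors()]); optionally `parent`/`child` to restrict
#'   matching within meioses (used when present in both inputs).
#' @param truth_events data frame with truth crossover positions: either a
#'   `pos` column or `left_pos`/`right_pos` (midpoint used), plus optional
#'   `parent`/`child`.
#' @param thresholds posterior thresholds to evaluate.
#' @return data frame with columns `threshold`, `tp`, `fp`, `n_truth`,
#'   `tpr`, `fdr`.
#' @export
crossover_accuracy <- function(calls, truth_events,
                               thresholds = seq(0, 0.95, by = 0.05)) {
  pos <- if ("pos" %in% names(truth_events)) truth_events$pos
  else (truth_events$left_pos + truth_events$right_pos) / 2
  by_meiosis <- all(c("parent", "child") %in% names(calls)) &&
    all(c("parent", "child") %in% names(truth_events))
  tkey <- if (by_meiosis) paste(truth_events$parent, truth_events$child)
  else rep("", length(pos))
  ckey <- if (by_meiosis) paste(calls$parent, calls$child)
  else rep("", nrow(calls))
  n_truth <- length(pos)
  out <- lapply(thresholds, function(th) {
    keep <- which(calls$posterior >= th)
    keep <- keep[order(calls$left_pos[keep], calls$right_pos[keep])]
    matched <- rep(FALSE, n_truth)
    tp <- 0L
    for (i in keep) {
      hit <- which(!matched & tkey == ckey[i] &
                     pos >= calls$left_pos[i] & pos <= calls$right_pos[i])
      if (length(hit)) {
        matched[hit[1L]] <- TRUE
        tp <- tp + 1L
      }
    }
    fp <- length(keep) - tp
    data.frame(threshold = th, tp = tp, fp = fp, n_truth = n_truth,
               tpr = if (n_truth > 0L) tp / n_truth else 0,
               fdr = if (tp + fp > 0L) fp / (tp + fp) else 0)
  })
  do.call(rbind, out)
}

#' Calibration of per-meiosis crossover counts against a Poisson model
#'
#' @param counts non-negative integer counts per meiosis.
#' @param expected_rate Poisson mean (the sex-specific genetic map length in
#'   Morgans; 25.9 paternal and 42.81 maternal for genome-wide autosomal
#'   counts under the family-based map).
#' @return list with `qq` (data frame expected, observed quantiles) and
#'   `dispersion` (variance/mean ratio; 1 under the Poisson model, 0 for
#'   constant counts).
#' @export
count_calibration <- function(counts, expected_rate) {
  if (!length(counts)) stop("no counts supplied")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- length(counts)
  qq <- data.frame(expected = stats::qpois(stats::ppoints(n), expected_rate),
                   observed = sort(counts))
  m <- mean(counts)
  list(qq = qq, dispersion = if (m > 0) stats::var(counts) / m else 0)
}

#' Read hotspot intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to 1-based inclusive
#' and merged if overlapping.
#'
#' @param path BED file path.
#' @return data frame with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_hotspots <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]) + 1, end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), ]
}

# TRUE where pos falls in some interval [start, end]
in_intervals <- function(pos, start, end) {
  if (!length(start)) return(rep(FALSE, length(pos)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  i <- findInterval(pos, start)
  i > 0L & pos <= end[pmax(i, 1L)]
}

#' Hotspot-usage phenotype per parent
#'
#' For each parent, the raw usage is the fraction of that parent's crossover
#' events whose interval midpoint (on the genetic scale, mapped back to a
#' physical position) falls inside a hotspot. The chance probability of
#' landing in a hotspot is estimated by simulating events uniformly on the
#' genetic map `n_null_sims` times and scoring them identically. The
#' chance-corrected usage is the clamped excess
#' `H = max(0, raw - chance) / (1 - chance)` (or the raw proportion with
#' `correction = "none"`), and the pseudo-count of hotspot events is
#' `y = round(H * n)` (ties to even), giving a weighted binomial response.
#'
#' @param events data frame of crossover events with `parent`, `left_pos`,
#'   `right_pos`.
#' @param hotspots data frame with `start`, `end` (1-based inclusive,
#'   disjoint), e.g. from [read_hotspots()].
#' @param map a [genetic_map()].
#' @param n_null_sims null simulations for the chance correction.
#' @param correction `"excess"` (default) or `"none"`.
#' @param seed integer seed for the null simulation.
#' @return data frame with `parent`, `n` (event count), `raw`, `chance`,
#'   `H`, `y`. Parents with no events are excluded with a warning.
#' @export
hotspot_usage <- function(events, hotspots, map, n_null_sims = 200L,
                          correction = c("excess", "none"), seed = 1L) {
  correction <- match.arg(correction)
  parents <- unique(events$parent)
  if (!length(parents)) {
    warning("no parents with crossover events")
    return(data.frame(parent = character(), n = integer(), raw = numeric(),
                      chance = numeric(), H = numeric(), y = numeric()))
  }
  mid_cM <- (interpolate_cM(map, pmin(events$left_pos, events$right_pos)) +
               interpolate_cM(map, pmax(events$left_pos, events$right_pos))) / 2
  mid_bp <- interpolate_bp(map, mid_cM)
  hit <- in_intervals(mid_bp, hotspots$start, hotspots$end)
  # chance probability for one uniformly placed event, by simulation
  chance <- withr_seed(seed + 7919L, {
    u <- stats::runif(n_null_sims, min(map$cum_cM), max(map$cum_cM))
    mean(in_intervals(interpolate_bp(map, u), hotspots$start, hotspots$end))
  })
  out <- do.call(rbind, lapply(parents, function(p) {
    sel <- events$parent == p
    n <- sum(sel)
    raw <- mean(hit[sel])
    H <- if (correction == "none") raw
    else if (chance < 1) min(max((raw - chance) / (1 - chance), 0), 1)
    else 0
    data.frame(parent = p, n = n, raw = raw, chance = chance, H = H,
               y = round(H * n), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Binomial GLM association of hotspot usage with genotype dosage
#'
#' Fits a binomial generalized linear model (logit link) with the per-parent
#' pseudo-count of hotspot events out of the observed crossover count as the
#' response and the allele dosage as covariate, and tests the dosage term by
#' a likelihood-ratio test against the intercept-only model. Parents with
#' few crossovers carry proportionally less weight through the binomial
#' denominator.
#'
#' @param phenotypes data frame from [hotspot_usage()] (columns `parent`,
#'   `n`, `y`).
#' @param dosages data frame with `id` and `dosage` (0-2 allele dosage).
#' @return list with `estimate` (log-odds per allele), `se`, `p` (LRT
#'   p-value; `NA` when flagged), `flagged` and `reason`.
#' @export
hotspot_association <- function(phenotypes, dosages) {
  d <- merge(phenotypes, dosages, by.x = "parent", by.y = "id")
  d <- d[d$n > 0, , drop = FALSE]
  if (nrow(d) < 2L)
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                flagged = TRUE, reason = "fewer than 2 usable parents"))
  if (length(unique(d$dosage)) < 2L)
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                flagged = TRUE, reason = "degenerate dosage"))
  if (all(d$y == 0) || all(d$y == d$n))
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                flagged = TRUE, reason = "response at the boundary"))
  fit1 <- stats::glm(cbind(y, n - y) ~ dosage, family = stats::binomial(),
                     data = d)
  fit0 <- stats::glm(cbind(y, n - y) ~ 1, family = stats::binomial(),
                     data = d)
  est <- stats::coef(fit1)[["dosage"]]
  se <- sqrt(diag(stats::vcov(fit1)))[["dosage"]]
  if (!fit1$converged || abs(est) > 10)
    return(list(estimate = est, se = se, p = NA_real_, flagged = TRUE,
                reason = "separation or non-convergence"))
  lrt <- 2 * (stats::logLik(fit1) - stats::logLik(fit0))
  list(estimate = est, se = se,
       p = stats::pchisq(as.numeric(lrt), df = 1L, lower.tail = FALSE),
       flagged = FALSE, reason = NA_character_)
}
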