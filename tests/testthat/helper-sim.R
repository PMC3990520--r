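# Shared fixtures built in code.

toy_map <- function() {
  genetic_map(c(1e6, 2e6, 3e6), cum_cM = c(0, 1, 2), chrom = "1")
}

uniform_map <- function(L = 2000, spacing = 5e4, cM_per_Mb = 1) {
  pos <- seq(1e5, by = spacing, length.out = L)
  genetic_map(pos, cum_cM = (pos - pos[1]) / 1e6 * cM_per_Mb, chrom = "X")
}

trio_ped <- function() {
  pedigree(data.frame(family = "F1", id = c("dad", "mum", "kid"),
                      father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
                      sex = c(1L, 2L, 0L), stringsAsFactors = FALSE))
}

# a clean duo where child haplotype 1 copies parent haplotype `ibd` and all
# other haplotypes are random
clean_duo <- function(L, ibd = 1, seed = NULL, sex = "male") {
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(sample(0:1, 2 * L, replace = TRUE), 2)
  C <- rbind(P[ibd, ], sample(0:1, L, replace = TRUE))
  duo_haplotypes("p1", "c1", sex, P, C,
                 pos = seq(1e6, by = 1e5, length.out = L))
}

# flip child haplotypes of a duo from marker k onward
flip_child_from <- function(duo, k) {
  L <- length(duo$pos)
  duo$C[, k:L] <- duo$C[2:1, k:L]
  duo
}

# maximal misphased regions between estimate and truth: marker index ranges
# over which the estimated haplotypes are swapped relative to the truth
# (orientation-normalized; `exclude` sites are masked first)
discordant_regions <- function(est, truth, exclude = integer(0)) {
  if (length(exclude)) est[, exclude] <- NA
  het <- which(est[1, ] != est[2, ] & truth[1, ] != truth[2, ] &
                 !is.na(est[1, ]) & !is.na(truth[1, ]))
  if (length(het) < 2) return(list())
  s <- est[1, het] != truth[1, het]
  if (mean(s) > 0.5) s <- !s
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    from <- het[starts[i]]
    to <- if (ends[i] < length(het)) het[ends[i] + 1] - 1 else ncol(est)
    out[[length(out) + 1]] <- c(from, to)
  }
  out
}

# a misphased region counts as a correctable miss only when flipping it back
# clearly improves the likelihood of at least one duo; regions where every
# duo's likelihood is indifferent (no informative sites bear on the region)
# are genuinely unresolved by the duo context
region_is_duo_determined <- function(duos_of_child, region, tol = 2) {
  for (d in duos_of_child) {
    est <- estimate_params(d)
    ll1 <- forward_backward(d, est)$loglik
    d2 <- d
    cols <- region[1]:region[2]
    d2$C[, cols] <- d$C[2:1, cols]
    ll2 <- forward_backward(d2, est)$loglik
    if (ll2 - ll1 > tol) return(TRUE)
  }
  FALSE
}

# independent brute-force minimum-uncovered oracle for duo/trio partitioning:
# recursion over individuals rather than units
partition_oracle <- function(ped) {
  ids <- ped$id[ped$genotyped]
  g <- stats::setNames(ped$genotyped, ped$id)
  units <- list()
  m <- pedigree_meioses(ped, genotyped_only = TRUE)
  for (i in seq_len(nrow(m)))
    units[[length(units) + 1L]] <- c(m$parent[i], m$child[i])
  for (k in seq_len(nrow(ped))) {
    f <- ped$father[k]; mo <- ped$mother[k]
    if (!is.na(f) && !is.na(mo) && isTRUE(g[f]) && isTRUE(g[mo]) &&
        isTRUE(g[ped$id[k]]))
      units[[length(units) + 1L]] <- c(f, mo, ped$id[k])
  }
  best <- length(ids)
  rec <- function(remaining, uncovered) {
    if (uncovered >= best) return(invisible())
    if (!length(remaining)) { best <<- uncovered; return(invisible()) }
    x <- remaining[1]
    # option 1: leave x uncovered
    rec(remaining[-1], uncovered + 1L)
    # option 2: cover x with any unit fully inside `remaining`
    for (u in units) {
      if (x %in% u && all(u %in% remaining))
        rec(setdiff(remaining, u), uncovered)
    }
  }
  rec(ids, 0L)
  best
}
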