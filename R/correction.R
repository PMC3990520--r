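# Haplotype correction from Viterbi decodings: child switch-error flips,
# minimum-recombinant parental corrections from sibships, and the sequential
# top-down pedigree cascade.

#' Correct child switch errors implied by a Viterbi path
#'
#' Transitions that change the child IBD index (sets T3 and T4) imply a
#' switch error in the child haplotypes. Scanning left to right, at each such
#' transition the child's two haplotypes are swapped from that locus onward,
#' so a re-decoded path contains no child-index changes.
#'
#' @param duo a [duo_haplotypes()].
#' @param viterbi_path integer state path (1-4) of length L from [viterbi()].
#' @return list with `C` (corrected 2 x L child haplotypes), `duo` (duo with
#'   corrected child) and `records` (data frame id, marker, kind).
#' @export
correct_child <- function(duo, viterbi_path) {
  L <- length(duo$pos)
  stopifnot(length(viterbi_path) == L)
  j <- STATE_CHILD[viterbi_path]
  flips <- which(diff(j) != 0L) + 1L  # first locus of the new phase
  C <- duo$C
  if (length(flips)) {
    parity <- cumsum(seq_len(L) %in% flips) %% 2L == 1L
    C[, parity] <- duo$C[2:1, parity]
  }
  kind <- if (duo$parent_sex == "male") "P" else "M"
  records <- data.frame(id = rep(duo$child, length(flips)), marker = flips,
                        kind = rep(kind, length(flips)),
                        stringsAsFactors = FALSE)
  duo2 <- duo
  duo2$C <- C
  list(C = C, duo = duo2, records = records)
}

#' Minimum-recombinant correction of parental haplotypes from a sibship
#'
#' A parent-index change (T2/T4) in a duo's decoded path is either a
#' recombination or a parental switch error. When the same change appears at
#' the same position for a strict majority of the parent's decoded children,
#' it is classified as a parental switch error and the parent's haplotypes
#' are swapped from that locus onward. Changes are matched across siblings by
#' their shared interval between the same flanking parent-heterozygous
#' markers (the finest resolution the model supports).
#'
#' @param parent_haps 2 x L matrix of the parent's haplotypes.
#' @param duos list of [duo_haplotypes()] for the children of this parent
#'   (all sharing `parent_haps`).
#' @param paths list of Viterbi paths aligned with `duos`.
#' @param parent_id id used in correction records.
#' @return list with `P` (corrected haplotypes) and `records` (data frame
#'   id, marker, kind = "C"). With fewer than two children this is a no-op
#'   with a warning.
#' @export
correct_parent_min_recombinant <- function(parent_haps, duos, paths,
                                           parent_id = "parent") {
  empty <- data.frame(id = character(), marker = integer(),
                      kind = character(), stringsAsFactors = FALSE)
  if (length(duos) < 2L) {
    warning("minimum-recombinant correction needs >= 2 decoded children; no-op")
    return(list(P = parent_haps, records = empty))
  }
  L <- ncol(parent_haps)
  het <- which(parent_haps[1L, ] != parent_haps[2L, ] &
                 !is.na(parent_haps[1L, ]) & !is.na(parent_haps[2L, ]))
  if (length(het) < 2L) return(list(P = parent_haps, records = empty))
  # map an elementary change interval to its flanking parent-het interval id
  interval_of <- function(marker) findInterval(marker - 0.5, het)
  n_child <- length(duos)
  votes <- matrix(FALSE, nrow = n_child, ncol = length(het) - 1L)
  for (ci in seq_len(n_child)) {
    i <- STATE_PARENT[paths[[ci]]]
    chg <- which(diff(i) != 0L) + 1L  # first locus after the change
    iv <- interval_of(chg)
    iv <- iv[iv >= 1L & iv <= ncol(votes)]
    votes[ci, unique(iv)] <- TRUE
  }
  majority <- which(colSums(votes) * 2L > n_child)
  if (!length(majority)) return(list(P = parent_haps, records = empty))
  flips <- het[majority + 1L]  # flip from the right flanking het marker on
  P <- parent_haps
  parity <- cumsum(seq_len(L) %in% flips) %% 2L == 1L
  P[, parity] <- parent_haps[2:1, parity]
  records <- data.frame(id = rep(parent_id, length(flips)), marker = flips,
                        kind = rep("C", length(flips)), stringsAsFactors = FALSE)
  list(P = P, records = records)
}

# loci that pin the child IBD index for a duo: child heterozygous, parent
# homozygous (unambiguous discriminators of the transmitted haplotype)
child_anchor_sites <- function(P, C) {
  which(C[1L, ] != C[2L, ] & !is.na(C[1L, ]) & !is.na(C[2L, ]) &
          P[1L, ] == P[2L, ] & !is.na(P[1L, ]))
}

# Child switch errors for a trio child from both duos jointly. At every
# anchor locus (child heterozygous, parent homozygous) the transmitted
# allele identifies which child haplotype is IBD with that parent,
# regardless of the parent's own gene flow (a homozygous parent transmits
# the same allele from either haplotype, so parental crossovers and switch
# errors cannot masquerade as child flips here). In a correctly phased
# child the father-IBD haplotype index is constant and the mother-IBD index
# is its complement, so the merged orientation sequence over both parents'
# anchors is constant; every value change marks a child switch error,
# resolved to the gap between consecutive anchors of either duo. Isolated
# single-anchor blips flanked by agreeing anchors are attributed to
# genotyping error and skipped (the error posterior flags them instead).
joint_child_flips <- function(duoP, duoQ, pathP = NULL, pathQ = NULL) {
  orient <- function(duo, flip) {
    l <- child_anchor_sites(duo$P, duo$C)
    o <- ifelse(duo$C[1L, l] == duo$P[1L, l], 1L, 2L)
    data.frame(l = l, s = if (flip) 3L - o else o,
               kind = if (duo$parent_sex == "male") "P" else "M",
               stringsAsFactors = FALSE)
  }
  df <- rbind(orient(duoP, FALSE), orient(duoQ, TRUE))
  df <- df[order(df$l), , drop = FALSE]
  none <- list(marker = integer(0), kind = character(0))
  if (nrow(df) < 2L) return(none)
  cand_p <- if (is.null(pathP)) integer(0)
  else which(diff(STATE_CHILD[pathP]) != 0L) + 1L
  cand_q <- if (is.null(pathQ)) integer(0)
  else which(diff(STATE_CHILD[pathQ]) != 0L) + 1L
  r <- rle(df$s)
  # Interior length-1 runs flanked by agreeing anchors are either a
  # genotyping error at that single anchor or a genuine switch pair whose
  # flipped region happens to contain just one anchor. A Viterbi decode
  # showing a candidate pair bracketing the anchor distinguishes the two:
  # keep such pairs (at the decoded positions), drop the rest (the error
  # posterior flags them instead).
  extra_m <- integer(0)
  extra_k <- character(0)
  if (length(r$lengths) > 2L) {
    ends <- cumsum(r$lengths)
    drop <- integer(0)
    for (i in 2:(length(r$lengths) - 1L)) {
      if (r$lengths[i] != 1L || r$values[i - 1L] != r$values[i + 1L]) next
      idx <- ends[i]
      l_prev <- df$l[idx - 1L]; l_b <- df$l[idx]; l_next <- df$l[idx + 1L]
      found <- FALSE
      for (cand in list(list(f = cand_p, kind = "P"),
                        list(f = cand_q, kind = "M"))) {
        f1 <- cand$f[cand$f > l_prev & cand$f <= l_b]
        f2 <- cand$f[cand$f > l_b & cand$f <= l_next]
        if (length(f1) && length(f2)) {
          kk <- if (duoP$parent_sex == "male") cand$kind
          else c(P = "M", M = "P")[[cand$kind]]
          extra_m <- c(extra_m, max(f1), min(f2))
          extra_k <- c(extra_k, kk, kk)
          found <- TRUE
          break
        }
      }
      drop <- c(drop, idx)
    }
    if (length(drop)) {
      df <- df[-drop, , drop = FALSE]
      r <- rle(df$s)
    }
  }
  if (length(r$lengths) < 2L && !length(extra_m)) return(none)
  ends <- cumsum(r$lengths)
  starts_idx <- if (length(r$lengths) < 2L) integer(0)
  else ends[-length(ends)] + 1L
  # refine each switch within its anchor gap using the Viterbi decodes,
  # which exploit parent-heterozygous sites the anchors cannot
  phet <- function(duo) duo$P[1L, ] != duo$P[2L, ] & !is.na(duo$P[1L, ]) &
    !is.na(duo$P[2L, ])
  chet <- duoP$C[1L, ] != duoP$C[2L, ] & !is.na(duoP$C[1L, ]) &
    !is.na(duoP$C[2L, ])
  info_p <- phet(duoP) & chet
  info_q <- phet(duoQ) & chet
  kind_default <- if (duoP$parent_sex == "male") "P" else "M"
  marker <- integer(0)
  kind <- character(0)
  for (t in starts_idx) {
    a <- df$l[t - 1L]  # last anchor of the previous run
    b <- df$l[t]       # first anchor of the new run
    fp <- cand_p[cand_p > a & cand_p <= b]
    fq <- cand_q[cand_q > a & cand_q <= b]
    if (length(fp) >= 3L && length(fp) %% 2L == 1L &&
        length(fq) == length(fp)) {
      # the gap holds a switch-pair cluster on top of the parity change;
      # both decodes agree on the count, so keep the full set
      marker <- c(marker, fp)
      kind <- c(kind, rep(kind_default, length(fp)))
      next
    }
    cands <- sort(unique(c(fp, fq)))
    pos <- if (length(cands) == 0L) b
    else if (length(cands) == 1L) cands
    else {
      # disagreeing placements: trust the duo whose parent is informative
      # between them (its likelihood pins the position)
      f1 <- cands[1L]; f2 <- cands[length(cands)]
      span <- f1:(f2 - 1L)
      has_p <- any(info_p[span])
      has_q <- any(info_q[span])
      if (has_p && !has_q) {
        if (length(fp)) fp[which.min(abs(fp - b))] else f2
      } else if (has_q && !has_p) {
        if (length(fq)) fq[which.min(abs(fq - b))] else f2
      } else f2
    }
    marker <- c(marker, pos)
    kind <- c(kind, df$kind[t])
  }
  marker <- c(marker, extra_m)
  kind <- c(kind, extra_k)
  # anchor-free stretches: the scan is blind inside a gap with no anchors
  # and beyond the terminal anchors, but the Viterbi decodes still localize
  # switches there through parent-heterozygous sites. Inside interior gaps
  # a net-zero-parity switch pair is accepted when both decodes report it;
  # in terminal stretches (no anchors beyond) any reported switch is kept.
  lv <- df$l
  kind_default <- if (duoP$parent_sex == "male") "P" else "M"
  gap_bounds <- cbind(c(0L, lv), c(lv, ncol(duoP$C) + 1L))
  for (g in seq_len(nrow(gap_bounds))) {
    a <- gap_bounds[g, 1L]; b <- gap_bounds[g, 2L]
    p_in <- setdiff(cand_p[cand_p > a & cand_p <= b], marker)
    q_in <- setdiff(cand_q[cand_q > a & cand_q <= b], marker)
    terminal <- g == 1L || g == nrow(gap_bounds)
    if (terminal) {
      add <- if (length(p_in)) p_in else q_in
    } else if (df$s[g - 1L] == df$s[g]) {
      add <- if (length(p_in) >= 2L && length(q_in) >= 2L) p_in else integer(0)
    } else add <- integer(0)
    if (length(add)) {
      marker <- c(marker, add)
      kind <- c(kind, rep(kind_default, length(add)))
    }
  }
  o <- order(marker)
  marker <- marker[o]; kind <- kind[o]
  # coincident flips cancel pairwise; keep odd-multiplicity positions only
  odd <- marker %in% names(which(table(marker) %% 2L == 1L))
  list(marker = marker[odd][!duplicated(marker[odd])],
       kind = kind[odd][!duplicated(marker[odd])])
}

# swap the two rows of C from each flip position onward
apply_suffix_flips <- function(C, flips) {
  if (!length(flips)) return(C)
  L <- ncol(C)
  parity <- cumsum(seq_len(L) %in% flips) %% 2L == 1L
  C[, parity] <- C[2:1, parity]
  C
}

#' Sequential top-down pedigree haplotype correction
#'
#' Pedigrees are processed generation by generation from founders downward:
#' each individual's haplotypes are finalized before any duo in which that
#' individual is the parent is decoded, so corrections made to a parent
#' propagate into the decoding of its children. Within each parent, duo
#' parameters are estimated, paths decoded, minimum-recombinant parental
#' corrections applied when the parent has two or more decoded children
#' (followed by re-estimation and re-decoding), and finally child
#' switch-error corrections applied.
#'
#' @param ped a [pedigree()].
#' @param haps a [haplotype_set()] covering the genotyped members.
#' @param map a [genetic_map()] for the markers.
#' @param male_scale sex-scaling factor applied to the map for male parents.
#' @param init initial [duohmm_params()] for per-duo estimation.
#' @param map_function map function for rho.
#' @return list with `haps` (corrected [haplotype_set()]) and `records`
#'   (data frame id, marker, kind in P/M/C).
#' @export
correct_pedigree <- function(ped, haps, map, male_scale = 0.605,
                             init = duohmm_params(), map_function = "haldane") {
  depth <- generation_depth(ped)
  ids <- hap_samples(haps)
  records <- list()
  h1 <- haps$h1; h2 <- haps$h2
  cm_f <- interpolate_cM(map, haps$markers$pos)
  cm_m <- min(cm_f) + (cm_f - min(cm_f)) * male_scale
  make_duo <- function(p, ch, sx) {
    duo_haplotypes(parent = p, child = ch, parent_sex = sx,
                   P = rbind(h1[p, ], h2[p, ]), C = rbind(h1[ch, ], h2[ch, ]),
                   pos = haps$markers$pos,
                   cM = if (sx == "male") cm_m else cm_f)
  }
  m <- pedigree_meioses(ped, genotyped_only = TRUE)
  m <- m[m$parent %in% ids & m$child %in% ids, , drop = FALSE]
  if (!nrow(m))
    return(list(haps = haps,
                records = data.frame(id = character(), marker = integer(),
                                     kind = character())))
  parents <- unique(m$parent)
  parents <- parents[order(depth[parents], parents)]
  for (p in parents) {
    kids <- m$child[m$parent == p]
    sx <- m$parent_sex[m$parent == p][1]
    decode <- function() {
      lapply(kids, function(ch) {
        duo <- make_duo(p, ch, sx)
        est <- estimate_params(duo, init = init, map_function = map_function)
        list(duo = duo, params = est, path = viterbi(duo, est))
      })
    }
    dec <- decode()
    if (length(kids) >= 2L) {
      fix <- correct_parent_min_recombinant(
        rbind(h1[p, ], h2[p, ]), lapply(dec, `[[`, "duo"),
        lapply(dec, `[[`, "path"), parent_id = p)
      if (nrow(fix$records)) {
        h1[p, ] <- fix$P[1L, ]; h2[p, ] <- fix$P[2L, ]
        records[[length(records) + 1L]] <- fix$records
        dec <- decode()  # re-decode children against the corrected parent
      }
    }
    for (k in seq_along(kids)) {
      kid <- kids[k]
      other <- setdiff(m$parent[m$child == kid], p)
      if (length(other) == 1L) {
        # both parents phased: reconcile the child across both duos via the
        # anchor-orientation scan, which separates child switch errors from
        # parental crossovers deterministically
        osx <- m$parent_sex[m$parent == other][1]
        qduo <- make_duo(other, kid, osx)
        estq <- estimate_params(qduo, init = init,
                                map_function = map_function)
        flips <- joint_child_flips(dec[[k]]$duo, qduo, dec[[k]]$path,
                                   viterbi(qduo, estq))
        if (length(flips$marker)) {
          C_new <- apply_suffix_flips(rbind(h1[kid, ], h2[kid, ]),
                                      flips$marker)
          h1[kid, ] <- C_new[1L, ]; h2[kid, ] <- C_new[2L, ]
          records[[length(records) + 1L]] <- data.frame(
            id = kid, marker = flips$marker, kind = flips$kind,
            stringsAsFactors = FALSE)
        }
      } else {
        cc <- correct_child(dec[[k]]$duo, dec[[k]]$path)
        if (nrow(cc$records)) {
          h1[kid, ] <- cc$C[1L, ]; h2[kid, ] <- cc$C[2L, ]
          records[[length(records) + 1L]] <- cc$records
        }
      }
    }
  }
  out <- haplotype_set(haps$markers, h1, h2)
  list(haps = out,
       records = if (length(records)) do.call(rbind, records)
       else data.frame(id = character(), marker = integer(),
                       kind = character()))
}
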