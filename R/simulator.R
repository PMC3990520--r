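# Simulation of validation cohorts with known truth: haploid pools with LD
# and shared IBD segments, pseudo-autosomal diploid founders assembled under
# a relatedness rejection scheme, Poisson crossovers on sex-scaled maps,
# and confusion-matrix genotyping error.

#' Simulate a hotspot-structured genetic map
#'
#' Human recombination is concentrated in narrow hotspots: a small fraction
#' of intervals carries most of the genetic length. This generator draws
#' per-interval genetic distances from a two-component mixture — a fraction
#' `hotspot_fraction` of intervals receive heavy-tailed (squared
#' exponential) weights, the rest a small constant background weight —
#' normalized to `total_cM`. The heavy tail reproduces the highly skewed
#' intensity distribution of fine-scale human maps, where the hottest
#' intervals carry a disproportionate share of the genetic length. The
#' hotspot intervals are returned alongside the map for use as a target
#' interval set in hotspot-usage analyses.
#'
#' @param n_markers number of markers.
#' @param spacing_bp physical spacing between adjacent markers.
#' @param total_cM total genetic length (female scale).
#' @param hotspot_fraction fraction of intervals that are hotspots.
#' @param background_weight relative weight of a non-hotspot interval
#'   (hotspot weights average 2).
#' @param chrom chromosome label.
#' @param seed integer seed.
#' @return list with `map` (a [genetic_map()]) and `hotspots` (data frame
#'   `chrom`, `start`, `end`, 1-based inclusive physical intervals).
#' @export
simulate_genetic_map <- function(n_markers = 2000L, spacing_bp = 5e4,
                                 total_cM = 100, hotspot_fraction = 0.05,
                                 background_weight = 0.02, chrom = "X",
                                 seed = 1L) {
  if (n_markers < 2L) stop("need at least 2 markers")
  pos <- seq(1e5, by = spacing_bp, length.out = n_markers)
  withr_seed(seed, {
    hot <- stats::runif(n_markers - 1L) < hotspot_fraction
    w <- ifelse(hot, stats::rexp(n_markers - 1L, 1)^2, background_weight)
  })
  d <- w / sum(w) * total_cM
  map <- genetic_map(pos, cum_cM = c(0, cumsum(d)), chrom = chrom)
  hotspots <- data.frame(chrom = chrom, start = pos[which(hot)],
                         end = pos[which(hot) + 1L], stringsAsFactors = FALSE)
  list(map = map, hotspots = hotspots)
}

#' Generate a synthetic haploid pool
#'
#' Haplotypes are generated by a copying-mosaic process: a small set of
#' template haplotypes is drawn first, then each pool haplotype copies
#' segments from the templates, switching template with per-interval
#' probability `1 - exp(-switch_rate * d_cM)` and flipping alleles at rate
#' `mut_rate`. The result has LD structure and long shared segments (IBD),
#' which the gene-flow model requires for signal. Fewer templates and a
#' lower switch rate give a higher-IBD pool. This is a synthetic stand-in
#' for a panel of male X chromosomes (whose phase is known unambiguously).
#'
#' @param n number of haploid sequences (>= 4, even).
#' @param map a [genetic_map()] defining marker positions.
#' @param n_templates number of founder template haplotypes.
#' @param switch_rate template-switch intensity per cM.
#' @param mut_rate per-site allele flip rate.
#' @param maf_range range of template allele frequencies.
#' @param seed integer seed; same seed gives an identical pool.
#' @return an object of class `haploid_pool`: list with `haplotypes`
#'   (n x L 0/1 matrix), `positions`, `map`.
#' @export
generate_haploid_pool <- function(n, map, n_templates = 8L, switch_rate = 0.1,
                                  mut_rate = 0.002, maf_range = c(0.1, 0.9),
                                  seed = 1L) {
  if (n < 4L) stop("pool size must be at least 4")
  if (n %% 2L != 0L) stop("pool size must be even")
  pos <- map$positions
  L <- length(pos)
  cm <- map$cum_cM
  p_switch <- 1 - exp(-switch_rate * diff(cm))
  withr_seed(seed, {
    freqs <- stats::runif(L, maf_range[1], maf_range[2])
    templates <- matrix(stats::rbinom(n_templates * L, 1L, rep(freqs, each = n_templates)),
                        nrow = n_templates, ncol = L)
    if (n_templates > 1L) {
      # keep every marker segregating among the templates themselves, so
      # polymorphism does not rely on private mutations
      mono_t <- which(colSums(templates) %in% c(0L, n_templates))
      if (length(mono_t))
        templates[cbind(sample.int(n_templates, length(mono_t), replace = TRUE),
                        mono_t)] <- 1L - templates[cbind(1L, mono_t)]
    }
    H <- matrix(0L, nrow = n, ncol = L)
    for (k in seq_len(n)) {
      switches <- c(FALSE, stats::runif(L - 1L) < p_switch)
      seg <- cumsum(switches)
      tpl <- sample.int(n_templates, max(seg) + 1L, replace = TRUE)
      src <- tpl[seg + 1L]
      h <- templates[cbind(src, seq_len(L))]
      if (mut_rate > 0) {
        mut <- stats::runif(L) < mut_rate
        h[mut] <- 1L - h[mut]
      }
      H[k, ] <- h
    }
    # polymorphic retention: monomorphic sites get one allele flipped so
    # every marker is segregating in the pool (mirrors the marker filter a
    # genotyping panel applies)
    if (mut_rate > 0 || n_templates > 1L) {
      mono <- which(colMeans(H) %in% c(0, 1))
      if (length(mono))
        H[cbind(sample.int(n, length(mono), replace = TRUE), mono)] <-
          1L - H[cbind(1L, mono)]
    }
  })
  rownames(H) <- sprintf("HAP%03d", seq_len(n))
  structure(list(haplotypes = H, positions = pos, map = map),
            class = "haploid_pool")
}

# run expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Genome-wide realised relatedness between two genotype vectors
#'
#' Centered-and-scaled genotype correlation
#' \eqn{\sum_l (g_{il} - m p_l)(g_{jl} - m p_l) / \sum_l m p_l (1 - p_l)},
#' where m is the ploidy (2 for diploid genotypes in 0..2, 1 for haploid
#' 0/1 vectors). Its expectation is approximately twice the kinship
#' coefficient. Monomorphic markers are excluded.
#'
#' @param g_i,g_j genotype vectors (same length).
#' @param allele_freqs allele frequencies per marker in (0, 1).
#' @param ploidy 1 for haploid sequences, 2 for diploid genotypes.
#' @return relatedness estimate (symmetric in its arguments).
#' @export
relatedness <- function(g_i, g_j, allele_freqs, ploidy = NULL) {
  stopifnot(length(g_i) == length(g_j), length(g_i) == length(allele_freqs))
  if (is.null(ploidy))
    ploidy <- if (max(c(g_i, g_j), na.rm = TRUE) > 1L) 2L else 1L
  keep <- allele_freqs > 0 & allele_freqs < 1 & !is.na(g_i) & !is.na(g_j)
  if (!any(keep)) stop("no polymorphic markers available")
  p <- allele_freqs[keep]
  num <- sum((g_i[keep] - ploidy * p) * (g_j[keep] - ploidy * p))
  den <- sum(ploidy * p * (1 - p))
  num / den
}

#' Assemble diploid founders from a haploid pool
#'
#' Combines disjoint pairs of haploid sequences into pseudo-autosomal diploid
#' founders with known truth haplotypes. A rejection sampling scheme avoids
#' consanguinity: a candidate pair is rejected when the realised relatedness
#' of its two source haplotypes exceeds `relatedness_threshold`.
#'
#' @param pool a [generate_haploid_pool()] result.
#' @param n_diploids number of founders (<= pool size / 2); default the
#'   maximum.
#' @param relatedness_threshold rejection threshold (1 disables rejection);
#'   default 0.05.
#' @param seed integer seed.
#' @param max_attempts resampling attempts before giving up.
#' @return list with `h1`, `h2` (n_diploids x L truth haplotypes, rownames
#'   founder ids), `sources` (pair of pool row indices per founder).
#' @export
make_founders <- function(pool, n_diploids = NULL,
                          relatedness_threshold = 0.05, seed = 1L,
                          max_attempts = 1000L) {
  H <- pool$haplotypes
  n_hap <- nrow(H)
  if (is.null(n_diploids)) n_diploids <- n_hap %/% 2L
  if (2L * n_diploids > n_hap)
    stop("pool of ", n_hap, " haploids supports at most ", n_hap %/% 2L,
         " diploids")
  freqs <- colMeans(H)
  ok_freq <- freqs > 0 & freqs < 1
  withr_seed(seed, {
    perm <- sample.int(n_hap)
    a <- perm[seq_len(n_diploids) * 2L - 1L]
    b <- perm[seq_len(n_diploids) * 2L]
    if (relatedness_threshold < 1) {
      unused <- setdiff(perm, c(a, b))
      for (attempt in seq_len(max_attempts)) {
        rel <- vapply(seq_len(n_diploids), function(i)
          relatedness(H[a[i], ok_freq], H[b[i], ok_freq], freqs[ok_freq],
                      ploidy = 1L), numeric(1))
        bad <- which(rel > relatedness_threshold)
        if (!length(bad)) break
        if (attempt == max_attempts)
          stop("rejection sampling failed after ", max_attempts,
               " attempts; raise relatedness_threshold")
        # re-pair offending pairs among themselves and any unused haplotypes
        free <- sample(c(a[bad], b[bad], unused))
        a[bad] <- free[seq_along(bad)]
        b[bad] <- free[length(bad) + seq_along(bad)]
        unused <- free[-seq_len(2L * length(bad))]
      }
    }
  })
  ids <- sprintf("F%03d", seq_len(n_diploids))
  h1 <- H[a, , drop = FALSE]; h2 <- H[b, , drop = FALSE]
  rownames(h1) <- rownames(h2) <- ids
  list(h1 = h1, h2 = h2, sources = cbind(a, b))
}

#' Simulate one meiosis
#'
#' The crossover count is Poisson with mean equal to the sex-specific map
#' length in Morgans; crossover positions are uniform on the genetic scale;
#' the transmitted gamete alternates source haplotype at each crossover,
#' starting from a fair-coin choice.
#'
#' @param parent_haps 2 x L matrix of the parent's true haplotypes.
#' @param map a [genetic_map()] (sex-averaged or female).
#' @param sex `"male"` or `"female"`; determines the scaled map.
#' @param male_scale scaling factor for male meioses.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return list with `gamete` (length-L 0/1 vector), `start` (source
#'   haplotype at the first marker, 1 or 2) and `crossovers` (data frame cM,
#'   left_pos, right_pos; crossovers outside the marker range are dropped
#'   from the table as they affect no marker).
#' @export
simulate_meiosis <- function(parent_haps, map, sex = c("female", "male"),
                             male_scale = 0.605, seed = NULL) {
  sex <- match.arg(sex)
  run <- function() {
    smap <- if (sex == "male") sex_scale(map, "male", factor = male_scale)
    else map
    cm <- interpolate_cM(smap, map$positions)
    total_M <- (max(cm) - min(cm)) / 100
    k <- stats::rpois(1L, total_M)
    start <- sample.int(2L, 1L)
    L <- ncol(parent_haps)
    if (k == 0L || total_M == 0) {
      return(list(gamete = parent_haps[start, ], start = start,
                  crossovers = data.frame(cM = numeric(), left_pos = numeric(),
                                          right_pos = numeric())))
    }
    xo_cM <- sort(stats::runif(k, min(cm), max(cm)))
    src <- 1L + (start - 1L + findInterval(cm, xo_cM, left.open = TRUE)) %% 2L
    gamete <- parent_haps[cbind(src, seq_len(L))]
    li <- findInterval(xo_cM, cm)
    keep <- li >= 1L & li < L
    xo <- data.frame(cM = xo_cM[keep],
                     left_pos = map$positions[li[keep]],
                     right_pos = map$positions[li[keep] + 1L])
    list(gamete = gamete, start = start, crossovers = xo)
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

#' Default genotype confusion matrix
#'
#' Row-stochastic 4 x 4 matrix over observed genotype (0, 1, 2, missing)
#' given true genotype, with a small realistic error mass concentrated on
#' adjacent genotype classes and missingness. This is a synthetic stand-in
#' calibrated to typical SNP-array error rates; a study-specific matrix can
#' be supplied wherever a confusion matrix is accepted.
#'
#' @param error per-genotype miscall mass (split over the other classes).
#' @param missing_rate per-genotype missingness.
#' @return 4 x 4 matrix with dimnames 0/1/2/NA.
#' @export
default_confusion_matrix <- function(error = 0.002, missing_rate = 0.002) {
  m <- matrix(0, 4L, 4L, dimnames = list(c("0", "1", "2", "NA"),
                                         c("0", "1", "2", "NA")))
  m["0", ] <- c(1 - error - missing_rate, 0.9 * error, 0.1 * error, missing_rate)
  m["1", ] <- c(0.5 * error, 1 - error - missing_rate, 0.5 * error, missing_rate)
  m["2", ] <- c(0.1 * error, 0.9 * error, 1 - error - missing_rate, missing_rate)
  m["NA", ] <- c(0, 0, 0, 1)
  m
}

#' Build a simulated cohort of mother-father-child trios
#'
#' Pairs pseudo-autosomal diploid founders into couples and simulates one
#' child per couple, recording truth haplotypes and crossover positions. The
#' trio count is `floor(n_haploids / 4)`.
#'
#' @param pool a [generate_haploid_pool()] result.
#' @param map a [genetic_map()].
#' @param relatedness_threshold founder rejection threshold.
#' @param male_scale male map scaling.
#' @param seed integer seed.
#' @return a `simulated_cohort`: list with `ped` ([pedigree()]), `truth_h1`,
#'   `truth_h2` (individuals x L), `genotypes` (truth-derived, before
#'   corruption), `obs_h1`, `obs_h2` (observed haplotypes, initially equal to
#'   truth), `crossovers` (parent, child, parent_sex, cM, left_pos,
#'   right_pos), `error_sites`, `switch_sites`, `map`, `seed`.
#' @export
build_trio_cohort <- function(pool, map, relatedness_threshold = 1,
                              male_scale = 0.605, seed = 1L) {
  n_hap <- nrow(pool$haplotypes)
  n_trios <- n_hap %/% 4L
  if (n_trios < 1L) stop("pool too small for any trio")
  founders <- make_founders(pool, 2L * n_trios,
                            relatedness_threshold = relatedness_threshold,
                            seed = seed)
  fathers <- sprintf("FA%03d", seq_len(n_trios))
  mothers <- sprintf("MO%03d", seq_len(n_trios))
  children <- sprintf("CH%03d", seq_len(n_trios))
  fam <- sprintf("TRIO%03d", seq_len(n_trios))
  L <- ncol(founders$h1)
  ids <- c(fathers, mothers, children)
  h1 <- matrix(0L, length(ids), L, dimnames = list(ids, NULL))
  h2 <- h1
  h1[fathers, ] <- founders$h1[seq_len(n_trios), , drop = FALSE]
  h2[fathers, ] <- founders$h2[seq_len(n_trios), , drop = FALSE]
  h1[mothers, ] <- founders$h1[n_trios + seq_len(n_trios), , drop = FALSE]
  h2[mothers, ] <- founders$h2[n_trios + seq_len(n_trios), , drop = FALSE]
  xo <- list()
  tx <- list()
  withr_seed(seed + 104729L, {
    for (t in seq_len(n_trios)) {
      pat <- simulate_meiosis(rbind(h1[fathers[t], ], h2[fathers[t], ]), map,
                              sex = "male", male_scale = male_scale)
      mat <- simulate_meiosis(rbind(h1[mothers[t], ], h2[mothers[t], ]), map,
                              sex = "female")
      h1[children[t], ] <- pat$gamete  # paternal haplotype first
      h2[children[t], ] <- mat$gamete
      tx[[length(tx) + 1L]] <- data.frame(
        parent = c(fathers[t], mothers[t]), child = children[t],
        parent_sex = c("male", "female"), start_hap = c(pat$start, mat$start),
        stringsAsFactors = FALSE)
      if (nrow(pat$crossovers))
        xo[[length(xo) + 1L]] <- cbind(parent = fathers[t],
                                       child = children[t],
                                       parent_sex = "male", pat$crossovers)
      if (nrow(mat$crossovers))
        xo[[length(xo) + 1L]] <- cbind(parent = mothers[t],
                                       child = children[t],
                                       parent_sex = "female", mat$crossovers)
    }
  })
  ped <- pedigree(data.frame(
    family = rep(fam, 3L), id = ids,
    father = c(rep(NA, 2L * n_trios), fathers),
    mother = c(rep(NA, 2L * n_trios), mothers),
    sex = c(rep(1L, n_trios), rep(2L, n_trios), rep(0L, n_trios)),
    stringsAsFactors = FALSE))
  new_cohort(ped, h1, h2, pool, map,
             if (length(xo)) do.call(rbind, xo) else empty_crossovers(), seed,
             transmissions = do.call(rbind, tx))
}

empty_crossovers <- function() {
  data.frame(parent = character(), child = character(),
             parent_sex = character(), cM = numeric(), left_pos = numeric(),
             right_pos = numeric(), stringsAsFactors = FALSE)
}

new_cohort <- function(ped, h1, h2, pool, map, crossovers, seed,
                       transmissions = NULL) {
  if (is.null(transmissions))
    transmissions <- data.frame(parent = character(), child = character(),
                                parent_sex = character(),
                                start_hap = integer(), stringsAsFactors = FALSE)
  structure(list(
    ped = ped, truth_h1 = h1, truth_h2 = h2,
    genotypes = {
      g <- h1 + h2
      mode(g) <- "integer"
      g
    },
    obs_h1 = h1, obs_h2 = h2,
    crossovers = crossovers,
    error_sites = data.frame(id = character(), marker = integer(),
                             true_g = integer(), obs_g = integer(),
                             stringsAsFactors = FALSE),
    switch_sites = data.frame(id = character(), marker = integer(),
                              stringsAsFactors = FALSE),
    transmissions = transmissions,
    positions = pool$positions, map = map, seed = seed),
    class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "simulated_cohort: %d individuals x %d markers, %d crossovers, %d error sites, %d switch sites\n",
    nrow(x$truth_h1), ncol(x$truth_h1), nrow(x$crossovers),
    nrow(x$error_sites), nrow(x$switch_sites)))
  invisible(x)
}

#' Build a simulated cohort from explicit pedigree structures
#'
#' Draws founders for each structure from the pool (with relatedness
#' rejection) and simulates descendants down the structure by repeated
#' meioses. Individuals whose `genotyped` flag is FALSE (for example
#' ungenotyped founders) are retained in the truth but marked ungenotyped in
#' the pedigree when `drop_ungenotyped_founders` is set.
#'
#' @param pool a [generate_haploid_pool()] result.
#' @param structures list of [pedigree()] objects (template ids are reused
#'   as-is and must be unique across structures).
#' @param map a [genetic_map()].
#' @param drop_ungenotyped_founders honour FALSE `genotyped` flags.
#' @param relatedness_threshold founder rejection threshold.
#' @param male_scale male map scaling.
#' @param seed integer seed.
#' @return a `simulated_cohort`.
#' @export
build_pedigree_cohort <- function(pool, structures, map,
                                  drop_ungenotyped_founders = FALSE,
                                  relatedness_threshold = 1,
                                  male_scale = 0.605, seed = 1L) {
  ped <- do.call(rbind, lapply(structures, as.data.frame))
  ped <- pedigree(ped)
  founder_ids <- ped$id[is.na(ped$father) & is.na(ped$mother)]
  n_f <- length(founder_ids)
  if (2L * n_f > nrow(pool$haplotypes))
    stop("structures need ", n_f, " founders; pool supports only ",
         nrow(pool$haplotypes) %/% 2L)
  founders <- make_founders(pool, n_f,
                            relatedness_threshold = relatedness_threshold,
                            seed = seed)
  L <- ncol(founders$h1)
  ids <- ped$id
  h1 <- matrix(0L, length(ids), L, dimnames = list(ids, NULL))
  h2 <- h1
  h1[founder_ids, ] <- founders$h1
  h2[founder_ids, ] <- founders$h2
  xo <- list()
  tx <- list()
  depth <- generation_depth(ped)
  withr_seed(seed + 104729L, {
    for (k in order(depth[ped$id])) {
      if (depth[ped$id[k]] == 0L) next
      ch <- ped$id[k]
      fa <- ped$father[k]; mo <- ped$mother[k]
      if (is.na(fa) || is.na(mo))
        stop("non-founder ", ch, " must have both parents in the structure")
      pat <- simulate_meiosis(rbind(h1[fa, ], h2[fa, ]), map, sex = "male",
                              male_scale = male_scale)
      mat <- simulate_meiosis(rbind(h1[mo, ], h2[mo, ]), map, sex = "female")
      h1[ch, ] <- pat$gamete
      h2[ch, ] <- mat$gamete
      tx[[length(tx) + 1L]] <- data.frame(
        parent = c(fa, mo), child = ch, parent_sex = c("male", "female"),
        start_hap = c(pat$start, mat$start), stringsAsFactors = FALSE)
      if (nrow(pat$crossovers))
        xo[[length(xo) + 1L]] <- cbind(parent = fa, child = ch,
                                       parent_sex = "male", pat$crossovers)
      if (nrow(mat$crossovers))
        xo[[length(xo) + 1L]] <- cbind(parent = mo, child = ch,
                                       parent_sex = "female", mat$crossovers)
    }
  })
  if (!drop_ungenotyped_founders) ped$genotyped <- TRUE
  new_cohort(ped, h1, h2, pool, map,
             if (length(xo)) do.call(rbind, xo) else empty_crossovers(), seed,
             transmissions = do.call(rbind, tx))
}

#' Apply confusion-matrix genotyping error to a cohort
#'
#' Each observed genotype is independently resampled from the row of the
#' confusion matrix indexed by its true genotype. Corrupted sites are
#' recorded and the observed haplotypes updated: a corrupted heterozygote
#' receives a random phase orientation, homozygotes receive both alleles,
#' and missing genotypes missing alleles.
#'
#' @param cohort a `simulated_cohort`.
#' @param confusion 4 x 4 row-stochastic matrix over observed genotype
#'   0/1/2/missing given true genotype (rows 0/1/2/missing).
#' @param seed integer seed.
#' @return the cohort with corrupted `genotypes`, `obs_h1`, `obs_h2` and
#'   populated `error_sites`.
#' @export
apply_genotype_errors <- function(cohort, confusion, seed = 1L) {
  if (!all(dim(confusion) == c(4L, 4L)))
    stop("confusion matrix must be 4 x 4")
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-8))
    stop("confusion matrix rows must be non-negative and sum to 1")
  g <- cohort$genotypes
  n <- nrow(g); L <- ncol(g)
  withr_seed(seed + 15485863L, {
    gv <- as.integer(g)  # column-major vector
    obs <- gv
    for (tg in 0:2) {
      idx <- which(gv == tg)
      if (!length(idx)) next
      draw <- sample.int(4L, length(idx), replace = TRUE,
                         prob = confusion[tg + 1L, ])
      obs[idx] <- c(0L, 1L, 2L, NA_integer_)[draw]
    }
  })
  changed <- which(is.na(obs) | obs != gv)
  obs_m <- matrix(obs, n, L, dimnames = dimnames(g))
  oh1 <- cohort$obs_h1; oh2 <- cohort$obs_h2
  if (length(changed)) {
    rr <- ((changed - 1L) %% n) + 1L
    cc <- ((changed - 1L) %/% n) + 1L
    new_g <- obs[changed]
    withr_seed(seed + 32452843L, {
      flip <- stats::runif(length(changed)) < 0.5
    })
    a1 <- ifelse(is.na(new_g), NA_integer_,
                 ifelse(new_g == 1L, ifelse(flip, 1L, 0L), new_g %/% 2L))
    a2 <- ifelse(is.na(new_g), NA_integer_,
                 ifelse(new_g == 1L, 1L - a1, new_g %/% 2L))
    oh1[cbind(rr, cc)] <- a1
    oh2[cbind(rr, cc)] <- a2
  }
  cohort$genotypes <- obs_m
  cohort$obs_h1 <- oh1
  cohort$obs_h2 <- oh2
  cohort$error_sites <- if (length(changed)) data.frame(
    id = rownames(g)[((changed - 1L) %% n) + 1L],
    marker = ((changed - 1L) %/% n) + 1L,
    true_g = gv[changed], obs_g = obs[changed], stringsAsFactors = FALSE)
  else cohort$error_sites
  cohort
}

#' Emulate population-phasing switch errors
#'
#' Statistical phasing engines resolve a heterozygous site correctly when the
#' individual shares a long haplotype segment (IBD) with another cohort
#' member spanning the site; elsewhere phase must be inferred from LD alone
#' and switch errors occur. This emulator injects switch errors into the
#' observed haplotypes at heterozygous sites drawn at `rate` per het site,
#' but (when `ibd_aware`) only at sites where neither of the individual's
#' haplotypes is identical to some haplotype of an individual outside the
#' individual's own family across a window of `window` markers either side.
#' High-IBD cohorts therefore receive fewer switch errors, as observed for
#' real phasing output. Within-family sharing is deliberately not counted as
#' support: it is the signal the gene-flow model itself consumes, and real
#' engines exploit it imperfectly, leaving residual errors for the model to
#' correct.
#'
#' @param cohort a `simulated_cohort`.
#' @param rate candidate switch-error rate per heterozygous site.
#' @param ibd_aware suppress errors at IBD-supported sites.
#' @param window half-window (markers) for IBD support.
#' @param ids restrict injection to these individuals (default all).
#' @param seed integer seed.
#' @return the cohort with updated `obs_h1`, `obs_h2` and `switch_sites`.
#' @export
inject_switch_errors <- function(cohort, rate = 0.01, ibd_aware = TRUE,
                                 window = 25L, ids = NULL, seed = 1L) {
  H1 <- cohort$obs_h1; H2 <- cohort$obs_h2
  n <- nrow(H1); L <- ncol(H1)
  allh <- rbind(cohort$truth_h1, cohort$truth_h2)
  fam <- stats::setNames(cohort$ped$family, cohort$ped$id)
  owner_fam <- rep(fam[rownames(H1)], 2L)
  targets <- if (is.null(ids)) seq_len(n) else match(ids, rownames(H1))
  sw <- list()
  withr_seed(seed + 49979687L, {
    for (k in targets) {
      het <- which(H1[k, ] != H2[k, ] & !is.na(H1[k, ]) & !is.na(H2[k, ]))
      if (!length(het)) next
      cand <- het[stats::runif(length(het)) < rate]
      if (!length(cand)) next
      if (ibd_aware) {
        outside <- owner_fam != fam[rownames(H1)[k]]
        supported <- vapply(cand, function(l) {
          lo <- max(1L, l - window); hi <- min(L, l + window)
          others <- t(allh[outside, lo:hi, drop = FALSE])
          for (h in c(k, n + k)) {
            if (any(colSums(others != allh[h, lo:hi]) == 0L)) return(TRUE)
          }
          FALSE
        }, logical(1))
        cand <- cand[!supported]
      }
      if (!length(cand)) next
      parity <- cumsum(seq_len(L) %in% cand) %% 2L == 1L
      tmp <- H1[k, parity]
      H1[k, parity] <- H2[k, parity]
      H2[k, parity] <- tmp
      sw[[length(sw) + 1L]] <- data.frame(id = rownames(H1)[k], marker = cand,
                                          stringsAsFactors = FALSE)
    }
  })
  cohort$obs_h1 <- H1
  cohort$obs_h2 <- H2
  cohort$switch_sites <- if (length(sw)) do.call(rbind, sw)
  else cohort$switch_sites
  cohort
}

#' Observed haplotypes of a cohort as a haplotype set
#'
#' @param cohort a `simulated_cohort`.
#' @param genotyped_only drop individuals flagged ungenotyped.
#' @return a [haplotype_set()].
#' @export
cohort_haplotypes <- function(cohort, genotyped_only = TRUE) {
  ids <- rownames(cohort$obs_h1)
  if (genotyped_only) {
    g <- stats::setNames(cohort$ped$genotyped, cohort$ped$id)
    ids <- ids[g[ids]]
  }
  markers <- data.frame(id = sprintf("M%05d", seq_along(cohort$positions)),
                        chrom = cohort$map$chrom, pos = cohort$positions,
                        stringsAsFactors = FALSE)
  haplotype_set(markers, cohort$obs_h1[ids, , drop = FALSE],
                cohort$obs_h2[ids, , drop = FALSE])
}

#' Truth haplotypes of a cohort as a haplotype set
#' @param cohort a `simulated_cohort`.
#' @return a [haplotype_set()].
#' @export
cohort_truth <- function(cohort) {
  markers <- data.frame(id = sprintf("M%05d", seq_along(cohort$positions)),
                        chrom = cohort$map$chrom, pos = cohort$positions,
                        stringsAsFactors = FALSE)
  haplotype_set(markers, cohort$truth_h1, cohort$truth_h2)
}
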