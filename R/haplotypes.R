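#' Haplotype set objects
#'
#' A `haplotype_set` stores phased biallelic haplotypes: a marker table
#' (`id`, `chrom`, `pos`, strictly increasing positions) and, per sample, two
#' haplotype vectors over \{0, 1, NA\}. Haplotypes are stored as two
#' `n_samples x L` integer matrices `h1` and `h2` with sample ids as
#' rownames.
#'
#' @param markers data frame with columns `id`, `chrom`, `pos`.
#' @param h1,h2 integer matrices (samples x markers), alleles 0/1/NA.
#' @return an object of class `haplotype_set`.
#' @export
haplotype_set <- function(markers, h1, h2) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos") %in% names(markers)))
  if (any(diff(markers$pos) <= 0))
    stop("marker positions must be strictly increasing")
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  if (!identical(dim(h1), dim(h2)))
    stop("h1 and h2 must have identical dimensions")
  if (ncol(h1) != nrow(markers))
    stop("haplotype matrices must have one column per marker")
  if (is.null(rownames(h1))) stop("haplotype matrices need sample id rownames")
  rownames(h2) <- rownames(h1)
  structure(list(markers = markers, h1 = h1, h2 = h2),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d samples x %d markers (chrom %s)\n",
              nrow(x$h1), nrow(x$markers), x$markers$chrom[1]))
  invisible(x)
}

#' Sample ids of a haplotype set
#' @param haps a [haplotype_set()].
#' @export
hap_samples <- function(haps) rownames(haps$h1)

#' Read phased haplotypes
#'
#' Reads SHAPEIT HAPS/SAMPLE or phased VCF into a [haplotype_set()].
#' Unphased or multiallelic VCF records are skipped (a message reports the
#' count). HAPS format: one row per marker with columns chrom, id, pos,
#' allele0, allele1, then two allele columns (0/1) per sample in SAMPLE
#' order; the SAMPLE file has two header lines.
#'
#' @param path path to the `.haps` or `.vcf` file.
#' @param format `"haps_sample"` or `"vcf"`.
#' @param sample_path for `haps_sample`, path to the SAMPLE file; defaults to
#'   `path` with the extension replaced by `.sample`.
#' @return a [haplotype_set()].
#' @export
read_haplotypes <- function(path, format = c("haps_sample", "vcf"),
                            sample_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("haplotype file not found: ", path)
  if (format == "haps_sample") {
    if (is.null(sample_path))
      sample_path <- paste0(sub("\\.haps(\\.gz)?$", "", path), ".sample")
    if (!file.exists(sample_path))
      stop("SAMPLE file not found: ", sample_path)
    smp <- utils::read.table(sample_path, header = TRUE,
                             stringsAsFactors = FALSE)
    smp <- smp[-1, , drop = FALSE]  # second header line of types
    ids <- as.character(smp[[2]])
    hp <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(hp) == 0L) stop("no markers in ", path)
    L <- nrow(hp)
    if (ncol(hp) != 5L + 2L * length(ids))
      stop("HAPS column count does not match SAMPLE file")
    al <- as.matrix(hp[, -(1:5), drop = FALSE])
    mode(al) <- "integer"
    al[al < 0L] <- NA_integer_  # "-1" encodes a missing allele
    h1 <- t(al[, seq(1L, ncol(al), by = 2L), drop = FALSE])
    h2 <- t(al[, seq(2L, ncol(al), by = 2L), drop = FALSE])
    rownames(h1) <- rownames(h2) <- ids
    markers <- data.frame(id = as.character(hp[[2]]),
                          chrom = as.character(hp[[1]]),
                          pos = as.numeric(hp[[3]]), stringsAsFactors = FALSE)
    return(haplotype_set(markers, h1, h2))
  }
  # VCF via vcfR
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) stop("no genotype records in ", path)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "."
  phased <- apply(gt, 1L, function(r) all(is.na(r) | grepl("^[01.]\\|[01.]$", r)))
  keep <- biallelic & phased
  skipped <- sum(!keep)
  if (skipped > 0L)
    message(skipped, " unphased or multiallelic record(s) skipped")
  if (!any(keep)) stop("no phased biallelic markers in ", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  a1 <- suppressWarnings(matrix(as.integer(sub("\\|.*$", "", gt)),
                                nrow = nrow(gt), dimnames = dimnames(gt)))
  a2 <- suppressWarnings(matrix(as.integer(sub("^.*\\|", "", gt)),
                                nrow = nrow(gt), dimnames = dimnames(gt)))
  h1 <- t(a1); h2 <- t(a2)
  markers <- data.frame(id = ifelse(fix[, "ID"] == "." | is.na(fix[, "ID"]),
                                    paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                    fix[, "ID"]),
                        chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                        stringsAsFactors = FALSE)
  o <- order(markers$pos)
  haplotype_set(markers[o, ], h1[, o, drop = FALSE], h2[, o, drop = FALSE])
}

#' Write phased haplotypes
#'
#' @param haps a [haplotype_set()].
#' @param path output path (`.haps` or `.vcf`).
#' @param format `"haps_sample"` or `"vcf"`.
#' @param sample_path SAMPLE output path for `haps_sample`.
#' @param header_lines optional comment lines prepended as `#` lines to the
#'   VCF header or written to a sidecar for HAPS.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(haps, path, format = c("haps_sample", "vcf"),
                             sample_path = NULL, header_lines = NULL) {
  format <- match.arg(format)
  ids <- hap_samples(haps)
  if (format == "haps_sample") {
    if (is.null(sample_path))
      sample_path <- paste0(sub("\\.haps$", "", path), ".sample")
    L <- nrow(haps$markers)
    al <- matrix(NA_integer_, nrow = L, ncol = 2L * length(ids))
    al[, seq(1L, ncol(al), 2L)] <- t(haps$h1)
    al[, seq(2L, ncol(al), 2L)] <- t(haps$h2)
    al[is.na(al)] <- -1L  # missing code
    out <- cbind(haps$markers$chrom, haps$markers$id,
                 format(haps$markers$pos, scientific = FALSE, trim = TRUE),
                 "A", "C", al)
    utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE, sep = " ")
    smp <- rbind(c("0", "0", "0"), cbind(ids, ids, "0"))
    writeLines(c("ID_1 ID_2 missing", apply(smp, 1L, paste, collapse = " ")),
               sample_path)
    return(invisible(path))
  }
  gt <- matrix("", nrow = nrow(haps$markers), ncol = length(ids))
  a1 <- t(haps$h1); a2 <- t(haps$h2)
  gt[] <- paste0(ifelse(is.na(a1), ".", a1), "|", ifelse(is.na(a2), ".", a2))
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(header_lines)) paste0("##", header_lines),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- cbind(haps$markers$chrom,
                format(haps$markers$pos, scientific = FALSE, trim = TRUE),
                haps$markers$id, "A", "C", ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Unphased genotypes from a haplotype set
#'
#' @param haps a [haplotype_set()].
#' @return integer matrix (samples x markers) with values 0/1/2/NA.
#' @export
genotypes_from_haplotypes <- function(haps) {
  g <- haps$h1 + haps$h2
  mode(g) <- "integer"
  g
}

#' Mendelian-consistency QC
#'
#' Detects genotype configurations that violate Mendelian transmission within
#' each pedigree (duo checks: opposite homozygotes; trio checks: full
#' transmission table). Any locus with a violation is set missing for all
#' members of the pedigree in which the violation occurred; loci violating in
#' more than `locus_violation_fraction` of pedigrees are excluded cohort-wide.
#'
#' @param genotypes integer matrix (samples x markers), values 0/1/2/NA.
#' @param ped a [pedigree()] whose genotyped ids appear in
#'   `rownames(genotypes)`.
#' @param locus_violation_fraction cohort-wide exclusion threshold (fraction
#'   of pedigrees with a violation at the locus); default 0.05.
#' @return list with `genotypes` (masked matrix), `excluded_loci` (integer
#'   marker indices excluded cohort-wide) and `family_masked` (data frame
#'   family, marker).
#' @export
mendel_qc <- function(genotypes, ped, locus_violation_fraction = 0.05) {
  ids <- rownames(genotypes)
  if (is.null(ids)) stop("genotype matrix needs sample id rownames")
  gped <- ped[ped$genotyped & ped$id %in% ids, , drop = FALSE]
  missing_ids <- setdiff(ped$id[ped$genotyped], ids)
  if (length(missing_ids))
    stop("genotyped pedigree member(s) absent from genotype matrix: ",
         paste(utils::head(missing_ids, 3L), collapse = ", "))
  fams <- unique(gped$family)
  L <- ncol(genotypes)
  viol_by_fam <- matrix(FALSE, nrow = length(fams), ncol = L)
  rownames(viol_by_fam) <- fams
  for (fam in fams) {
    sub <- ped[ped$family == fam, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      ch <- sub$id[k]
      if (!(ch %in% ids)) next
      f <- sub$father[k]; m <- sub$mother[k]
      gf <- if (!is.na(f) && f %in% ids) genotypes[f, ] else NULL
      gm <- if (!is.na(m) && m %in% ids) genotypes[m, ] else NULL
      gc <- genotypes[ch, ]
      v <- rep(FALSE, L)
      if (!is.null(gf)) v <- v | mendel_duo_violation(gf, gc)
      if (!is.null(gm)) v <- v | mendel_duo_violation(gm, gc)
      if (!is.null(gf) && !is.null(gm)) v <- v | mendel_trio_violation(gf, gm, gc)
      viol_by_fam[fam, ] <- viol_by_fam[fam, ] | v
    }
  }
  masked <- genotypes
  fam_masked <- list()
  for (fam in fams) {
    loci <- which(viol_by_fam[fam, ])
    if (!length(loci)) next
    members <- intersect(ped$id[ped$family == fam], ids)
    masked[members, loci] <- NA_integer_
    fam_masked[[fam]] <- data.frame(family = fam, marker = loci,
                                    stringsAsFactors = FALSE)
  }
  frac <- colMeans(viol_by_fam)
  excluded <- which(frac > locus_violation_fraction)
  if (length(excluded)) masked[, excluded] <- NA_integer_
  list(genotypes = masked, excluded_loci = excluded,
       family_masked = if (length(fam_masked)) do.call(rbind, fam_masked)
       else data.frame(family = character(), marker = integer()))
}

# parent/child opposite homozygotes are impossible
mendel_duo_violation <- function(gp, gc) {
  !is.na(gp) & !is.na(gc) & ((gp == 0L & gc == 2L) | (gp == 2L & gc == 0L))
}

# full trio transmission table
mendel_trio_violation <- function(gf, gm, gc) {
  ok <- !is.na(gf) & !is.na(gm) & !is.na(gc)
  v <- rep(FALSE, length(gc))
  # child must receive one allele from each parent
  v[ok] <- (gf[ok] == 0L & gm[ok] == 0L & gc[ok] != 0L) |
    (gf[ok] == 2L & gm[ok] == 2L & gc[ok] != 2L) |
    (((gf[ok] == 0L & gm[ok] == 2L) | (gf[ok] == 2L & gm[ok] == 0L)) &
       gc[ok] != 1L) |
    (gf[ok] == 0L & gm[ok] == 1L & gc[ok] == 2L) |
    (gf[ok] == 1L & gm[ok] == 0L & gc[ok] == 2L) |
    (gf[ok] == 2L & gm[ok] == 1L & gc[ok] == 0L) |
    (gf[ok] == 1L & gm[ok] == 2L & gc[ok] == 0L)
  v
}

#' Extract parent-child duos from a pedigree and haplotype set
#'
#' One duo per genotyped, phased parent-child pair; meioses where either
#' member lacks haplotypes yield no duo.
#'
#' @param ped a [pedigree()].
#' @param haps a [haplotype_set()].
#' @param map optional [genetic_map()]; when given, each duo carries
#'   sex-scaled genetic positions (`male_scale` applied for male parents).
#' @param male_scale scaling factor applied to the map for male parents.
#' @return list of `duo_haplotypes` objects.
#' @export
extract_duos <- function(ped, haps, map = NULL, male_scale = 0.605) {
  ids <- hap_samples(haps)
  m <- pedigree_meioses(ped, genotyped_only = TRUE)
  m <- m[m$parent %in% ids & m$child %in% ids, , drop = FALSE]
  cm_m <- cm_f <- NULL
  if (!is.null(map)) {
    cm_f <- interpolate_cM(map, haps$markers$pos)
    cm_m <- min(cm_f) + (cm_f - min(cm_f)) * male_scale
  }
  lapply(seq_len(nrow(m)), function(i) {
    sx <- m$parent_sex[i]
    duo_haplotypes(
      parent = m$parent[i], child = m$child[i], parent_sex = sx,
      P = rbind(haps$h1[m$parent[i], ], haps$h2[m$parent[i], ]),
      C = rbind(haps$h1[m$child[i], ], haps$h2[m$child[i], ]),
      pos = haps$markers$pos,
      cM = if (is.null(map)) NULL else if (sx == "male") cm_m else cm_f)
  })
}

#' Duo haplotype objects
#'
#' Ordered parent and child haplotype pairs over shared markers, with
#' physical and (optionally sex-scaled) genetic positions.
#'
#' @param parent,child sample ids.
#' @param parent_sex `"male"` or `"female"`.
#' @param P,C 2 x L matrices of parent/child alleles (0/1/NA).
#' @param pos physical positions (length L).
#' @param cM genetic positions in cM (length L, non-decreasing) or `NULL`.
#' @return an object of class `duo_haplotypes`.
#' @export
duo_haplotypes <- function(parent, child, parent_sex, P, C, pos, cM = NULL) {
  P <- as.matrix(P); C <- as.matrix(C)
  L <- length(pos)
  stopifnot(nrow(P) == 2L, nrow(C) == 2L, ncol(P) == L, ncol(C) == L)
  if (!is.null(cM)) {
    stopifnot(length(cM) == L)
    if (any(diff(cM) < 0)) stop("genetic positions must be non-decreasing")
  }
  structure(list(parent = parent, child = child, parent_sex = parent_sex,
                 P = P, C = C, pos = as.numeric(pos), cM = cM),
            class = "duo_haplotypes")
}

#' @export
print.duo_haplotypes <- function(x, ...) {
  cat(sprintf("duo: parent %s (%s) -> child %s, %d markers\n",
              x$parent, x$parent_sex, x$child, length(x$pos)))
  invisible(x)
}
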