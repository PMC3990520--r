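# End-to-end pipeline entry points backing the command-line front-end.

# header lines recording provenance for every output file
run_header <- function(config) {
  cfg <- paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), ""), sep = "=", collapse = ";")
  c(paste0("# kinphase ", as.character(utils::packageVersion("kinphase"))),
    paste0("# config_hash=", sprintf("%08x", sum(utf8ToInt(cfg) *
                                                   (seq_along(utf8ToInt(cfg)) %% 97 + 1)) %% .Machine$integer.max)),
    paste0("# seed=", config$seed %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_with_header <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(run_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_run_inputs <- function(haps, pedigree, map, format = NULL) {
  ped <- if (inherits(pedigree, "pedigree")) pedigree
  else read_pedigree(pedigree)
  hp <- if (inherits(haps, "haplotype_set")) haps
  else {
    if (is.null(format))
      format <- if (grepl("\\.vcf(\\.gz)?$", haps)) "vcf" else "haps_sample"
    read_haplotypes(haps, format = format)
  }
  gm <- if (inherits(map, "genetic_map")) map else read_genetic_map(map)
  ped$genotyped <- ped$genotyped & ped$id %in% hap_samples(hp)
  if (!nrow(pedigree_meioses(ped, genotyped_only = TRUE)))
    stop("no genotyped parent-child pairs shared between pedigree and haplotypes")
  list(ped = ped, haps = hp, map = gm)
}

#' Run the haplotype-correction pipeline
#'
#' Extracts parent-child duos, estimates per-duo HMM parameters, decodes
#' gene-flow paths and applies the sequential top-down correction cascade.
#'
#' @param haps a [haplotype_set()] or path to a HAPS or VCF file.
#' @param pedigree a [pedigree()] or path to a PLINK FAM file.
#' @param map a [genetic_map()] or path to a map file.
#' @param out_dir optional output directory; when given, corrected
#'   haplotypes (input format) and a corrections TSV are written.
#' @param male_scale sex-scaling factor for male-parent maps.
#' @param map_function `"haldane"` or `"linear"`.
#' @param seed integer seed recorded in output headers (the pipeline itself
#'   is deterministic).
#' @param format haplotype file format override.
#' @return list with `haps` (corrected), `records`, `n_duos`.
#' @export
run_correct <- function(haps, pedigree, map, out_dir = NULL,
                        male_scale = 0.605, map_function = "haldane",
                        seed = 1L, format = NULL) {
  inp <- load_run_inputs(haps, pedigree, map, format)
  res <- correct_pedigree(inp$ped, inp$haps, inp$map,
                          male_scale = male_scale,
                          map_function = map_function)
  n_duos <- nrow(pedigree_meioses(inp$ped, genotyped_only = TRUE))
  message(sprintf("processed %d duos; %d corrections (P=%d M=%d C=%d)",
                  n_duos, nrow(res$records),
                  sum(res$records$kind == "P"), sum(res$records$kind == "M"),
                  sum(res$records$kind == "C")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    config <- list(subcommand = "correct", male_scale = male_scale,
                   map_function = map_function, seed = seed)
    write_haplotypes(res$haps, file.path(out_dir, "corrected.haps"))
    rec <- res$records
    rec$pos <- inp$haps$markers$pos[rec$marker]
    rec$chrom <- inp$haps$markers$chrom[rec$marker]
    write_tsv_with_header(rec[, c("id", "chrom", "pos", "kind")],
                          file.path(out_dir, "corrections.tsv"), config)
  }
  list(haps = res$haps, records = res$records, n_duos = n_duos)
}

#' Run the recombination-detection pipeline
#'
#' Optionally applies the correction cascade first, then re-estimates
#' per-duo parameters on the corrected haplotypes and computes the posterior
#' probability of a crossover between every pair of consecutive
#' parent-heterozygous markers, thresholding into called events.
#'
#' @inheritParams run_correct
#' @param threshold posterior call threshold in (0, 1\].
#' @param correct_first run the correction cascade before detection.
#' @return list with `posteriors` (all intervals), `calls` (thresholded),
#'   `haps` (haplotypes used).
#' @export
run_recombinations <- function(haps, pedigree, map, out_dir = NULL,
                               threshold = 0.5, correct_first = TRUE,
                               male_scale = 0.605, map_function = "haldane",
                               seed = 1L, format = NULL) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  inp <- load_run_inputs(haps, pedigree, map, format)
  hp <- inp$haps
  if (correct_first)
    hp <- correct_pedigree(inp$ped, hp, inp$map, male_scale = male_scale,
                           map_function = map_function)$haps
  duos <- extract_duos(inp$ped, hp, map = inp$map, male_scale = male_scale)
  posts <- lapply(duos, function(duo) {
    est <- estimate_params(duo, map_function = map_function)
    recombination_posteriors(duo, attr(est, "fb"), est)
  })
  posts <- do.call(rbind, posts)
  calls <- call_recombinations(posts, threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    config <- list(subcommand = "recombinations", threshold = threshold,
                   correct_first = correct_first, male_scale = male_scale,
                   map_function = map_function, seed = seed)
    out <- calls
    out$chrom <- hp$markers$chrom[1]
    write_tsv_with_header(
      out[, c("parent", "child", "parent_sex", "chrom", "left_pos",
              "right_pos", "posterior")],
      file.path(out_dir, "recombinations.tsv"), config)
  }
  list(posteriors = posts, calls = calls, haps = hp)
}

#' Run the genotyping-error masking pipeline
#'
#' Computes per-locus genotyping-error posteriors for every duo and masks
#' (sets missing) the haplotype alleles of both duo members at loci whose
#' posterior reaches the mask threshold.
#'
#' @inheritParams run_correct
#' @param mask_threshold error-posterior threshold in (0, 1\].
#' @return list with `haps` (masked), `flagged` (data frame of flagged
#'   sites), `error_posteriors` (all loci, all duos).
#' @export
run_mask_errors <- function(haps, pedigree, map, out_dir = NULL,
                            mask_threshold = 0.5, male_scale = 0.605,
                            map_function = "haldane", seed = 1L,
                            format = NULL) {
  if (mask_threshold <= 0 || mask_threshold > 1)
    stop("mask_threshold must lie in (0, 1]")
  inp <- load_run_inputs(haps, pedigree, map, format)
  duos <- extract_duos(inp$ped, inp$haps, map = inp$map,
                       male_scale = male_scale)
  err <- lapply(duos, function(duo) {
    est <- estimate_params(duo, map_function = map_function)
    genotype_error_posteriors(duo, attr(est, "fb"))
  })
  err <- do.call(rbind, err)
  flagged <- err[err$posterior >= mask_threshold, , drop = FALSE]
  hp <- inp$haps
  if (nrow(flagged)) {
    for (i in seq_len(nrow(flagged))) {
      for (id in c(flagged$parent[i], flagged$child[i])) {
        hp$h1[id, flagged$marker[i]] <- NA_integer_
        hp$h2[id, flagged$marker[i]] <- NA_integer_
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    config <- list(subcommand = "errors", mask_threshold = mask_threshold,
                   male_scale = male_scale, map_function = map_function,
                   seed = seed)
    write_haplotypes(hp, file.path(out_dir, "masked.haps"))
    fl <- flagged
    fl$chrom <- inp$haps$markers$chrom[1]
    write_tsv_with_header(fl[, c("parent", "child", "chrom", "pos",
                                 "posterior")],
                          file.path(out_dir, "errors.tsv"), config)
  }
  list(haps = hp, flagged = flagged, error_posteriors = err)
}
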