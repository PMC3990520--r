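#' Pedigree objects
#'
#' A `pedigree` is a data frame with columns `family`, `id`, `father`,
#' `mother`, `sex` (1 = male, 2 = female, 0/NA = unknown) and `genotyped`
#' (logical). Parent links are `NA` for founders. Pedigrees must be
#' cycle-free and parent links must reference existing individuals.
#'
#' @param df data frame with at least columns `id`, `father`, `mother`;
#'   optional `family`, `sex`, `genotyped`.
#' @return an object of classes `pedigree` and `data.frame`.
#' @export
pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("id", "father", "mother") %in% names(df)))
    stop("pedigree needs columns id, father, mother")
  if (is.null(df$family)) df$family <- "FAM1"
  if (is.null(df$sex)) df$sex <- NA_integer_
  if (is.null(df$genotyped)) df$genotyped <- TRUE
  df$id <- as.character(df$id)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  df$father[df$father %in% c("0", "")] <- NA_character_
  df$mother[df$mother %in% c("0", "")] <- NA_character_
  if (anyDuplicated(df$id))
    stop("duplicate individual id: ", df$id[duplicated(df$id)][1])
  known <- df$id
  for (col in c("father", "mother")) {
    bad <- !is.na(df[[col]]) & !(df[[col]] %in% known)
    # parent referenced but not listed: add as an ungenotyped founder
    if (any(bad)) {
      extra <- unique(df[[col]][bad])
      fam_of <- vapply(extra, function(p) df$family[which(df[[col]] == p)[1]], "")
      add <- data.frame(
        family = fam_of, id = extra, father = NA_character_,
        mother = NA_character_, sex = if (col == "father") 1L else 2L,
        genotyped = FALSE, stringsAsFactors = FALSE)
      df <- rbind(df[names(add)], add)
    }
  }
  ped <- structure(df[c("family", "id", "father", "mother", "sex", "genotyped")],
                   class = c("pedigree", "data.frame"))
  # cycle check via generation depth
  generation_depth(ped)
  ped
}

#' Generation depth of every pedigree member
#'
#' Founders have depth 0; a child's depth is 1 + the maximum parental depth.
#' Errors on cyclic parentage.
#'
#' @param ped a [pedigree()].
#' @return named integer vector of depths.
#' @export
generation_depth <- function(ped) {
  n <- nrow(ped)
  depth <- rep(NA_integer_, n)
  names(depth) <- ped$id
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  depth[is.na(fi) & is.na(mi)] <- 0L
  for (iter in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) return(depth)
    progressed <- FALSE
    for (k in todo) {
      dp <- c(if (!is.na(fi[k])) depth[fi[k]], if (!is.na(mi[k])) depth[mi[k]])
      need <- c(if (!is.na(fi[k])) is.na(depth[fi[k]]) else FALSE,
                if (!is.na(mi[k])) is.na(depth[mi[k]]) else FALSE)
      if (!any(need)) {
        depth[k] <- max(dp) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cyclic parentage involving: ",
                          paste(ped$id[is.na(depth)], collapse = ", "))
  }
  depth
}

#' Read a PLINK FAM file as a pedigree
#'
#' Six whitespace-separated columns: family, id, father, mother, sex,
#' phenotype. Parent code "0" means unknown (founder).
#'
#' @param fam_path path to the FAM file.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(fam_path) {
  if (!file.exists(fam_path)) stop("FAM file not found: ", fam_path)
  df <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 6L) stop("FAM file must have 6 columns: ", fam_path)
  names(df)[1:6] <- c("family", "id", "father", "mother", "sex", "pheno")
  self_parent <- df$id == df$father | df$id == df$mother
  if (any(self_parent))
    stop("individual listed as its own parent: ", df$id[self_parent][1])
  pedigree(data.frame(family = df$family, id = df$id, father = df$father,
                      mother = df$mother, sex = suppressWarnings(as.integer(df$sex)),
                      stringsAsFactors = FALSE))
}

#' Write a pedigree as a PLINK FAM file
#' @param ped a [pedigree()].
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(ped$family, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    ifelse(is.na(ped$sex), 0L, ped$sex), 0L)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Parent-child meioses of a pedigree
#'
#' @param ped a [pedigree()].
#' @param genotyped_only keep only meioses where both members are genotyped.
#' @return data frame with columns `parent`, `child`, `parent_sex`
#'   ("male"/"female"), `family`.
#' @export
pedigree_meioses <- function(ped, genotyped_only = TRUE) {
  rows <- list()
  for (col in c("father", "mother")) {
    has <- !is.na(ped[[col]])
    if (!any(has)) next
    rows[[col]] <- data.frame(
      parent = ped[[col]][has], child = ped$id[has],
      parent_sex = if (col == "father") "male" else "female",
      family = ped$family[has], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(parent = character(), child = character(),
                      parent_sex = character(), family = character()))
  rownames(out) <- NULL
  if (genotyped_only) {
    g <- stats::setNames(ped$genotyped, ped$id)
    out <- out[g[out$parent] & g[out$child], , drop = FALSE]
  }
  out[order(out$family, out$child, out$parent_sex), , drop = FALSE]
}

#' Classify meioses as informative or not
#'
#' A parent-child meiosis is informative when crossovers in it are resolvable
#' by classical pedigree methods: either the child belongs to a sibship of at
#' least three genotyped children of that parent, or the duo lies on a
#' three-generation genotyped path (the parent has a genotyped parent, or the
#' child has a genotyped child).
#'
#' @param ped a [pedigree()].
#' @return the meiosis data frame from [pedigree_meioses()] with a logical
#'   `informative` column.
#' @export
classify_informative <- function(ped) {
  m <- pedigree_meioses(ped, genotyped_only = TRUE)
  if (!nrow(m)) { m$informative <- logical(0); return(m) }
  g <- stats::setNames(ped$genotyped, ped$id)
  sib_n <- stats::ave(seq_len(nrow(m)), m$parent, FUN = length)
  has_gp <- vapply(m$parent, function(p) {
    r <- ped[ped$id == p, ]
    any(c(!is.na(r$father) && g[r$father], !is.na(r$mother) && g[r$mother]))
  }, logical(1))
  has_gc <- vapply(m$child, function(ch) {
    kids <- ped$id[(!is.na(ped$father) & ped$father == ch) |
                     (!is.na(ped$mother) & ped$mother == ch)]
    any(g[kids])
  }, logical(1))
  m$informative <- sib_n >= 3L | has_gp | has_gc
  rownames(m) <- NULL
  m
}

#' Partition a pedigree into duos and trios
#'
#' Enumerates disjoint assignments of pedigree members into mother-father-child
#' trios and parent-child duos, and returns a partition minimizing the number
#' of uncovered individuals. Ties between optimal partitions are broken
#' uniformly at random under `seed`. Pedigrees with more than `max_edges`
#' parent-child edges are refused unless `method = "greedy"`, which repeatedly
#' extracts a trio when possible, else a duo.
#'
#' @param ped a [pedigree()] (one family; multi-family input is partitioned
#'   family by family).
#' @param seed integer seed for tie-breaking.
#' @param max_edges exact-enumeration bound on parent-child edges.
#' @param method `"exact"` or `"greedy"`.
#' @return a list with elements `trios` (data frame father, mother, child),
#'   `duos` (data frame parent, child) and `uncovered` (character vector).
#' @export
partition_duos_trios <- function(ped, seed = 1L, max_edges = 12L,
                                 method = c("exact", "greedy")) {
  method <- match.arg(method)
  fams <- unique(ped$family)
  if (length(fams) > 1L) {
    parts <- lapply(seq_along(fams), function(i)
      partition_duos_trios(ped[ped$family == fams[i], ], seed = seed + i,
                           max_edges = max_edges, method = method))
    return(list(
      trios = do.call(rbind, lapply(parts, `[[`, "trios")),
      duos = do.call(rbind, lapply(parts, `[[`, "duos")),
      uncovered = unlist(lapply(parts, `[[`, "uncovered"), use.names = FALSE)))
  }
  ids <- ped$id[ped$genotyped]
  m <- pedigree_meioses(ped, genotyped_only = TRUE)
  empty_trios <- data.frame(father = character(), mother = character(),
                            child = character(), stringsAsFactors = FALSE)
  empty_duos <- data.frame(parent = character(), child = character(),
                           stringsAsFactors = FALSE)
  # candidate units
  duos <- if (nrow(m)) lapply(seq_len(nrow(m)), function(i)
    list(kind = "duo", members = c(m$parent[i], m$child[i]))) else list()
  trio_child <- ped$id[ped$genotyped & !is.na(ped$father) & !is.na(ped$mother)]
  trios <- list()
  g <- stats::setNames(ped$genotyped, ped$id)
  for (ch in trio_child) {
    f <- ped$father[ped$id == ch]; mo <- ped$mother[ped$id == ch]
    if (isTRUE(g[f]) && isTRUE(g[mo]))
      trios[[length(trios) + 1L]] <- list(kind = "trio", members = c(f, mo, ch))
  }
  units <- c(trios, duos)
  if (!length(units))
    return(list(trios = empty_trios, duos = empty_duos, uncovered = ids))
  if (method == "exact" && nrow(m) > max_edges)
    stop("pedigree has ", nrow(m), " parent-child edges (> ", max_edges,
         "); use method = \"greedy\"")

  if (method == "greedy") {
    used <- character(0); chosen <- list()
    repeat {
      ok <- Filter(function(u) !any(u$members %in% used), units)
      if (!length(ok)) break
      kinds <- vapply(ok, `[[`, "", "kind")
      pick <- if (any(kinds == "trio")) ok[[which(kinds == "trio")[1]]] else ok[[1]]
      chosen[[length(chosen) + 1L]] <- pick
      used <- c(used, pick$members)
    }
  } else {
    # exhaustive branch-and-bound over unit subsets
    best_cov <- -1L
    best_sets <- list()
    nU <- length(units)
    recurse <- function(i, used, chosen, covered) {
      if (i > nU) {
        if (covered > best_cov) {
          best_cov <<- covered; best_sets <<- list(chosen)
        } else if (covered == best_cov) {
          best_sets[[length(best_sets) + 1L]] <<- chosen
        }
        return(invisible())
      }
      u <- units[[i]]
      if (!any(u$members %in% used))
        recurse(i + 1L, c(used, u$members), c(chosen, i),
                covered + length(u$members))
      recurse(i + 1L, used, chosen, covered)
    }
    recurse(1L, character(0), integer(0), 0L)
    keys <- vapply(best_sets, function(s) paste(sort(s), collapse = ","), "")
    best_sets <- best_sets[!duplicated(keys)]
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    pick <- best_sets[[sample.int(length(best_sets), 1L)]]
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    chosen <- units[pick]
  }

  tri <- Filter(function(u) u$kind == "trio", chosen)
  duo <- Filter(function(u) u$kind == "duo", chosen)
  trios_df <- if (length(tri)) data.frame(
    father = vapply(tri, function(u) u$members[1], ""),
    mother = vapply(tri, function(u) u$members[2], ""),
    child = vapply(tri, function(u) u$members[3], ""),
    stringsAsFactors = FALSE) else empty_trios
  duos_df <- if (length(duo)) data.frame(
    parent = vapply(duo, function(u) u$members[1], ""),
    child = vapply(duo, function(u) u$members[2], ""),
    stringsAsFactors = FALSE) else empty_duos
  covered <- c(unlist(lapply(chosen, `[[`, "members"), use.names = FALSE))
  list(trios = trios_df, duos = duos_df, uncovered = setdiff(ids, covered))
}
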