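#' Genetic map objects
#'
#' A `genetic_map` holds the physical-to-genetic coordinate mapping for one
#' chromosome: physical positions (1-based bp, strictly increasing), the local
#' recombination rate in cM/Mb, and the cumulative genetic position in
#' centiMorgans (non-decreasing).
#'
#' @param positions integer/numeric vector of physical positions (bp),
#'   strictly increasing.
#' @param cum_cM numeric vector of cumulative genetic positions (cM),
#'   non-decreasing, same length as `positions`.
#' @param rate numeric vector of local rates (cM/Mb), non-negative. If `NULL`,
#'   derived from finite differences of `cum_cM` (last value repeated).
#' @param chrom chromosome label.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(positions, cum_cM, rate = NULL, chrom = "1") {
  positions <- as.numeric(positions)
  cum_cM <- as.numeric(cum_cM)
  if (length(positions) == 0L) stop("genetic map is empty")
  if (length(positions) != length(cum_cM))
    stop("positions and cum_cM must have equal length")
  if (anyNA(positions) || anyNA(cum_cM))
    stop("genetic map contains missing values")
  if (any(diff(positions) <= 0))
    stop("physical positions must be strictly increasing (first violation at row ",
         which(diff(positions) <= 0)[1] + 1L, ")")
  if (any(diff(cum_cM) < 0))
    stop("cumulative cM must be non-decreasing")
  if (is.null(rate)) {
    if (length(positions) > 1L) {
      r <- diff(cum_cM) / (diff(positions) / 1e6)
      rate <- c(r, r[length(r)])
    } else rate <- 0
  }
  rate <- as.numeric(rate)
  if (length(rate) != length(positions))
    stop("rate must have the same length as positions")
  if (any(rate < 0)) stop("rates must be non-negative")
  structure(
    list(positions = positions, cum_cM = cum_cM, rate = rate,
         chrom = as.character(chrom)[1]),
    class = "genetic_map"
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: chrom %s, %d positions, %.0f-%.0f bp, %.3f cM total\n",
              x$chrom, length(x$positions), min(x$positions), max(x$positions),
              map_length_cM(x)))
  invisible(x)
}

#' Total genetic length of a map in centiMorgans
#' @param map a [genetic_map()].
#' @export
map_length_cM <- function(map) {
  max(map$cum_cM) - min(map$cum_cM)
}

#' Read a HapMap-style genetic map
#'
#' Expects whitespace-separated columns (position, rate cM/Mb, cumulative cM)
#' for a single chromosome; a header line is detected and skipped.
#'
#' @param path path to the map file.
#' @param chrom chromosome label to attach to the map.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path, chrom = "1") {
  if (!file.exists(path)) stop("map file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    is.na(suppressWarnings(as.numeric(strsplit(trimws(first), "\\s+")[[1]][1])))
  df <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty genetic map file: ", path)
  if (ncol(df) < 3L) stop("genetic map needs 3 columns (position, rate, cM): ", path)
  pos <- as.numeric(df[[1]]); rate <- as.numeric(df[[2]]); cm <- as.numeric(df[[3]])
  if (anyNA(pos)) stop("non-numeric position in map file ", path)
  if (anyDuplicated(pos))
    stop("duplicate position at line ", which(duplicated(pos))[1] + has_header,
         " of ", path)
  bad <- which(diff(pos) <= 0)
  if (length(bad))
    stop("non-increasing position at line ", bad[1] + 1L + has_header, " of ", path)
  genetic_map(pos, cm, rate, chrom = chrom)
}

#' Interpolate genetic positions (cM) at physical positions
#'
#' Piecewise-linear inside the map range; beyond the range, extrapolates at
#' the terminal local rate and is clamped so the output is non-decreasing.
#'
#' @param map a [genetic_map()].
#' @param query_positions sorted physical positions (bp).
#' @return numeric vector of genetic positions (cM).
#' @export
interpolate_cM <- function(map, query_positions) {
  q <- as.numeric(query_positions)
  if (length(q) == 0L) return(numeric(0))
  if (is.unsorted(q)) stop("query positions must be sorted")
  n <- length(map$positions)
  if (n == 1L) {
    out <- map$cum_cM + (q - map$positions) / 1e6 * map$rate[1]
  } else {
    out <- stats::approx(map$positions, map$cum_cM, xout = q,
                         rule = 2, ties = "ordered")$y
    lo <- q < map$positions[1]
    hi <- q > map$positions[n]
    if (any(lo))
      out[lo] <- map$cum_cM[1] - (map$positions[1] - q[lo]) / 1e6 * map$rate[1]
    if (any(hi))
      out[hi] <- map$cum_cM[n] + (q[hi] - map$positions[n]) / 1e6 * map$rate[n]
  }
  cummax(out)
}

#' Map genetic positions (cM) back to physical positions
#'
#' Inverse of [interpolate_cM()] by linear interpolation on the (cM, bp)
#' curve. Flat (zero-rate) segments resolve to their left edge.
#'
#' @param map a [genetic_map()].
#' @param cM genetic positions in centiMorgans.
#' @return numeric physical positions (bp).
#' @export
interpolate_bp <- function(map, cM) {
  if (length(cM) == 0L) return(numeric(0))
  stats::approx(map$cum_cM, map$positions, xout = pmin(pmax(cM, min(map$cum_cM)),
                                                       max(map$cum_cM)),
                rule = 2, ties = "min")$y
}

#' Scale a genetic map to a sex-specific length
#'
#' Multiplies all cumulative genetic positions (and rates) by a constant so
#' that the total map length equals `factor` times the original length, or a
#' given target length in cM. The default male factor (0.605) is the
#' male/female rate ratio for an X-like map estimated from family-based maps.
#'
#' @param map a [genetic_map()].
#' @param sex `"male"` or `"female"`.
#' @param factor scaling factor (> 0); defaults to 0.605 for males, 1 for
#'   females.
#' @param target_cM alternatively, target total length in cM (> 0).
#' @return a scaled [genetic_map()].
#' @export
sex_scale <- function(map, sex = c("male", "female"), factor = NULL,
                      target_cM = NULL) {
  sex <- match.arg(sex)
  if (!is.null(factor) && !is.null(target_cM))
    stop("give either factor or target_cM, not both")
  if (is.null(factor) && is.null(target_cM))
    factor <- if (sex == "male") 0.605 else 1.0
  if (!is.null(target_cM)) {
    if (target_cM <= 0) stop("target length must be positive")
    len <- map_length_cM(map)
    if (len == 0) stop("cannot rescale a zero-length map to a target length")
    factor <- target_cM / len
  }
  if (factor <= 0) stop("scaling factor must be positive")
  genetic_map(map$positions,
              min(map$cum_cM) + (map$cum_cM - min(map$cum_cM)) * factor,
              map$rate * factor, chrom = map$chrom)
}

#' Recombination probability for a genetic distance
#'
#' Converts an inter-marker genetic distance (Morgans) to the probability of
#' an odd number of crossovers in the interval. The default is the Haldane
#' map function \eqn{\rho = (1 - e^{-2d})/2} (no interference); a linear
#' approximation \eqn{\min(d, 0.5)} is available. For SNP-array spacings
#' (d << 0.01 M) the two agree to first order.
#'
#' @param d genetic distance(s) in Morgans, non-negative.
#' @param map_function `"haldane"` (default) or `"linear"`.
#' @return recombination probabilities in \[0, 0.5\].
#' @export
interval_recomb_prob <- function(d, map_function = c("haldane", "linear")) {
  map_function <- match.arg(map_function)
  if (any(d < 0, na.rm = TRUE)) stop("genetic distances must be non-negative")
  switch(map_function,
         haldane = (1 - exp(-2 * d)) / 2,
         linear = pmin(d, 0.5))
}

#' Per-interval recombination probabilities for a set of markers
#'
#' @param map a [genetic_map()] (already sex-scaled if required).
#' @param positions sorted marker physical positions (bp).
#' @param map_function passed to [interval_recomb_prob()].
#' @return numeric vector of length `length(positions) - 1`.
#' @export
marker_recomb_probs <- function(map, positions,
                                map_function = c("haldane", "linear")) {
  cm <- interpolate_cM(map, positions)
  interval_recomb_prob(diff(cm) / 100, match.arg(map_function))
}
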