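#' Define a genomic region binned at fixed resolution
#'
#' A region is the genomic footprint of a contact map: a chromosome interval
#' \[start, end\] in Mb, binned at `resolution_kb`. Bins are fenceposts: every
#' bin whose start coordinate lies in \[start, end\] belongs to the region, so
#' the number of loci is `floor((end - start)/resolution) + 1`. The 20.5-71.4
#' Mb stretch of murine chromosome 1 at 100 kb, for example, holds 510 loci.
#'
#' @param chromosome Chromosome label, e.g. `"chr1"`.
#' @param start_mb,end_mb Region bounds in megabases; `start_mb < end_mb`.
#' @param resolution_kb Bin size in kilobases.
#' @return An object of class `genomic_region` with a `locus_count` field.
#' @examples
#' genomic_region("chr1", 20.5, 71.4, 100)  # 510 loci
#' @export
genomic_region <- function(chromosome, start_mb, end_mb, resolution_kb) {
  stopifnot(is.numeric(start_mb), is.numeric(end_mb),
            is.numeric(resolution_kb), resolution_kb > 0)
  if (start_mb >= end_mb) stop("start_mb must be < end_mb")
  res_mb <- resolution_kb / 1000
  n <- floor((end_mb - start_mb) / res_mb + 1e-9) + 1
  structure(list(chromosome = as.character(chromosome),
                 start_mb = start_mb, end_mb = end_mb,
                 resolution_kb = resolution_kb,
                 locus_count = as.integer(n)),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s:%.3f-%.3f Mb @ %g kb (%d loci)\n",
              x$chromosome, x$start_mb, x$end_mb, x$resolution_kb,
              x$locus_count))
  invisible(x)
}

#' Construct a contact-probability map
#'
#' Wraps a square symmetric matrix of contact probabilities together with its
#' genomic region. Entries must be non-negative; a map is `normalized` once
#' both first off-diagonals are pinned to 1 (see [normalize_adjacent()]).
#'
#' @param P Square symmetric numeric matrix, entries `>= 0`.
#' @param region A [genomic_region()] whose `locus_count` matches `nrow(P)`.
#' @param normalized Logical flag; set by [normalize_adjacent()].
#' @return An object of class `contact_map` with fields `P` and `region`.
#' @export
contact_map <- function(P, region, normalized = FALSE) {
  stopifnot(is.matrix(P), inherits(region, "genomic_region"))
  if (nrow(P) != ncol(P)) stop("contact matrix must be square")
  if (nrow(P) != region$locus_count)
    stop(sprintf("matrix side %d does not match region locus count %d",
                 nrow(P), region$locus_count))
  if (any(!is.finite(P))) stop("contact matrix has non-finite entries")
  if (any(P < 0)) stop("contact probabilities must be non-negative")
  if (max(abs(P - t(P))) > 1e-12) stop("contact matrix must be symmetric")
  P <- (P + t(P)) / 2
  structure(list(P = P, region = region, normalized = isTRUE(normalized)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d x %d loci, %s:%.3f-%.3f Mb @ %g kb, %s\n",
              nrow(x$P), ncol(x$P), x$region$chromosome, x$region$start_mb,
              x$region$end_mb, x$region$resolution_kb,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Read a contact map from a text file
#'
#' Two plain-text dialects are accepted: a dense whitespace-delimited square
#' matrix, or coordinate triples `i j value` with 0-based bin indices within
#' the region. Triples are mirrored to enforce symmetry. The matrix side is
#' validated against the region's locus count.
#'
#' @param path Path to the file.
#' @param region The [genomic_region()] the file covers.
#' @param format `"auto"` (default), `"dense"` or `"triples"`. Auto detection
#'   treats a file whose row and column counts both equal the locus count as
#'   dense, and a 3-column file otherwise as triples; pass the format
#'   explicitly for ambiguous tiny regions.
#' @return A [contact_map()].
#' @export
read_contact_map <- function(path, region, format = c("auto", "dense",
                                                      "triples")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- as.matrix(read.table(path, header = FALSE))
  n <- region$locus_count
  if (format == "auto") {
    format <- if (nrow(tab) == n && ncol(tab) == n) "dense"
              else if (ncol(tab) == 3) "triples"
              else stop(sprintf(
                "cannot interpret %d x %d file for a %d-locus region",
                nrow(tab), ncol(tab), n))
  }
  if (format == "dense") {
    if (nrow(tab) != ncol(tab))
      stop(sprintf("dense matrix is not square: %d rows x %d cols",
                   nrow(tab), ncol(tab)))
    if (nrow(tab) != n)
      stop(sprintf("dense matrix side %d does not match region locus count %d",
                   nrow(tab), n))
    if (any(tab < 0)) {
      bad <- which(tab < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("negative value at row %d, column %d", bad[1], bad[2]))
    }
    P <- unname(tab)
    P <- (P + t(P)) / 2
  } else {
    if (ncol(tab) != 3) stop("triples file must have exactly 3 columns")
    i <- tab[, 1]; j <- tab[, 2]; v <- tab[, 3]
    bad <- which(i < 0 | i >= n | j < 0 | j >= n)
    if (length(bad))
      stop(sprintf("triple record %d: index (%g, %g) out of range [0, %d]",
                   bad[1], i[bad[1]], j[bad[1]], n - 1))
    bad <- which(v < 0)
    if (length(bad))
      stop(sprintf("triple record %d: negative value %g", bad[1], v[bad[1]]))
    P <- matrix(0, n, n)
    P[cbind(i + 1, j + 1)] <- v
    P[cbind(j + 1, i + 1)] <- v
  }
  contact_map(P, region)
}

#' Write a contact map to a text file
#'
#' The dense dialect round-trips bit-exactly through [read_contact_map()];
#' the triples dialect stores the non-zero upper triangle (plus diagonal) as
#' 0-based `i j value` records.
#'
#' @param map A [contact_map()].
#' @param path Output path.
#' @param format `"dense"` (default) or `"triples"`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, format = c("dense", "triples")) {
  format <- match.arg(format)
  stopifnot(inherits(map, "contact_map"))
  if (nrow(map$P) < 1) stop("empty contact map")
  if (format == "dense") {
    lines <- apply(map$P, 1, function(r) paste(sprintf("%.17g", r),
                                               collapse = " "))
    writeLines(lines, path)
  } else {
    idx <- which(upper.tri(map$P, diag = TRUE) & map$P != 0, arr.ind = TRUE)
    lines <- sprintf("%d %d %.17g", idx[, 1] - 1L, idx[, 2] - 1L,
                     map$P[idx])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Normalize a contact map to the unit-adjacent convention
#'
#' Hi-C contact probabilities for a polymer model are anchored by assuming
#' neighbouring beads are always in contact: after normalization every first
#' off-diagonal entry equals 1 exactly. The whole matrix is divided by the
#' mean first-off-diagonal value, entries exceeding 1 are clipped to 1, the
#' adjacent band (and diagonal) is pinned to exactly 1, and symmetry is
#' preserved. The operation is idempotent.
#'
#' @param map A [contact_map()] with positive mean first off-diagonal.
#' @return A normalized [contact_map()].
#' @export
normalize_adjacent <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  P <- map$P
  n <- nrow(P)
  if (n < 2) stop("need at least 2 loci to normalize")
  adj <- P[cbind(seq_len(n - 1), seq_len(n - 1) + 1)]
  anchor <- mean(adj)
  if (anchor <= 0)
    stop("mean first-off-diagonal contact is zero; normalization anchor undefined")
  P <- P / anchor
  P[P > 1] <- 1
  P[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- 1
  P[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- 1
  diag(P) <- 1
  contact_map(P, map$region, normalized = TRUE)
}

#' Mean contact probability per genomic separation
#'
#' Entry `s` of the result is the mean of `P[i, i + s]` over all valid `i`:
#' the distance-decay curve used as the "expected" reference for enhanced
#' contacts. The diagonal (`s = 0`) is excluded.
#'
#' @param map A [contact_map()].
#' @return Numeric vector of length `locus_count - 1`, named by separation.
#' @export
expected_by_distance <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  P <- map$P
  n <- nrow(P)
  out <- vapply(seq_len(n - 1), function(s) {
    i <- seq_len(n - s)
    mean(P[cbind(i, i + s)])
  }, numeric(1))
  names(out) <- seq_len(n - 1)
  out
}

#' Enhanced (observed over expected) contact map at coarse resolution
#'
#' The fine map is aggregated into coarse bins (default 1 Mb blocks of 100 kb
#' loci): `P_obs[I, J]` sums the fine contact probabilities in the `I x J`
#' block (fine diagonal excluded), `P_exp` is the distance-decay expectation
#' of the coarse matrix, and the result is `log2(P_obs / P_exp)`, masked
#' (`NA`) wherever either term is zero. Trailing loci that do not fill a
#' coarse bin are dropped. The map is invariant under global scaling of the
#' input.
#'
#' @param map A [contact_map()].
#' @param coarse_resolution_kb Coarse bin size in kb; must be an integer
#'   multiple of the map resolution.
#' @return An object of class `enhanced_map` with fields `log2_ratio`
#'   (matrix with `NA` mask), `P_obs`, `P_exp`, `bin_size` (fine loci per
#'   coarse bin) and `region`.
#' @export
enhanced_contacts <- function(map, coarse_resolution_kb = 1000) {
  stopifnot(inherits(map, "contact_map"))
  w <- coarse_resolution_kb / map$region$resolution_kb
  if (abs(w - round(w)) > 1e-9)
    stop("coarse resolution must be an integer multiple of the map resolution")
  w <- as.integer(round(w))
  n <- nrow(map$P)
  nc <- n %/% w
  if (nc < 2) stop("fewer than 2 coarse bins; choose a finer coarse resolution")
  P <- map$P
  diag(P) <- 0  # self-contacts carry no structural information
  grp <- rep(seq_len(nc), each = w)
  used <- seq_len(nc * w)
  A <- rowsum(P[used, used], grp)          # collapse rows
  P_obs <- t(rowsum(t(A), grp))            # collapse cols
  # expected at coarse scale: mean over each diagonal of P_obs (s >= 0)
  P_exp <- matrix(0, nc, nc)
  for (s in 0:(nc - 1)) {
    i <- seq_len(nc - s)
    m <- mean(P_obs[cbind(i, i + s)])
    P_exp[cbind(i, i + s)] <- m
    P_exp[cbind(i + s, i)] <- m
  }
  ratio <- matrix(NA_real_, nc, nc)
  ok <- P_obs > 0 & P_exp > 0
  ratio[ok] <- log2(P_obs[ok] / P_exp[ok])
  structure(list(log2_ratio = ratio, P_obs = P_obs, P_exp = P_exp,
                 bin_size = w, region = map$region),
            class = "enhanced_map")
}

#' Insulation score profile
#'
#' For each locus `i`, the raw score is the mean contact probability in the
#' `w x w` square upstream-by-downstream of `i` (rows `i-w..i-1`, columns
#' `i+1..i+w`, `w = window/resolution` loci); the profile is the log2 ratio
#' of the raw score to its chromosome-wide mean. Loci within `w` of either
#' end are masked (`NA`). Dips in the profile mark TAD boundaries.
#'
#' @param map A [contact_map()].
#' @param window_kb Sliding-window size in kb (default 500, i.e. a
#'   500 x 500 kb square at 100 kb resolution).
#' @return An object of class `insulation_profile` with fields `scores`
#'   (per-locus log2 vector with `NA` mask), `raw`, `window_loci`.
#' @export
insulation_profile <- function(map, window_kb = 500) {
  stopifnot(inherits(map, "contact_map"))
  w <- window_kb / map$region$resolution_kb
  if (abs(w - round(w)) > 1e-9 || w < 1)
    stop("window must be a positive integer multiple of the resolution")
  w <- as.integer(round(w))
  n <- nrow(map$P)
  if (n <= 2 * w) stop("window larger than the map allows")
  raw <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    raw[i] <- mean(map$P[(i - w):(i - 1), (i + 1):(i + w)])
  }
  m <- mean(raw, na.rm = TRUE)
  scores <- log2(raw / m)  # raw == 0 yields -Inf: an absolute insulation gap
  structure(list(scores = scores, raw = raw, window_loci = w,
                 window_kb = window_kb, region = map$region),
            class = "insulation_profile")
}

#' Call TAD boundaries from an insulation profile
#'
#' Boundaries are local minima of the insulation profile whose boundary
#' strength -- the mean of the two flanking local maxima minus the minimum
#' value -- reaches `strength_threshold` (log2 units). Profile ends stand in
#' for missing flanking maxima.
#'
#' @param profile An [insulation_profile()].
#' @param strength_threshold Minimum boundary strength (default 0.1).
#' @return Integer vector of boundary locus indices (1-based), ordered.
#' @export
tad_boundaries <- function(profile, strength_threshold = 0.1) {
  stopifnot(inherits(profile, "insulation_profile"))
  s <- profile$scores
  idx <- which(!is.na(s))
  if (length(idx) < 3) return(integer(0))
  v <- s[idx]
  k <- length(v)
  is_min <- is_max <- rep(FALSE, k)
  for (p in 2:(k - 1)) {
    if (v[p] < v[p - 1] && v[p] <= v[p + 1]) is_min[p] <- TRUE
    if (v[p] > v[p - 1] && v[p] >= v[p + 1]) is_max[p] <- TRUE
  }
  is_max[1] <- v[1] > v[2]
  is_max[k] <- v[k] > v[k - 1]
  mins <- which(is_min)
  maxs <- which(is_max)
  keep <- vapply(mins, function(p) {
    left <- maxs[maxs < p]
    right <- maxs[maxs > p]
    lv <- if (length(left)) v[max(left)] else v[1]
    rv <- if (length(right)) v[min(right)] else v[k]
    mean(c(lv, rv)) - v[p] >= strength_threshold
  }, logical(1))
  sort(idx[mins[keep]])
}

#' A/B compartment profile from an enhanced contact map
#'
#' The compartment profile is the first principal axis of the enhanced
#' (observed/expected) matrix, with coarse bins as observations. Masked
#' entries are imputed to 0 for the decomposition. The sign is fixed by a
#' deterministic convention: the bin class carrying the higher mean
#' short-range observed contact density (adjacent coarse bins) is oriented
#' positive.
#'
#' @param emap An `enhanced_map` from [enhanced_contacts()].
#' @return An object of class `compartment_profile` with fields `pc1` (unit
#'   norm, length = number of coarse bins) and `explained_variance`.
#' @export
compartment_profile <- function(emap) {
  stopifnot(inherits(emap, "enhanced_map"))
  M <- emap$log2_ratio
  M[is.na(M)] <- 0
  if (nrow(M) < 3) stop("need at least 3 defined coarse bins")
  if (max(abs(M)) == 0) stop("degenerate (all-zero) enhanced map")
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  # sign convention: class with higher adjacent-bin observed density positive
  nc <- length(v)
  adj <- emap$P_obs[cbind(seq_len(nc - 1), seq_len(nc - 1) + 1)]
  dens <- c(adj, adj[nc - 1]) / 2 + c(adj[1], adj) / 2
  pos <- v > 0
  if (any(pos) && any(!pos) &&
      mean(dens[pos]) < mean(dens[!pos])) v <- -v
  v <- v / sqrt(sum(v^2))
  structure(list(pc1 = unname(v), explained_variance = unname(ev[1])),
            class = "compartment_profile")
}
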