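#' Distance Spearman correlation coefficient (dSCC)
#'
#' The primary reconstruction-accuracy metric: the Spearman rank correlation
#' between the structure's pairwise Euclidean distances and the wish
#' distances, over the masked (positive-contact) pairs. Being rank-based it
#' is invariant to rigid motion and uniform scaling of the structure - the
#' appropriate property, since structures are only defined up to similarity.
#' Ties receive average ranks. Values near 1 indicate accurate
#' reconstruction.
#'
#' @param s a [structure3d] (or N x 3 matrix).
#' @param wd a `wish_distances` object on the same loci.
#' @return correlation in `[-1, 1]`.
#' @export
dscc <- function(s, wd) {
  dm <- structure_distances(s)
  if (nrow(dm) != nrow(wd$d)) stop("structure and wish distances disagree on N")
  sel <- wd$mask & upper.tri(wd$mask)
  if (sum(sel) < 3) stop("need at least 3 masked pairs for dSCC")
  x <- dm[sel]; y <- wd$d[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("dSCC undefined: constant distance vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Distance RMSD against wish distances
#'
#' Root mean squared deviation between the structure's pairwise distances and
#' the wish distances over masked pairs. dRMSD is scale-sensitive, so
#' `rescale = TRUE` first applies the single scalar
#' `s* = sum(d * dist) / sum(dist^2)` minimizing the squared deviation
#' (the one-parameter Procrustes rescaling); the rescaled value is never
#' larger than the raw one.
#'
#' @inheritParams dscc
#' @param rescale apply the optimal uniform scale first.
#' @return non-negative scalar in wish-distance units.
#' @export
drmsd <- function(s, wd, rescale = FALSE) {
  dm <- structure_distances(s)
  if (nrow(dm) != nrow(wd$d)) stop("structure and wish distances disagree on N")
  sel <- wd$mask & upper.tri(wd$mask)
  if (sum(sel) < 3) stop("need at least 3 masked pairs for dRMSD")
  x <- dm[sel]; y <- wd$d[sel]
  if (rescale) {
    denom <- sum(x^2)
    if (denom > 0) x <- x * sum(y * x) / denom
  }
  sqrt(mean((x - y)^2))
}

#' Linear interpolation of a structure to a finer resolution
#'
#' Baseline for cross-resolution comparisons: between each pair of
#' consecutive coordinates, `k - 1` equally spaced points are inserted on the
#' connecting line, giving `k * (N - 1) + 1` points with the same spatial
#' configuration as the input. When a `n_target` is supplied (the locus count
#' of the finer map, typically `k * N`), the final coordinate is repeated to
#' pad the difference, with a message.
#'
#' @param s a [structure3d].
#' @param k subdivision factor (`k = 2` doubles, `k = 4` quadruples).
#' @param n_target optional required output length.
#' @return a [structure3d].
#' @export
interpolate_structure <- function(s, k, n_target = NULL) {
  stopifnot(inherits(s, "structure3d"))
  if (k < 1) stop("k must be >= 1")
  k <- as.integer(k)
  xyz <- s$coords
  n <- nrow(xyz)
  if (n < 2) stop("need at least 2 points to interpolate")
  if (k == 1L) {
    out <- xyz
  } else {
    t_new <- seq(1, n, by = 1 / k)
    out <- apply(xyz, 2, function(col) stats::approx(seq_len(n), col, xout = t_new)$y)
  }
  if (!is.null(n_target)) {
    if (nrow(out) > n_target) {
      message("interpolate_structure: truncating ", nrow(out), " -> ", n_target)
      out <- out[seq_len(n_target), , drop = FALSE]
    } else if (nrow(out) < n_target) {
      message("interpolate_structure: padding ", nrow(out), " -> ", n_target,
              " by repeating the final coordinate")
      out <- rbind(out, out[rep(nrow(out), n_target - nrow(out)), , drop = FALSE])
    }
  }
  structure3d(out, chromosome_label = s$chromosome_label)
}

#' Call A/B compartments from a contact map
#'
#' Megabase-scale chromatin compartments are read off the sign pattern of the
#' principal eigenvector of the Pearson correlation matrix of the normalized
#' (by default KR-balanced) contact map: loci with positive entries form one
#' compartment, negative entries the other. The eigenvector sign is itself
#' arbitrary; lacking external annotation (gene density, GC content) the
#' convention here labels the larger compartment "A". Zero eigenvector
#' entries are assigned "B" with a message; loci whose correlation is
#' undefined (constant rows) are dropped and reported.
#'
#' @param m a [contact_map].
#' @param normalization `"kr"` (default) or `"raw"`.
#' @return object of class `compartment_call`: `labels` (character "A"/"B"
#'   per retained locus), `eigenvector`, `kept_indices`.
#' @export
call_compartments <- function(m, normalization = c("kr", "raw")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(m, "contact_map"))
  if (m$n_loci < 3) stop("need at least 3 loci to call compartments")
  if (normalization == "kr") {
    nm <- kr_balance(m)
    w <- nm$weights
    keep <- nm$kept_indices
  } else {
    keep <- which(rowSums(m$counts) > 0)
    w <- m$counts[keep, keep, drop = FALSE]
  }
  sds <- apply(w, 2, stats::sd)
  if (any(sds == 0)) {
    drop <- which(sds == 0)
    message("call_compartments: dropping ", length(drop),
            " loci with constant profiles")
    w <- w[-drop, -drop, drop = FALSE]
    keep <- keep[-drop]
  }
  if (nrow(w) < 3) stop("too few variable loci to call compartments")
  p <- stats::cor(w)
  ev <- eigen(p, symmetric = TRUE)$vectors[, 1]
  if (sum(ev > 0) < sum(ev < 0)) ev <- -ev   # larger compartment labeled A
  labels <- ifelse(ev > 0, "A", "B")
  if (any(ev == 0)) {
    message("call_compartments: ", sum(ev == 0),
            " zero eigenvector entries assigned to B")
  }
  structure(list(labels = labels, eigenvector = ev, kept_indices = keep,
                 chromosome_label = m$chromosome_label,
                 bin_size = m$bin_size,
                 bin_start_bp = m$bin_start_bp[keep]),
            class = "compartment_call")
}

#' @export
print.compartment_call <- function(x, ...) {
  cat(sprintf("<compartment_call> %d loci: %d A / %d B\n",
              length(x$labels), sum(x$labels == "A"), sum(x$labels == "B")))
  invisible(x)
}

#' Write compartment calls as BED-like text
#'
#' Tab-separated `chrom start end label`, half-open bins.
#'
#' @param cc a `compartment_call`.
#' @param path output path.
#' @export
write_compartments <- function(cc, path) {
  stopifnot(inherits(cc, "compartment_call"))
  start <- cc$bin_start_bp
  if (is.null(start)) start <- (cc$kept_indices - 1) * cc$bin_size
  df <- data.frame(chrom = cc$chromosome_label,
                   start = format(start, scientific = FALSE, trim = TRUE),
                   end = format(start + cc$bin_size, scientific = FALSE, trim = TRUE),
                   label = cc$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Compare structure distances between two sets of locus pairs
#'
#' Utility behind orthogonal validations (e.g. looped vs non-looped region
#' pairs from ChIA-PET-style data, or intra- vs inter-compartment pairs): if
#' a structure is faithful, pairs known to interact should sit closer in 3D
#' than control pairs. Reports the mean distance of each set and a two-sample
#' Wilcoxon rank-sum test.
#'
#' @param s a [structure3d].
#' @param set1,set2 two-column matrices (or data frames) of 1-based locus
#'   index pairs.
#' @return list: `mean1`, `mean2`, `p_value`, `statistic`, `n1`, `n2`.
#' @export
region_distance_compare <- function(s, set1, set2) {
  dm <- structure_distances(s)
  pick <- function(set, name) {
    set <- as.matrix(set)
    if (nrow(set) == 0) stop(name, " is empty")
    if (ncol(set) != 2) stop(name, " must have two columns")
    if (any(set < 1) || any(set > nrow(dm))) stop(name, " indexes invalid loci")
    dm[set]
  }
  d1 <- pick(set1, "set1")
  d2 <- pick(set2, "set2")
  wt <- suppressWarnings(stats::wilcox.test(d1, d2))
  list(mean1 = mean(d1), mean2 = mean(d2),
       p_value = wt$p.value, statistic = unname(wt$statistic),
       n1 = length(d1), n2 = length(d2))
}
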