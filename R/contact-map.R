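#' Construct a contact map
#'
#' A contact map is the dense, symmetric N x N matrix of raw Hi-C contact
#' frequencies for one chromosome, together with its bin metadata. Interpreted
#' as an adjacency matrix it defines an edge-weighted undirected graph on the
#' N genomic loci: entry (i, j) is the edge weight between locus i and locus j
#' and zero entries mean the loci are not connected.
#'
#' @param counts square, symmetric, non-negative numeric matrix of contact
#'   frequencies.
#' @param bin_size integer number of base pairs per bin (the map resolution).
#' @param bin_start_bp genomic start position (bp) of each bin; defaults to
#'   `0, bin_size, 2*bin_size, ...`. Bins are half-open `[start, start+bin_size)`.
#' @param chromosome_label chromosome name carried through the pipeline.
#' @param validate check invariants (symmetry, non-negativity, metadata shape).
#'
#' @return An object of class `contact_map` with fields `counts`, `bin_size`,
#'   `bin_start_bp`, `chromosome_label`, `n_loci`.
#' @export
contact_map <- function(counts, bin_size = 1L, bin_start_bp = NULL,
                        chromosome_label = "chr", validate = TRUE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  if (is.null(bin_start_bp)) {
    bin_start_bp <- as.numeric(bin_size) * (seq_len(n) - 1)
  }
  m <- structure(
    list(counts = unname(counts),
         bin_size = as.numeric(bin_size),
         bin_start_bp = as.numeric(bin_start_bp),
         chromosome_label = chromosome_label,
         n_loci = n),
    class = "contact_map")
  if (validate) validate_contact_map(m)
  m
}

#' Validate a contact map's invariants
#'
#' Checks that the count matrix is square, symmetric within 1e-9, non-negative,
#' and that the bin metadata is consistent (length N, strictly increasing).
#'
#' @param m a `contact_map`.
#' @param constant_step also require `bin_start_bp` to advance by exactly
#'   `bin_size` per bin (true for freshly read maps; dropped-empty-bin maps
#'   legitimately violate it).
#' @return `m`, invisibly; errors on violation.
#' @export
validate_contact_map <- function(m, constant_step = TRUE) {
  stopifnot(inherits(m, "contact_map"))
  cm <- m$counts
  if (nrow(cm) != ncol(cm)) stop("contact map counts must be square")
  if (any(!is.finite(cm))) stop("contact map counts must be finite")
  if (any(cm < 0)) stop("contact map counts must be non-negative")
  if (max(abs(cm - t(cm))) > 1e-9) stop("contact map counts must be symmetric within 1e-9")
  if (m$n_loci != nrow(cm)) stop("n_loci does not match counts dimension")
  if (length(m$bin_start_bp) != m$n_loci) stop("bin_start_bp length must equal n_loci")
  if (m$n_loci > 1) {
    d <- diff(m$bin_start_bp)
    if (any(d <= 0)) stop("bin_start_bp must be strictly increasing")
    if (constant_step && any(abs(d - m$bin_size) > 1e-6)) {
      stop("bin_start_bp must advance by bin_size per bin")
    }
  }
  invisible(m)
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s: %d loci @ %s bp/bin, total contacts %.4g\n",
              x$chromosome_label, x$n_loci, format(x$bin_size, big.mark = ","),
              sum(x$counts)))
  invisible(x)
}

#' Drop bins with no observed contacts
#'
#' Removes all-zero rows/columns from a contact map. The remaining
#' `bin_start_bp` keep their original genomic positions, so the constant-step
#' invariant no longer holds; `kept_indices` records the surviving loci.
#'
#' @param m a `contact_map`.
#' @return list with the reduced `map` and integer `kept_indices`.
#' @export
drop_empty_bins <- function(m) {
  keep <- which(rowSums(m$counts) > 0 | colSums(m$counts) > 0)
  out <- structure(
    list(counts = m$counts[keep, keep, drop = FALSE],
         bin_size = m$bin_size,
         bin_start_bp = m$bin_start_bp[keep],
         chromosome_label = m$chromosome_label,
         n_loci = length(keep)),
    class = "contact_map")
  list(map = out, kept_indices = keep)
}

#' Construct a 3D structure
#'
#' An N x 3 matrix of xyz coordinates, one row per genomic locus, in arbitrary
#' units (structures are used for visualization and rank-based comparison, so
#' absolute scale carries no meaning). Bin metadata is copied from the source
#' contact map when available.
#'
#' @param coords N x 3 numeric matrix of coordinates.
#' @param bin_size,bin_start_bp,chromosome_label optional bin metadata.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(coords, bin_size = NA_real_, bin_start_bp = NULL,
                        chromosome_label = "chr") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3) stop("structure coordinates must have 3 columns")
  if (any(!is.finite(coords))) stop("structure coordinates must be finite")
  structure(
    list(coords = unname(coords),
         bin_size = bin_size,
         bin_start_bp = bin_start_bp,
         chromosome_label = chromosome_label,
         n_loci = nrow(coords)),
    class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %s: %d loci\n", x$chromosome_label, x$n_loci))
  invisible(x)
}

#' Pairwise Euclidean distances of a structure
#'
#' @param s a `structure3d` or a bare N x 3 matrix.
#' @return dense symmetric N x N matrix of Euclidean distances.
#' @export
structure_distances <- function(s) {
  coords <- if (inherits(s, "structure3d")) s$coords else as.matrix(s)
  as.matrix(stats::dist(coords))
}
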