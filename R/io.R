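#' Read a Hi-C contact map from a coordinate-list text file
#'
#' Parses the whitespace-separated `position_i position_j count` dialect used
#' by common Hi-C text dumps. Positions are either genomic base-pair positions
#' (multiples of a common bin size) or already bin indices. A record (i, j, c)
#' sets both (i, j) and (j, i); duplicate records for the same unordered pair
#' are summed. Bins with no records inside the observed coordinate range are
#' retained as all-zero rows, so that row counts across resolutions of the same
#' chromosome remain exact scalar multiples (required by the cross-resolution
#' expansion procedure); set `drop_empty = TRUE` to remove them for
#' single-map workflows.
#'
#' @param path path to the text file; `#` comment lines are skipped.
#' @param bin_size integer bp per bin, or `"infer"` to infer the bin size from
#'   the spacing of the observed positions (an inferred step of 1 means the
#'   positions are taken as bin indices).
#' @param positions `"auto"` (bp if all positions are multiples of `bin_size`,
#'   else bin indices), `"bp"`, or `"bin"`.
#' @param chromosome_label label carried into the map.
#' @param drop_empty drop all-zero bins after reading.
#' @return a [contact_map] (when `drop_empty = TRUE`, a list as returned by
#'   [drop_empty_bins] is collapsed back to its reduced map, with
#'   `kept_indices` attached as an attribute).
#' @export
read_coordinate_list <- function(path, bin_size = "infer",
                                 positions = c("auto", "bp", "bin"),
                                 chromosome_label = "chr",
                                 drop_empty = FALSE) {
  positions <- match.arg(positions)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  line_no <- which(keep)
  if (length(lines) == 0) stop("empty coordinate-list file: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("line ", line_no[which(nf < 3)[1]], ": expected >= 3 columns (pos_i pos_j count)")
  }
  pi_ <- as.numeric(vapply(fields, `[[`, "", 1))
  pj_ <- as.numeric(vapply(fields, `[[`, "", 2))
  cc <- as.numeric(vapply(fields, `[[`, "", 3))
  bad <- which(!is.finite(pi_) | !is.finite(pj_) | !is.finite(cc))
  if (length(bad)) stop("line ", line_no[bad[1]], ": non-numeric record")
  neg <- which(cc < 0)
  if (length(neg)) stop("line ", line_no[neg[1]], ": negative contact count")

  pos <- c(pi_, pj_)
  if (identical(bin_size, "infer")) {
    u <- sort(unique(pos))
    if (length(u) == 1) {
      step <- 1
    } else {
      step <- min(diff(u))
      if (step <= 0) stop("cannot infer bin size from positions")
      off <- (u - u[1]) %% step
      if (any(abs(pmin(off, step - off)) > 1e-6 * step)) {
        stop("non-constant inferred bin size: positions are not on a common grid")
      }
    }
    bin_size <- step
    bi <- round(pi_ / step); bj <- round(pj_ / step)
  } else {
    bin_size <- as.numeric(bin_size)
    as_bp <- switch(positions,
                    bp = TRUE,
                    bin = FALSE,
                    auto = all(abs(pos %% bin_size) < 1e-6 |
                               abs(pos %% bin_size - bin_size) < 1e-6))
    if (as_bp) {
      bi <- round(pi_ / bin_size); bj <- round(pj_ / bin_size)
    } else {
      if (any(abs(pos - round(pos)) > 1e-9)) {
        stop("positions declared as bin indices must be integers")
      }
      bi <- round(pi_); bj <- round(pj_)
    }
  }

  b0 <- min(c(bi, bj))
  bi <- bi - b0; bj <- bj - b0
  n <- max(c(bi, bj)) + 1L
  cm <- matrix(0, n, n)
  for (k in seq_along(bi)) {
    i <- bi[k] + 1L; j <- bj[k] + 1L
    if (i == j) {
      cm[i, i] <- cm[i, i] + cc[k]
    } else {
      cm[i, j] <- cm[i, j] + cc[k]
      cm[j, i] <- cm[j, i] + cc[k]
    }
  }
  m <- contact_map(cm, bin_size = bin_size,
                   bin_start_bp = (b0 + 0:(n - 1L)) * bin_size,
                   chromosome_label = chromosome_label)
  if (drop_empty) {
    red <- drop_empty_bins(m)
    m <- red$map
    attr(m, "kept_indices") <- red$kept_indices
  }
  m
}

#' Read a Hi-C contact map from a dense square-matrix text file
#'
#' Reads a whitespace-separated numeric rectangle. Slight numerical asymmetry
#' (at most `1e-6 * max entry`) is repaired by averaging `(M + t(M))/2`;
#' anything larger is rejected.
#'
#' @param path path to the matrix text file.
#' @param bin_size integer bp per bin.
#' @param chromosome_label label carried into the map.
#' @return a [contact_map].
#' @export
read_square_matrix <- function(path, bin_size = 1L, chromosome_label = "chr") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "numeric")
  cm <- unname(as.matrix(tab))
  if (nrow(cm) != ncol(cm)) {
    stop("matrix not square: ", nrow(cm), " x ", ncol(cm))
  }
  if (any(is.nan(cm)) || any(!is.finite(cm))) stop("matrix contains NaN or non-finite entries")
  asym <- max(abs(cm - t(cm)))
  if (asym > 1e-6 * max(abs(cm), 1e-300)) {
    stop("matrix asymmetry ", format(asym), " exceeds tolerance; not a contact map")
  }
  cm <- (cm + t(cm)) / 2
  if (any(cm < 0)) stop("matrix contains negative contact counts")
  contact_map(cm, bin_size = bin_size, chromosome_label = chromosome_label)
}

#' Write a contact map (or any matrix) as dense whitespace-separated text
#'
#' Full-precision output so that write/read round trips reproduce counts
#' exactly.
#'
#' @param m a [contact_map] or a bare matrix.
#' @param path output path.
#' @export
write_contact_matrix <- function(m, path) {
  cm <- if (inherits(m, "contact_map")) m$counts else as.matrix(m)
  lines <- apply(cm, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(lines, path)
}

#' Write a 3D structure to disk
#'
#' `"xyz"` writes one `x y z` line per locus in bin order. `"pdb"` writes one
#' fixed-width ATOM record per locus (CA atoms, sequential serial and residue
#' numbers; backbone connectivity is implied by record order). PDB coordinate
#' fields are 8.3 fixed width, so coordinates are uniformly rescaled when any
#' exceeds +-999.999.
#'
#' @param s a [structure3d].
#' @param path output path.
#' @param format `"xyz"` or `"pdb"`.
#' @export
write_structure <- function(s, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  stopifnot(inherits(s, "structure3d"))
  xyz <- s$coords
  if (any(!is.finite(xyz))) stop("structure has non-finite coordinates")
  if (format == "xyz") {
    lines <- apply(xyz, 1, function(r) paste(sprintf("%.9f", r), collapse = " "))
    writeLines(lines, path)
  } else {
    mx <- max(abs(xyz))
    if (mx > 999.999) xyz <- xyz * (999 / mx)
    n <- nrow(xyz)
    lines <- sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), ((seq_len(n) - 1L) %% 9999L) + 1L,
      xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}

#' Read a structure written in XYZ plain-text format
#'
#' @param path path to an xyz file written by [write_structure].
#' @param chromosome_label label carried into the structure.
#' @return a [structure3d].
#' @export
read_structure_xyz <- function(path, chromosome_label = "chr") {
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) != 3) stop("xyz file must have exactly 3 columns")
  structure3d(as.matrix(tab), chromosome_label = chromosome_label)
}
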