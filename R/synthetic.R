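#' Generate a ground-truth 3D structure
#'
#' Deterministic (per seed) synthetic chromosome backbones used to emulate
#' simulated Hi-C experiments where the true structure is known:
#' * `"helix"` - a regular helix (fixed radius and pitch); consecutive points
#'   are equidistant.
#' * `"random_walk"` - a smoothed cumulative-sum curve, a generic
#'   polymer-like open chain.
#' * `"two_domain"` - two compact globular clusters, consecutive along the
#'   chain and separated in space; the planted two-compartment geometry for
#'   compartment-calling tests. The first `floor(n/2)` loci form domain 1.
#'
#' @param n number of loci (>= 10).
#' @param kind `"helix"`, `"random_walk"`, or `"two_domain"`.
#' @param seed RNG seed (only the stochastic kinds consume it).
#' @return a [structure3d]; for `"two_domain"` the planted domain of each
#'   locus is attached as attribute `"domain"`.
#' @export
make_structure <- function(n, kind = c("helix", "random_walk", "two_domain"),
                           seed = 1L) {
  kind <- match.arg(kind)
  if (n < 10) stop("need n >= 10 loci")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  if (kind == "helix") {
    i <- seq_len(n) - 1
    theta <- 2 * pi * i / 10
    xyz <- cbind(cos(theta), sin(theta), 0.15 * i)
  } else if (kind == "random_walk") {
    steps <- matrix(stats::rnorm(3 * (n + 4)), ncol = 3)
    sm <- apply(steps, 2, function(v) stats::filter(v, rep(1 / 5, 5), sides = 2))
    sm <- sm[!apply(is.na(sm), 1, any), , drop = FALSE][seq_len(n), ]
    xyz <- apply(sm, 2, cumsum)
    # rescale to unit mean bond length; jitter guards coincident points
    bonds <- sqrt(rowSums(diff(xyz)^2))
    xyz <- xyz / mean(bonds) + 1e-4 * matrix(stats::rnorm(3 * n), ncol = 3)
  } else {
    n1 <- floor(n / 2)
    n2 <- n - n1
    blob <- function(m, center) {
      pts <- matrix(stats::rnorm(3 * m, sd = 0.8), ncol = 3)
      sweep(pts, 2, center, `+`)
    }
    xyz <- rbind(blob(n1, c(0, 0, 0)), blob(n2, c(8, 0, 0)))
  }
  s <- structure3d(xyz, chromosome_label = paste0("synthetic_", kind))
  if (kind == "two_domain") {
    attr(s, "domain") <- rep(c(1L, 2L), c(floor(n / 2), n - floor(n / 2)))
  }
  s
}

#' Convert a structure to a synthetic Hi-C contact map
#'
#' Inverts the wish-distance power law: `CF_ij = d(i, j)^(-1/gamma)`, so that
#' `wish_distances(structure_to_map(s, gamma, 0), gamma)` recovers the true
#' pairwise distances exactly - the load-bearing identity behind every
#' parameter-recovery experiment. Optional multiplicative log-normal noise
#' (spread `noise_alpha` on the log scale) emulates experimental counting
#' noise while keeping counts positive and heavy-tailed; `noise_alpha = 0` is
#' exact. The map is symmetric by construction with a zero diagonal.
#'
#' @param s a [structure3d] with strictly positive off-diagonal pair
#'   distances.
#' @param gamma conversion factor used for generation (`gamma_true`).
#' @param noise_alpha log-normal noise spread (>= 0).
#' @param seed RNG seed for the noise.
#' @return a [contact_map] with `bin_size` copied from the structure (or 1).
#' @export
structure_to_map <- function(s, gamma, noise_alpha = 0, seed = 1L) {
  stopifnot(inherits(s, "structure3d"), noise_alpha >= 0)
  if (gamma < 0.1 || gamma > 2) {
    warning("conversion factor ", gamma,
            " lies outside the empirical range [0.1, 2]")
  }
  dm <- structure_distances(s)
  n <- nrow(dm)
  off <- dm[upper.tri(dm)]
  if (any(off <= 0)) stop("structure has coincident points; distances must be positive")
  cf <- matrix(0, n, n)
  cf[upper.tri(cf)] <- off^(-1 / gamma)
  if (noise_alpha > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    cf[upper.tri(cf)] <- cf[upper.tri(cf)] *
      exp(stats::rnorm(sum(upper.tri(cf)), 0, noise_alpha))
  }
  cf <- cf + t(cf)
  bs <- if (is.na(s$bin_size)) 1 else s$bin_size
  contact_map(cf, bin_size = bs, chromosome_label = s$chromosome_label)
}

#' Coarsen a contact map by block-summing bins
#'
#' Produces the lower-resolution companion of a map: counts are summed over
#' k x k bin blocks and the bin size multiplies by k, mimicking re-binning
#' the same experiment at a coarser resolution. If N is not divisible by k
#' the map is padded with zero bins first (with a message), so the coarse map
#' always has `ceiling(N / k)` loci and total contacts are conserved.
#'
#' @param m a [contact_map].
#' @param k integer coarsening factor (>= 1).
#' @return a [contact_map] at `k * bin_size`.
#' @export
coarsen_map <- function(m, k) {
  stopifnot(inherits(m, "contact_map"))
  if (k < 1) stop("k must be >= 1")
  k <- as.integer(k)
  if (k == 1L) return(m)
  cm <- m$counts
  n <- nrow(cm)
  if (n %% k != 0) {
    pad <- k - n %% k
    message("coarsen_map: padding with ", pad, " zero bins")
    cm <- rbind(cbind(cm, matrix(0, n, pad)),
                matrix(0, pad, n + pad))
    n <- n + pad
  }
  g <- rep(seq_len(n %/% k), each = k)
  coarse <- rowsum(t(rowsum(cm, g)), g)
  contact_map(coarse, bin_size = m$bin_size * k,
              bin_start_bp = m$bin_start_bp[1] + (seq_len(n %/% k) - 1) * m$bin_size * k,
              chromosome_label = m$chromosome_label)
}

#' Thin a contact map to a fraction of its coverage
#'
#' Emulates a lower-coverage experiment (fewer replicates / smaller cell
#' population) by binomial thinning: each integerized count c is replaced by
#' a Binomial(c, fraction) draw, applied once per unordered pair and
#' mirrored, so the expected total is `fraction` times the original.
#'
#' @param m a [contact_map].
#' @param fraction retention probability in (0, 1).
#' @param seed RNG seed.
#' @return a [contact_map] with integer counts.
#' @export
split_coverage <- function(m, fraction, seed = 1L) {
  stopifnot(inherits(m, "contact_map"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  cm <- round(m$counts)
  n <- nrow(cm)
  ut <- upper.tri(cm, diag = TRUE)
  vals <- cm[ut]
  thinned <- stats::rbinom(length(vals), size = vals, prob = fraction)
  out <- matrix(0, n, n)
  out[ut] <- thinned
  out <- out + t(out) - diag(diag(out))
  contact_map(out, bin_size = m$bin_size, bin_start_bp = m$bin_start_bp,
              chromosome_label = m$chromosome_label)
}

#' Generate a complete synthetic instance
#'
#' Bundles a ground-truth structure with derived contact maps at one or more
#' resolutions: the finest map comes straight from the inverse power law at
#' `gamma_true` (plus optional noise), coarser companions by block-summing.
#'
#' @param n loci at the finest resolution.
#' @param kind structure kind, see [make_structure].
#' @param gamma_true conversion factor used for generation.
#' @param noise_alpha log-normal noise spread.
#' @param coarsen integer vector of additional coarsening factors (e.g.
#'   `c(2, 4)`).
#' @param seed RNG seed.
#' @return list of class `synthetic_instance`: `true_structure`, `maps`
#'   (named list, finest first), `gamma_true`, `noise_alpha`, `seed`.
#' @export
synthetic_instance <- function(n, kind = "helix", gamma_true = 1,
                               noise_alpha = 0, coarsen = integer(0),
                               seed = 1L) {
  s <- make_structure(n, kind, seed = seed)
  fine <- structure_to_map(s, gamma_true, noise_alpha, seed = seed + 1L)
  maps <- list(fine)
  names(maps) <- "k1"
  for (k in coarsen) {
    maps[[paste0("k", k)]] <- coarsen_map(fine, k)
  }
  structure(list(true_structure = s, maps = maps, gamma_true = gamma_true,
                 noise_alpha = noise_alpha, seed = as.integer(seed)),
            class = "synthetic_instance")
}
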