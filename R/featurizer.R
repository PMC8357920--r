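# Symmetry-function featurizer.
#
# Translation/rotation/permutation-invariant atomic environment descriptors:
# two-body radial terms (gaussian expansion of interatomic distances) and
# three-body angular terms (joint gaussian expansion of the average distance
# to a pair of neighbours and a sharpened cosine expansion of the angle they
# subtend), every term damped by a cosine cutoff.  The raw per-neighbour /
# per-pair functions are contracted with atomic feature vectors (AFVs) into a
# fixed-length per-atom embedding; with one-hot AFVs this reduces to the
# classic per-species / per-species-pair summation.

#' Symmetry-function parameters
#'
#' Defaults: 16 radial centers on (0.8, 5.2] A with width eta_r = 16 A^-2 and
#' cutoff R_cut = 5.2 A; 4 angular distance centers on (0.8, 3.5] A with
#' eta_a = 8, 8 angle centers on \[0, pi\] with sharpness zeta = 32, and a
#' smaller angular cutoff of 3.5 A (the usual convention for three-body
#' terms).  All grids are configurable.
#'
#' @param r_cut radial cutoff, Angstrom.
#' @param radial_centers radial gaussian centers, Angstrom, within (0, r_cut].
#' @param eta_r radial gaussian width, Angstrom^-2.
#' @param ang_cut angular cutoff, Angstrom.
#' @param ang_dist_centers angular-block distance centers, Angstrom.
#' @param eta_a angular-block distance width.
#' @param angle_centers angle centers, radians.
#' @param zeta angular sharpness exponent.
#' @return Object of class `"symfun_params"`.
#' @export
symfun_params <- function(r_cut = 5.2,
                          radial_centers = 0.8 + seq_len(16) * (5.2 - 0.8) / 16,
                          eta_r = 16,
                          ang_cut = 3.5,
                          ang_dist_centers = 0.8 + seq_len(4) * (3.5 - 0.8) / 4,
                          eta_a = 8,
                          angle_centers = seq(0, pi, length.out = 8),
                          zeta = 32) {
  stopifnot(r_cut > 0, ang_cut > 0, eta_r > 0, eta_a > 0, zeta > 0,
            length(radial_centers) >= 1, length(ang_dist_centers) >= 1,
            length(angle_centers) >= 1)
  if (any(radial_centers <= 0) || any(radial_centers > r_cut))
    stop("radial centers must lie within (0, r_cut]", call. = FALSE)
  if (any(ang_dist_centers <= 0) || any(ang_dist_centers > ang_cut))
    stop("angular distance centers must lie within (0, ang_cut]", call. = FALSE)
  structure(list(r_cut = r_cut, radial_centers = radial_centers, eta_r = eta_r,
                 ang_cut = ang_cut, ang_dist_centers = ang_dist_centers,
                 eta_a = eta_a, angle_centers = angle_centers, zeta = zeta),
            class = "symfun_params")
}

#' Number of radial / angular basis functions
#' @param params a [symfun_params()].
#' @return List with `n_radial`, `n_angular` and `embedding_length(d_afv)`.
#' @export
symfun_size <- function(params) {
  nr <- length(params$radial_centers)
  na <- length(params$ang_dist_centers) * length(params$angle_centers)
  list(n_radial = nr, n_angular = na,
       embedding_length = function(d_afv) (nr + na) * d_afv)
}

#' Cosine cutoff function
#'
#' \eqn{f_c(R) = (\cos(\pi R / R_c) + 1)/2} for `R < r_cut`, exactly 0 beyond.
#'
#' @param r distances, Angstrom.
#' @param r_cut cutoff, Angstrom.
#' @export
cutoff_cosine <- function(r, r_cut) {
  ifelse(r < r_cut, 0.5 * (cos(pi * r / r_cut) + 1), 0)
}

#' Compute raw symmetry functions for a conformer
#'
#' Radial term for an ordered pair (i, j) and center \eqn{R_s}:
#' \eqn{\exp(-\eta_r (R_{ij} - R_s)^2) f_c(R_{ij})}.  Angular term for a
#' triplet (i; j < k):
#' \eqn{2^{1-\zeta} (1 + \cos(\theta_{ijk} - \theta_s))^\zeta
#'   \exp(-\eta_a ((R_{ij}+R_{ik})/2 - R_s)^2) f_c(R_{ij}) f_c(R_{ik})},
#' with the angular cutoff used in both \eqn{f_c} factors.  Pairs/triplets at
#' or beyond the cutoff are dropped (their terms are exactly zero).
#'
#' @param conf a [conformer()].
#' @param params a [symfun_params()].
#' @return Object of class `"raw_symfun"` with components `radial`
#'   (`idx`: P x 2 ordered pairs (i, j); `values`: P x n_radial), `angular`
#'   (`idx`: T x 3 triplets (i, j, k), j < k; `values`: T x n_angular),
#'   `n_atoms` and `params`.  A single atom yields empty matrices.
#' @export
compute_symmetry_functions <- function(conf, params = symfun_params()) {
  stopifnot(inherits(conf, "conformer"))
  n <- length(conf$elements)
  d <- as.matrix(stats::dist(conf$coords))
  if (n > 1 && min(d[upper.tri(d)]) < 1e-6)
    stop("coincident atoms (distance < 1e-6 A)", call. = FALSE)
  nr <- length(params$radial_centers)
  na_d <- length(params$ang_dist_centers)
  na_t <- length(params$angle_centers)

  # radial: all ordered pairs with R < r_cut
  pair_idx <- which(d < params$r_cut & upper.tri(d), arr.ind = TRUE)
  if (nrow(pair_idx) > 0) {
    pair_idx <- rbind(pair_idx, pair_idx[, 2:1, drop = FALSE])
    rij <- d[pair_idx]
    fc <- cutoff_cosine(rij, params$r_cut)
    rad <- exp(-params$eta_r * outer(rij, params$radial_centers, "-")^2) * fc
  } else {
    pair_idx <- matrix(integer(0), 0, 2)
    rad <- matrix(numeric(0), 0, nr)
  }
  dimnames(pair_idx) <- NULL

  # angular: for each center atom i, unordered neighbour pairs (j < k)
  trip_idx <- matrix(integer(0), 0, 3)
  ang <- matrix(numeric(0), 0, na_d * na_t)
  if (n > 2) {
    tl <- vector("list", n)
    for (i in seq_len(n)) {
      nb <- which(d[i, ] < params$ang_cut & seq_len(n) != i)
      if (length(nb) >= 2) {
        cmb <- utils::combn(nb, 2)
        tl[[i]] <- cbind(i, t(cmb))
      }
    }
    trip_idx <- do.call(rbind, tl)
    if (is.null(trip_idx)) trip_idx <- matrix(integer(0), 0, 3)
  }
  if (nrow(trip_idx) > 0) {
    i <- trip_idx[, 1]; j <- trip_idx[, 2]; k <- trip_idx[, 3]
    rij <- d[cbind(i, j)]; rik <- d[cbind(i, k)]
    vj <- conf$coords[j, , drop = FALSE] - conf$coords[i, , drop = FALSE]
    vk <- conf$coords[k, , drop = FALSE] - conf$coords[i, , drop = FALSE]
    cth <- rowSums(vj * vk) / (rij * rik)
    cth <- pmin(1, pmax(-1, cth))
    theta <- acos(cth)
    fc2 <- cutoff_cosine(rij, params$ang_cut) * cutoff_cosine(rik, params$ang_cut)
    gdist <- exp(-params$eta_a *
                   outer((rij + rik) / 2, params$ang_dist_centers, "-")^2)
    gang <- 2^(1 - params$zeta) *
      (1 + cos(outer(theta, params$angle_centers, "-")))^params$zeta
    # column layout: distance center index fastest, angle center slower
    ang <- matrix(0, nrow(trip_idx), na_d * na_t)
    for (t in seq_len(na_t))
      ang[, (t - 1L) * na_d + seq_len(na_d)] <- gdist * gang[, t]
    ang <- ang * fc2
  }
  structure(list(radial = list(idx = pair_idx, values = rad),
                 angular = list(idx = trip_idx, values = ang),
                 n_atoms = n, params = params),
            class = "raw_symfun")
}

#' Linear contraction operators of a featurized conformer
#'
#' The embedding is linear in the per-atom AFV matrix: both the radial and
#' the angular block of atom i can be written as `C %*% A` where `A` is the
#' N x d_afv AFV matrix.  This function materializes the two operators
#' (`c_rad`: (N * n_radial) x N, rows ordered radial-basis-fastest within
#' atom; `c_ang`: (N * n_angular) x N).  The angular operator already folds
#' in the symmetric pair reduction (sum of the two neighbour AFVs).
#'
#' @param raw a `"raw_symfun"` from [compute_symmetry_functions()].
#' @return List with matrices `c_rad`, `c_ang` and sizes.
#' @export
contraction_ops <- function(raw) {
  n <- raw$n_atoms
  nr <- ncol(raw$radial$values)
  na <- ncol(raw$angular$values)
  c_rad <- matrix(0, n * nr, n)
  if (nrow(raw$radial$idx) > 0) {
    i <- raw$radial$idx[, 1]; j <- raw$radial$idx[, 2]
    for (r in seq_len(nr)) {
      rows <- (i - 1L) * nr + r
      c_rad[cbind(rows, j)] <- c_rad[cbind(rows, j)] + raw$radial$values[, r]
    }
  }
  c_ang <- matrix(0, n * na, n)
  if (nrow(raw$angular$idx) > 0) {
    # each triplet (i; j, k) contributes its basis vector to columns j and k
    # of atom i's row block; aggregate by (center, neighbour) first
    i2 <- rep(raw$angular$idx[, 1], 2L)
    j2 <- c(raw$angular$idx[, 2], raw$angular$idx[, 3])
    v2 <- rbind(raw$angular$values, raw$angular$values)
    agg <- rowsum(v2, group = (i2 - 1L) * n + j2)
    key <- as.integer(rownames(agg))
    ui <- (key - 1L) %/% n + 1L
    uj <- (key - 1L) %% n + 1L
    rows <- rep((ui - 1L) * na, each = na) + seq_len(na)
    cols <- rep(uj, each = na)
    c_ang[cbind(rows, cols)] <- as.vector(t(agg))
  }
  list(c_rad = c_rad, c_ang = c_ang, n_atoms = n, n_radial = nr, n_angular = na)
}

# The contraction product M = C %*% A has rows ordered (basis within atom);
# the embedding needs rows = atoms with flattened (basis, afv-dim) columns.
# That reshape is a fixed index permutation; gather vectors are memoized
# per (n_atoms, n_basis, d_afv).
.perm_cache <- new.env(parent = emptyenv())
.reshape_perm <- function(n, nb, d) {
  key <- paste(n, nb, d)
  p <- .perm_cache[[key]]
  if (is.null(p)) {
    # target (i, (c-1)*nb + r) <- M[(i-1)*nb + r, c]
    i <- rep(seq_len(n), times = nb * d)
    r <- rep(rep(seq_len(nb), each = n), times = d)
    cc <- rep(seq_len(d), each = n * nb)
    p <- (i - 1L) * nb + r + (cc - 1L) * (n * nb)
    .perm_cache[[key]] <- p
  }
  p
}

# embedding matrix from precomputed operators and an AFV matrix;
# rows = atoms, cols = flattened (radial block, angular block),
# basis index fastest within each d_afv column.
.embed_from_ops <- function(ops, afvs) {
  n <- ops$n_atoms; d <- ncol(afvs)
  mr <- ops$c_rad %*% afvs                       # (n * nr) x d
  ma <- ops$c_ang %*% afvs                       # (n * na) x d
  xr <- matrix(mr[.reshape_perm(n, ops$n_radial, d)], n, ops$n_radial * d)
  xa <- matrix(ma[.reshape_perm(n, ops$n_angular, d)], n, ops$n_angular * d)
  cbind(xr, xa)
}

# backward of .embed_from_ops: gradient wrt the AFV matrix
.embed_backward <- function(ops, g_embed) {
  n <- ops$n_atoms
  nrd <- ops$n_radial; nad <- ops$n_angular
  d <- ncol(g_embed) / (nrd + nad)
  gmr <- matrix(0, n * nrd, d)
  gmr[.reshape_perm(n, nrd, d)] <- g_embed[, seq_len(nrd * d)]
  gma <- matrix(0, n * nad, d)
  gma[.reshape_perm(n, nad, d)] <- g_embed[, nrd * d + seq_len(nad * d)]
  crossprod(ops$c_rad, gmr) + crossprod(ops$c_ang, gma)
}

#' Contract raw symmetry functions with atomic feature vectors
#'
#' Computes the per-atom embedding: the radial block accumulates, for every
#' neighbour j, the outer product of the radial basis values with the AFV of
#' j; the angular block accumulates, for every neighbour pair (j, k), the
#' outer product of the angular basis values with the symmetric pair feature
#' (elementwise sum of the two neighbour AFVs).  The result is flattened to a
#' fixed length `(n_radial + n_angular) * d_afv` independent of the neighbour
#' count; an isolated atom maps to the zero vector.
#'
#' @param raw a `"raw_symfun"` from [compute_symmetry_functions()].
#' @param atom_afvs N x d_afv matrix: one AFV per atom of the conformer.
#' @return N x embedding_length numeric matrix.
#' @export
contract_embedding <- function(raw, atom_afvs) {
  atom_afvs <- as.matrix(atom_afvs)
  if (nrow(atom_afvs) != raw$n_atoms)
    stop("need one AFV row per atom (got ", nrow(atom_afvs), " rows for ",
         raw$n_atoms, " atoms)", call. = FALSE)
  .embed_from_ops(contraction_ops(raw), atom_afvs)
}
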