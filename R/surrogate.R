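# Deterministic physics surrogate: an electronegativity-equalization (QEq
# style) energy model used as ground truth for desk-scale training and
# validation experiments.  Per spin channel the atomic charges minimize
#
#   sum_i (chi_Z + s * spin_shift_Z) q_i + 1/2 sum_i eta_Z q_i^2
#     + 1/2 sum_{i != j} J(R_ij) q_i q_j        s.t.  sum_i q_i = Q^s
#
# with a shielded, Debye-screened Coulomb kernel
#   J(R) = k_e exp(-R/lambda) / (R^3 + gamma_ij^3)^(1/3).
# The pair shielding length gamma_ij = 4 k_e / (eta_i + eta_j) caps the
# on-site limit of the kernel at a quarter of the summed atomic hardnesses,
# which keeps diag(eta) + J positive definite and the equilibrated charges
# bounded for arbitrary geometries; the screening length lambda (default
# 4 A, a typical effective dielectric screening scale in EEM
# parameterizations) makes the oracle genuinely short-ranged, so that a
# model with a finite descriptor cutoff can in principle recover it.  The
# constrained minimum is solved exactly through the KKT linear system.  The total energy adds per-element self energies,
# harmonic bond springs and a short-range pair repulsion.  The spin shift is
# applied with opposite signs to the alpha/beta electronegativities for
# open-shell states only, giving ions a nontrivial spin-density pattern.
#
# The geometric terms are deliberately thermal-scale: with the generator's
# 0.05-0.15 A Gaussian coordinate perturbations (its near-equilibrium MD
# stand-in), the default spring constant of 3 eV/A^2 puts per-bond strain
# energies at a few k_B T (~0.1 eV), as near-equilibrium sampling should.

.SURROGATE_ELEMENT_TABLE <- data.frame(
  element = c("H", "C", "N", "O", "F", "Si", "P", "S", "Cl"),
  chi    = c(7.18, 6.27, 7.30, 7.54, 10.41, 4.77, 5.62, 6.22, 8.30),  # eV/e
  eta    = c(12.9, 10.0, 14.5, 12.2, 14.0, 6.8, 9.8, 8.3, 9.4),       # eV/e^2
  e0     = c(-13.6, -100, -130, -160, -200, -240, -280, -320, -360),  # eV
  radius = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.11, 1.07, 1.05, 1.02),   # A
  spin_shift = c(0.3, 1.0, 1.2, 1.4, 1.6, 0.8, 0.9, 1.0, 1.1),        # eV/e
  valence = c(1L, 4L, 3L, 2L, 1L, 4L, 3L, 2L, 1L),
  stringsAsFactors = FALSE)

#' Parameters of the electronegativity-equalization surrogate
#'
#' Per-element Mulliken-style electronegativities (eV/e), hardnesses
#' (eV/e^2), self-energies (eV), covalent radii (A) and spin shifts (eV/e,
#' applied with opposite sign to the two spin channels of open-shell
#' states), plus global constants: the Coulomb scale (14.399645 eV A/e^2),
#' a harmonic bond spring constant, a short-range pair repulsion, and label
#' noise widths for energies and charges.
#'
#' @param elements element subset to expose (default \{H, C, N, O\}).
#' @param coulomb_scale Coulomb constant, eV A / e^2.
#' @param screening_length Debye screening length of the Coulomb kernel, A.
#' @param k_bond bond spring constant, eV / A^2.
#' @param k_rep,rho_rep short-range repulsion amplitude (eV) and decay (A).
#' @param bond_tol bonds are detected as pairs closer than
#'   `bond_tol * (r_i + r_j)`.
#' @param sigma_energy,sigma_charge label noise standard deviations (eV, e).
#'   Charge noise is drawn zero-sum per spin channel so labels conserve the
#'   channel charge exactly.
#' @return Object of class `"surrogate_params"`.
#' @export
surrogate_params <- function(elements = c("H", "C", "N", "O"),
                             coulomb_scale = 14.399645, screening_length = 4,
                             k_bond = 3, k_rep = 2, rho_rep = 0.4,
                             bond_tol = 1.3,
                             sigma_energy = 0.01, sigma_charge = 0.005) {
  tab <- .SURROGATE_ELEMENT_TABLE
  if (!all(elements %in% tab$element))
    stop("unsupported element(s) for the surrogate: ",
         paste(setdiff(elements, tab$element), collapse = ", "), call. = FALSE)
  stopifnot(coulomb_scale > 0, screening_length > 0, k_bond >= 0,
            k_rep >= 0, rho_rep > 0, sigma_energy >= 0, sigma_charge >= 0)
  structure(list(elements = elements,
                 table = tab[tab$element %in% c(elements, "H"), , drop = FALSE],
                 full_table = tab,
                 coulomb_scale = coulomb_scale,
                 screening_length = screening_length, k_bond = k_bond,
                 k_rep = k_rep, rho_rep = rho_rep, bond_tol = bond_tol,
                 sigma_energy = sigma_energy, sigma_charge = sigma_charge),
            class = "surrogate_params")
}

.sur_lookup <- function(params, elements, field) {
  tab <- params$full_table
  tab[[field]][match(elements, tab$element)]
}

.sur_bonds <- function(conf, params) {
  n <- length(conf$elements)
  if (n < 2) return(matrix(integer(0), 0, 2))
  d <- as.matrix(stats::dist(conf$coords))
  r <- .sur_lookup(params, conf$elements, "radius")
  thr <- outer(r, r, "+") * params$bond_tol
  idx <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  dimnames(idx) <- NULL
  idx
}

#' Exact surrogate solve: energy and spin-resolved charges
#'
#' Minimizes the per-channel electronegativity-equalization energy under the
#' channel charge constraint via the KKT linear system (always solvable for
#' positive hardness and a shielded kernel), and adds the geometric energy
#' terms.  Deterministic; no noise is applied here.
#'
#' @param conf a [conformer()].
#' @param state a [spin_state()].
#' @param params a [surrogate_params()].
#' @return List with `energy` (total, eV) and `charges` (N x 2 alpha/beta
#'   matrix; each column sums exactly to its channel charge).
#' @export
surrogate_solve <- function(conf, state, params = surrogate_params()) {
  stopifnot(inherits(conf, "conformer"), inherits(state, "spin_state"))
  n <- length(conf$elements)
  chi <- .sur_lookup(params, conf$elements, "chi")
  eta <- .sur_lookup(params, conf$elements, "eta")
  rad <- .sur_lookup(params, conf$elements, "radius")
  sshift <- .sur_lookup(params, conf$elements, "spin_shift")
  open_shell <- state$multiplicity > 1L

  if (n > 1) {
    d <- as.matrix(stats::dist(conf$coords))
    gamma <- 4 * params$coulomb_scale / outer(eta, eta, "+")
    J <- params$coulomb_scale * exp(-d / params$screening_length) /
      (d^3 + gamma^3)^(1 / 3)
    diag(J) <- 0
  } else J <- matrix(0, 1, 1)
  A <- J; diag(A) <- eta

  solve_channel <- function(b, Qs) {
    K <- rbind(cbind(A, 1), c(rep(1, n), 0))
    sol <- solve(K, c(-b, Qs))
    q <- sol[seq_len(n)]
    e <- sum(b * q) + 0.5 * sum(q * (A %*% q))
    list(q = q, e = e)
  }
  sgn <- c(1, -1)  # alpha gets +shift, beta -shift (open shell only)
  qs <- matrix(0, n, 2)
  e_el <- 0
  for (s in 1:2) {
    b <- chi + (if (open_shell) sgn[s] * sshift else 0)
    Qs <- if (s == 1) state$q_alpha else state$q_beta
    r <- solve_channel(b, Qs)
    qs[, s] <- r$q
    e_el <- e_el + r$e
  }

  e_geom <- 0
  bonds <- .sur_bonds(conf, params)
  if (nrow(bonds) > 0) {
    db <- sqrt(rowSums((conf$coords[bonds[, 1], , drop = FALSE] -
                          conf$coords[bonds[, 2], , drop = FALSE])^2))
    r0 <- rad[bonds[, 1]] + rad[bonds[, 2]]
    e_geom <- e_geom + sum(0.5 * params$k_bond * (db - r0)^2)
  }
  if (n > 1) {
    dv <- stats::dist(conf$coords)
    e_geom <- e_geom + sum(params$k_rep * exp(-dv / params$rho_rep))
  }
  list(energy = sum(.sur_lookup(params, conf$elements, "e0")) + e_el + e_geom,
       charges = qs)
}

#' Ground-truth conceptual-DFT report from the surrogate
#'
#' Applies the same vertical three-state construction as [cdft_report()] to
#' exact surrogate energies and charges; used as the recovery target when
#' validating trained models.
#'
#' @param conf a [conformer()].
#' @param params a [surrogate_params()].
#' @param charge reference charge (default 0).
#' @return A `"cdft_report"`.
#' @export
surrogate_cdft <- function(conf, params = surrogate_params(), charge = 0L) {
  states <- .state_triple(conf, as.integer(charge))
  sol <- lapply(states, function(st) surrogate_solve(conf, st, params))
  en <- vapply(sol, function(s) s$energy, 0)
  ipea <- vertical_ip_ea(en[["neutral"]], en[["cation"]], en[["anion"]])
  gi <- global_indexes(ipea$ip, ipea$ea)
  qtot <- lapply(sol, function(s) rowSums(s$charges))
  fk <- condensed_fukui(qtot$cation, qtot$neutral, qtot$anion)
  ph <- condensed_philicity(gi$omega, fk)
  structure(c(list(ip = ipea$ip, ea = ipea$ea), gi, fk, ph,
              list(state_energies = en,
                   state_charges = lapply(sol, function(s) s$charges),
                   conformer = conf)),
            class = "cdft_report")
}

# ---- toy molecule generation ------------------------------------------------

# random tree-bonded molecule: heavy-atom tree, hydrogens fill the remaining
# valence, electron count forced even so the neutral parent is a singlet.
.random_molecule <- function(n_heavy, elements, params) {
  heavy_pool <- setdiff(elements, "H")
  wts <- ifelse(heavy_pool == "C", 0.6, 0.4 / max(1, length(heavy_pool) - 1))
  el <- sample(heavy_pool, n_heavy, replace = TRUE, prob = wts)
  rad <- .sur_lookup(params, el, "radius")
  val <- .sur_lookup(params, el, "valence")
  coords <- matrix(0, n_heavy, 3)
  used <- integer(n_heavy)  # bonds used per heavy atom
  place_near <- function(coords_have, parent, blen) {
    for (try in 1:60) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      pos <- coords_have[parent, ] + blen * u
      dmin <- min(sqrt(rowSums((coords_have - matrix(pos, nrow(coords_have), 3,
                                                     byrow = TRUE))^2)))
      if (dmin > 0.85 * blen) return(pos)
    }
    pos
  }
  if (n_heavy > 1) {
    for (i in 2:n_heavy) {
      cand <- which(used[1:(i - 1)] < val[1:(i - 1)])
      if (!length(cand)) cand <- seq_len(i - 1)
      parent <- if (length(cand) == 1) cand else sample(cand, 1)
      coords[i, ] <- place_near(coords[1:(i - 1), , drop = FALSE], parent,
                                rad[parent] + rad[i])
      used[parent] <- used[parent] + 1L
      used[i] <- used[i] + 1L
    }
  }
  # hydrogens
  r_h <- .sur_lookup(params, "H", "radius")
  h_coords <- NULL; h_parent <- integer(0)
  for (i in seq_len(n_heavy)) {
    for (k in seq_len(max(0, val[i] - used[i]))) {
      all_coords <- rbind(coords, h_coords)
      pos <- place_near(all_coords, i, rad[i] + r_h)
      h_coords <- rbind(h_coords, pos)
      h_parent <- c(h_parent, i)
    }
  }
  el_all <- c(el, rep("H", length(h_parent)))
  coords_all <- rbind(coords, h_coords)
  # force an even electron count (neutral singlet parent)
  if (sum(atomic_numbers(el_all)) %% 2L == 1L) {
    h_idx <- which(el_all == "H")
    if (length(h_idx)) {
      drop <- h_idx[length(h_idx)]
      el_all <- el_all[-drop]
      coords_all <- coords_all[-drop, , drop = FALSE]
    } else {
      pos <- place_near(coords_all, 1L, rad[1] + r_h)
      el_all <- c(el_all, "H")
      coords_all <- rbind(coords_all, pos)
    }
  }
  rownames(coords_all) <- NULL
  list(elements = el_all, coords = coords_all)
}

.states_for_parent <- function(parent_charge) {
  switch(as.character(parent_charge),
         "0" = c(-1L, 0L, 1L),
         "-1" = c(-1L, 0L),
         "1" = c(0L, 1L),
         stop("parent charge must be -1, 0 or +1", call. = FALSE))
}

#' Generate a labelled surrogate dataset
#'
#' Builds random tree-bonded toy molecules over the configured element
#' subset, perturbs each one into `n_conformers` near-equilibrium geometries
#' (Gaussian coordinate noise with amplitude drawn from
#' `perturbation_range`), and labels every conformer in the neighbouring
#' charge states of its parent (-1, 0 for anions; -1, 0, +1 for neutral
#' parents; 0, +1 for cations) with exact surrogate energies/charges plus
#' optional Gaussian label noise.  Fully reproducible from `seed`.  Record
#' ids are `mol<i>/c<j>/q<Q>` so that the states and conformers of one
#' molecule can be regrouped.
#'
#' @param n_molecules number of distinct molecules.
#' @param size_range inclusive range of heavy-atom counts.
#' @param n_conformers perturbed conformers per molecule.
#' @param parent_charge charge state whose neighbourhood is labelled
#'   (default 0: neutral parents, three states per conformer).
#' @param params a [surrogate_params()].
#' @param perturbation_range Gaussian per-coordinate amplitude bounds, A.
#' @param seed integer seed.
#' @return A [mol_dataset()].
#' @export
generate_dataset <- function(n_molecules, size_range = c(2L, 8L),
                             n_conformers = 1L, parent_charge = 0L,
                             params = surrogate_params(),
                             perturbation_range = c(0.05, 0.15),
                             seed = 1L) {
  stopifnot(n_molecules >= 1, length(params$elements) >= 1)
  if (!any(params$elements != "H"))
    stop("element subset must contain at least one heavy element",
         call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  states_q <- .states_for_parent(parent_charge)
  samples <- list()
  for (im in seq_len(n_molecules)) {
    nh <- if (size_range[1] == size_range[2]) size_range[1] else
      sample(size_range[1]:size_range[2], 1)
    mol <- .random_molecule(nh, params$elements, params)
    for (ic in seq_len(n_conformers)) {
      amp <- stats::runif(1, perturbation_range[1], perturbation_range[2])
      coords <- mol$coords + matrix(stats::rnorm(length(mol$coords), sd = amp),
                                    nrow(mol$coords), 3)
      for (q in states_q) {
        id <- sprintf("mol%05d/c%d/q%+d", im, ic, q)
        conf <- conformer(mol$elements, coords, id = id)
        st <- spin_state_for(conf, q)
        sol <- surrogate_solve(conf, st, params)
        energy <- sol$energy + stats::rnorm(1, sd = params$sigma_energy)
        charges <- sol$charges
        if (params$sigma_charge > 0) {
          nz <- matrix(stats::rnorm(length(charges), sd = params$sigma_charge),
                       nrow(charges), 2)
          nz <- sweep(nz, 2, colMeans(nz))  # zero-sum per channel
          charges <- charges + nz
        }
        samples[[length(samples) + 1L]] <- labeled_sample(conf, st, energy,
                                                          charges)
      }
    }
  }
  mol_dataset(samples)
}
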