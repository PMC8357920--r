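#' @keywords internal
"_PACKAGE"

# Elements the models are parametrized for, with atomic numbers.
.SUPPORTED_Z <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L,
                  Si = 14L, P = 15L, S = 16L, Cl = 17L)

#' Chemical elements supported by the package
#'
#' @return Character vector of element symbols.
#' @export
supported_elements <- function() names(.SUPPORTED_Z)

#' Atomic numbers of element symbols
#'
#' @param elements character vector of element symbols.
#' @return Integer vector of atomic numbers.
#' @export
atomic_numbers <- function(elements) {
  z <- .SUPPORTED_Z[elements]
  if (anyNA(z)) {
    bad <- unique(elements[is.na(z)])
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         "; supported set is {", paste(names(.SUPPORTED_Z), collapse = ", "),
         "}", call. = FALSE)
  }
  unname(z)
}

# eV -> kcal/mol conversion used for optional reporting
.EV_TO_KCALMOL <- 23.060548

#' Convert energies between eV and kcal/mol
#'
#' All internal energies are in eV; tables in the literature often use
#' kcal/mol.  One documented constant (1 eV = 23.060548 kcal/mol) is used for
#' both directions.
#'
#' @param x numeric energies.
#' @return Converted numeric vector.
#' @export
ev_to_kcalmol <- function(x) x * .EV_TO_KCALMOL

#' @rdname ev_to_kcalmol
#' @export
kcalmol_to_ev <- function(x) x / .EV_TO_KCALMOL

#' Molecular conformer
#'
#' A conformer is a list of element symbols plus Cartesian coordinates in
#' Angstrom.  It is the geometric input to every operation in the package.
#'
#' @param elements character vector of element symbols (length N >= 1), all
#'   from [supported_elements()].
#' @param coords numeric N x 3 matrix of Cartesian coordinates, Angstrom.
#' @param id opaque string label.
#' @return An object of class `"conformer"`.
#' @examples
#' conformer(c("O", "H", "H"),
#'           rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' @export
conformer <- function(elements, coords, id = "") {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) < 1L)
    stop("a conformer needs at least one atom", call. = FALSE)
  if (nrow(coords) != length(elements) || ncol(coords) != 3L)
    stop("coords must be a ", length(elements), " x 3 matrix", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite", call. = FALSE)
  atomic_numbers(elements)  # validates the element set
  structure(list(elements = elements, coords = unname(coords),
                 id = as.character(id)),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  comp <- table(x$elements)
  cat(sprintf("<conformer> %s: %d atoms (%s)\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              length(x$elements),
              paste0(names(comp), comp, collapse = " ")))
  invisible(x)
}

#' Number of electrons of a conformer in a given charge state
#'
#' @param conf a [conformer()].
#' @param charge total molecular charge (elementary charge units).
#' @return Integer electron count, sum(Z) - charge.
#' @export
n_electrons <- function(conf, charge = 0L) {
  sum(atomic_numbers(conf$elements)) - as.integer(charge)
}

#' Spin state: total charge and multiplicity with per-channel charges
#'
#' Converts a (charge, multiplicity) pair into per-spin-channel molecular
#' charges.  The package convention is that the alpha channel carries the
#' excess unpaired electrons, i.e. more electrons and hence the more negative
#' channel charge:
#' \deqn{Q^\alpha = (Q - (M-1))/2, \quad Q^\beta = (Q + (M-1))/2}
#' so that \eqn{Q^\alpha + Q^\beta = Q} exactly.  The electron count is needed
#' to check the parity constraint: M - 1 (number of unpaired electrons) must
#' have the same parity as the electron count.
#'
#' @param charge integer total molecular charge Q.
#' @param multiplicity integer spin multiplicity M = 2S + 1, M >= 1.
#' @param n_electrons integer number of electrons (>= 1), e.g. from
#'   [n_electrons()].
#' @return An object of class `"spin_state"` with fields `charge`,
#'   `multiplicity`, `q_alpha`, `q_beta`.
#' @examples
#' spin_state(0, 1, 10)   # closed shell: Q_alpha = Q_beta = 0
#' spin_state(1, 2, 9)    # doublet cation: Q_alpha = 0, Q_beta = 1
#' @export
spin_state <- function(charge, multiplicity, n_electrons) {
  charge <- as.integer(charge)
  multiplicity <- as.integer(multiplicity)
  n_electrons <- as.integer(n_electrons)
  if (multiplicity < 1L) stop("multiplicity must be >= 1", call. = FALSE)
  if (n_electrons < 1L) stop("n_electrons must be >= 1", call. = FALSE)
  if ((n_electrons %% 2L) != ((multiplicity - 1L) %% 2L))
    stop(sprintf(paste0("parity violation: %d electrons cannot form ",
                        "multiplicity %d (M - 1 = %d unpaired electrons ",
                        "must have the same parity as the electron count)"),
                 n_electrons, multiplicity, multiplicity - 1L),
         call. = FALSE)
  m1 <- multiplicity - 1L
  structure(list(charge = charge, multiplicity = multiplicity,
                 q_alpha = (charge - m1) / 2, q_beta = (charge + m1) / 2),
            class = "spin_state")
}

#' @export
print.spin_state <- function(x, ...) {
  cat(sprintf("<spin_state> Q = %+d, M = %d (Q_alpha = %g, Q_beta = %g)\n",
              x$charge, x$multiplicity, x$q_alpha, x$q_beta))
  invisible(x)
}

#' Spin state for a specific conformer
#'
#' Convenience wrapper around [spin_state()] that derives the electron count
#' from the conformer composition.
#'
#' @inheritParams spin_state
#' @param conf a [conformer()].
#' @export
spin_state_for <- function(conf, charge, multiplicity = NULL) {
  ne <- n_electrons(conf, charge)
  if (is.null(multiplicity))
    multiplicity <- 1L + (ne %% 2L)  # singlet if even, doublet if odd
  spin_state(charge, multiplicity, ne)
}

#' Reconstruct (charge, multiplicity) from per-channel charges
#'
#' Exact inverse of the channel-charge convention of [spin_state()].
#'
#' @param q_alpha,q_beta per-channel molecular charges.
#' @return List with integer `charge` and `multiplicity`.
#' @export
spin_state_from_channels <- function(q_alpha, q_beta) {
  list(charge = as.integer(round(q_alpha + q_beta)),
       multiplicity = as.integer(round(q_beta - q_alpha)) + 1L)
}

#' Labelled training sample
#'
#' One conformer in one spin state together with its reference total energy
#' (eV) and per-atom spin-resolved charges (elementary charge).
#'
#' @param conf a [conformer()].
#' @param state a [spin_state()].
#' @param energy total energy, eV.
#' @param charges N x 2 matrix of per-atom (alpha, beta) channel charges.
#' @return Object of class `"labeled_sample"`.
#' @export
labeled_sample <- function(conf, state, energy, charges) {
  stopifnot(inherits(conf, "conformer"), inherits(state, "spin_state"))
  charges <- as.matrix(charges)
  storage.mode(charges) <- "double"
  n <- length(conf$elements)
  if (nrow(charges) != n || ncol(charges) != 2L)
    stop("charges must be an N x 2 (alpha, beta) matrix", call. = FALSE)
  if (!is.finite(energy)) stop("energy must be finite", call. = FALSE)
  dq <- abs(sum(charges) - state$charge)
  if (dq > 0.05)
    stop(sprintf("sum of atomic charges (%.4f) deviates from total charge %d by %.4f > 0.05",
                 sum(charges), state$charge, dq), call. = FALSE)
  structure(list(conformer = conf, spin_state = state,
                 energy = as.numeric(energy), charges = unname(charges)),
            class = "labeled_sample")
}

#' @export
print.labeled_sample <- function(x, ...) {
  cat(sprintf("<labeled_sample> %d atoms, Q = %+d, M = %d, E = %.4f eV\n",
              length(x$conformer$elements), x$spin_state$charge,
              x$spin_state$multiplicity, x$energy))
  invisible(x)
}
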