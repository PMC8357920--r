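# Conceptual-DFT descriptors from three-state predictions at fixed geometry.
#
# Sign conventions: hardness is implemented as eta = +(IP - EA)/2, so that
# eta > 0 whenever IP > EA and the electrophilicity omega = mu^2 / (2 eta) is
# positive; and the radical Fukui function as f0 = (q_C - q_A)/2 =
# (f- + f+)/2, which preserves the sum-to-one normalization.  Both choices
# are the standard finite-difference c-DFT forms (printed variants with the
# opposite eta sign or with a "+" in f0 break positivity / normalization and
# are treated as misprints; see the package vignette).

#' Vertical ionization potential and electron affinity
#'
#' \eqn{IP = E_{cation} - E_{neutral}}, \eqn{EA = E_{neutral} - E_{anion}},
#' all three energies taken at the same geometry (vertical transitions).
#'
#' @param e_neutral,e_cation,e_anion total energies, eV, same geometry.
#' @return List with `ip` and `ea`, eV.
#' @examples
#' vertical_ip_ea(-100, -92, -101)  # IP = 8, EA = 1
#' @export
vertical_ip_ea <- function(e_neutral, e_cation, e_anion) {
  if (!all(is.finite(c(e_neutral, e_cation, e_anion))))
    stop("non-finite state energy", call. = FALSE)
  list(ip = e_cation - e_neutral, ea = e_neutral - e_anion)
}

#' Global conceptual-DFT indexes from IP and EA
#'
#' \eqn{\mu = -(IP + EA)/2}, \eqn{\chi = -\mu}, \eqn{\eta = (IP - EA)/2},
#' \eqn{\omega = \mu^2 / (2\eta)}.
#'
#' @param ip,ea vertical ionization potential and electron affinity, eV.
#' @return List with `mu`, `chi`, `eta`, `omega` (all eV).  `eta = 0` is an
#'   error (omega undefined); a negative eta is kept but flagged with a
#'   warning.
#' @examples
#' global_indexes(8, 2)  # mu = -5, chi = 5, eta = 3, omega = 25/6
#' @export
global_indexes <- function(ip, ea) {
  if (!all(is.finite(c(ip, ea)))) stop("non-finite IP/EA", call. = FALSE)
  mu <- -(ip + ea) / 2
  eta <- (ip - ea) / 2
  if (eta == 0)
    stop("hardness eta = (IP - EA)/2 is zero; electrophilicity undefined",
         call. = FALSE)
  if (eta < 0)
    warning("negative hardness (EA > IP): omega sign is not meaningful")
  list(mu = mu, chi = -mu, eta = eta, omega = mu^2 / (2 * eta))
}

#' Condensed Fukui functions from three-state atomic charges
#'
#' Finite-difference condensed Fukui functions:
#' \eqn{f^-_a = q_a(cation) - q_a(neutral)} (electrophilic attack),
#' \eqn{f^+_a = q_a(neutral) - q_a(anion)} (nucleophilic attack),
#' \eqn{f^0_a = (f^-_a + f^+_a)/2} (radical attack).
#' When each charge vector sums to its state's total charge, every Fukui
#' vector sums to exactly 1.
#'
#' @param q_cation,q_neutral,q_anion per-atom total charges (alpha + beta) in
#'   the three states, same geometry.
#' @return List with vectors `f_minus`, `f_plus`, `f_zero`.
#' @export
condensed_fukui <- function(q_cation, q_neutral, q_anion) {
  if (length(q_cation) != length(q_neutral) ||
      length(q_neutral) != length(q_anion))
    stop("charge vectors must have equal length", call. = FALSE)
  f_minus <- q_cation - q_neutral
  f_plus <- q_neutral - q_anion
  list(f_minus = f_minus, f_plus = f_plus, f_zero = (f_minus + f_plus) / 2)
}

#' Condensed philicity indexes
#'
#' \eqn{\omega^x_a = \omega f^x_a} for x in \{-, +, 0\}.
#'
#' @param omega global electrophilicity index, eV.
#' @param fukui list from [condensed_fukui()].
#' @return List with `omega_minus`, `omega_plus`, `omega_zero` (eV).
#' @export
condensed_philicity <- function(omega, fukui) {
  if (!is.finite(omega)) stop("non-finite omega", call. = FALSE)
  list(omega_minus = omega * fukui$f_minus,
       omega_plus = omega * fukui$f_plus,
       omega_zero = omega * fukui$f_zero)
}

.state_triple <- function(conf, charge) {
  # ion radicals of a closed-shell parent are doublets
  list(neutral = spin_state_for(conf, charge),
       cation = spin_state_for(conf, charge + 1L),
       anion = spin_state_for(conf, charge - 1L))
}

#' Full conceptual-DFT report for a conformer
#'
#' Runs three forward passes (cation, neutral, anion relative to `charge`) at
#' fixed geometry through a charge-conditioned model (or an ensemble of
#' models, averaged) and assembles IP, EA, the global indexes and the
#' condensed per-atom indexes from per-atom total charges
#' \eqn{q_a = q_a^\alpha + q_a^\beta}.
#'
#' @param model a trained `aimnet_nse` model, or a list of such models
#'   (ensemble).
#' @param conf a [conformer()].
#' @param charge charge of the "neutral" reference state (default 0).
#' @return Object of class `"cdft_report"`: `ip`, `ea`, `mu`, `chi`, `eta`,
#'   `omega`, per-atom `f_minus`/`f_plus`/`f_zero`,
#'   `omega_minus`/`omega_plus`/`omega_zero`, per-state energies and charge
#'   matrices.
#' @export
cdft_report <- function(model, conf, charge = 0L) {
  members <- if (inherits(model, "neq_model")) list(model) else model
  states <- .state_triple(conf, as.integer(charge))
  pred <- lapply(states, function(st) ensemble_predict(members, conf, st))
  en <- vapply(pred, function(p) p$energy, 0)
  ipea <- vertical_ip_ea(en[["neutral"]], en[["cation"]], en[["anion"]])
  gi <- global_indexes(ipea$ip, ipea$ea)
  qtot <- lapply(pred, function(p) rowSums(p$charges))
  fk <- condensed_fukui(qtot$cation, qtot$neutral, qtot$anion)
  ph <- condensed_philicity(gi$omega, fk)
  structure(c(list(ip = ipea$ip, ea = ipea$ea), gi, fk, ph,
              list(state_energies = en,
                   state_charges = lapply(pred, function(p) p$charges),
                   conformer = conf)),
            class = "cdft_report")
}

#' @export
print.cdft_report <- function(x, ...) {
  cat(sprintf("<cdft_report> IP %.3f eV, EA %.3f eV | chi %.3f, eta %.3f, omega %.3f eV\n",
              x$ip, x$ea, x$chi, x$eta, x$omega))
  df <- data.frame(element = x$conformer$elements,
                   f_minus = round(x$f_minus, 4),
                   f_plus = round(x$f_plus, 4),
                   f_zero = round(x$f_zero, 4),
                   omega_minus = round(x$omega_minus, 4))
  print(utils::head(df, 12))
  if (nrow(df) > 12) cat("  ...\n")
  invisible(x)
}

#' Per-atom site descriptors for electrophilic aromatic substitution
#'
#' The descriptor set used to model EAS regioselectivity: the global
#' electrophilicity \eqn{\omega}, the electrophilic condensed philicity
#' \eqn{\omega^-_a} of the query atom, and the AIM latent vector of the query
#' atom taken from the forward pass of the molecule in its cation-radical
#' form.  Length d_aim + 2.
#'
#' @param model a trained `aimnet_nse` model (or list of models).
#' @param conf a [conformer()].
#' @param atom_index index of the query atom.
#' @param charge parent charge state (default 0).
#' @return Numeric vector of length `d_aim + 2` named
#'   `c("omega", "omega_minus_a", "aim1", ...)`.
#' @export
eas_site_features <- function(model, conf, atom_index, charge = 0L) {
  members <- if (inherits(model, "neq_model")) list(model) else model
  n <- length(conf$elements)
  atom_index <- as.integer(atom_index)
  if (atom_index < 1L || atom_index > n)
    stop("atom_index out of range 1..", n, call. = FALSE)
  rep_ <- cdft_report(members, conf, charge)
  st_cat <- spin_state_for(conf, as.integer(charge) + 1L)
  aim <- ensemble_predict(members, conf, st_cat)$aim[atom_index, ]
  stats::setNames(c(rep_$omega, rep_$omega_minus[atom_index], aim),
                  c("omega", "omega_minus_a", paste0("aim", seq_along(aim))))
}
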