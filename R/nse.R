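# Neural Spin-charge Equilibration (NSE).
#
# Given raw per-atom, per-spin-channel charge predictions q_tilde and
# strictly positive weight factors f, the residual between the requested
# molecular spin charge Q^s and the sum of the raw predictions is
# redistributed across atoms proportionally to f:
#
#   q_i^s = q_tilde_i^s + f_i^s / sum_j f_j^s * (Q^s - sum_j q_tilde_j^s)
#
# so the renormalized charges sum to Q^s by construction.  The weights f play
# the role of atomic Fukui functions: dq_i / dQ = f_i / sum(f).  The two spin
# channels are equilibrated independently against their own channel charges.

#' Equilibrate raw spin charges against requested molecular spin charges
#'
#' @param q_tilde N x 2 matrix (or length-N vector for a single channel) of
#'   raw per-atom charges.
#' @param f matrix/vector of the same shape as `q_tilde`; strictly positive
#'   weight factors.
#' @param channel_charges requested molecular spin charges: length-2 vector
#'   (Q_alpha, Q_beta), a [spin_state()], or a scalar when `q_tilde` has one
#'   column.
#' @return Matrix (or vector) of conserved charges with the same shape as
#'   `q_tilde`: each channel sums to its requested charge to machine
#'   precision, and channels whose raw sum already matches are returned
#'   unchanged.
#' @examples
#' nse_equilibrate(c(0.2, -0.1), c(1, 1), 0.3)  # -> 0.3, 0.0
#' @export
nse_equilibrate <- function(q_tilde, f, channel_charges) {
  vec_in <- is.null(dim(q_tilde))
  q_tilde <- as.matrix(q_tilde)
  f <- as.matrix(f)
  if (inherits(channel_charges, "spin_state"))
    channel_charges <- c(channel_charges$q_alpha, channel_charges$q_beta)
  if (!all(dim(q_tilde) == dim(f)))
    stop("q_tilde and f must have identical shapes", call. = FALSE)
  if (length(channel_charges) != ncol(q_tilde))
    stop("need one requested charge per spin channel", call. = FALSE)
  if (!all(is.finite(q_tilde)) || !all(is.finite(f)) ||
      !all(is.finite(channel_charges)))
    stop("non-finite input to NSE (upstream head bug?)", call. = FALSE)
  if (any(f <= 0))
    stop("all NSE weights f must be strictly positive (got min f = ",
         format(min(f)), "); the network head must apply a positivity ",
         "transform", call. = FALSE)
  q <- q_tilde
  for (s in seq_len(ncol(q_tilde))) {
    resid <- channel_charges[s] - sum(q_tilde[, s])
    if (resid != 0)
      q[, s] <- q_tilde[, s] + f[, s] / sum(f[, s]) * resid
  }
  if (vec_in) q <- drop(q)
  q
}
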