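# Model definition: iterative symmetry-function network with charge
# conditioning.
#
# One pass: featurize with the current AFVs -> shared interaction MLP ->
# AIM latent vector -> output heads (atomic energy; charges; NSE weights).
# For the charge-conditioned variant the raw charges are equilibrated against
# the requested molecular spin charges (nse_equilibrate) and the Update block
# folds the conserved charges and weights into the AFVs for the next pass.
# Weights of all blocks are shared across passes.  Variants:
#   ani        one-hot AFVs, per-element energy heads, single pass, no charges
#   aimnet     learnable AFVs, energy + raw charge heads, no conservation
#   aimnet_mt  multitask heads for the fixed state set {cation, neutral, anion}
#   aimnet_nse energy + (q_tilde, f) heads with spin-charge equilibration

# smooth non-saturating activation (SiLU / swish); its sigmoid factor is
# cached on the forward pass so the backward needs no transcendentals
.sigmoid <- function(x) 1 / (1 + exp(-x))
.silu <- function(x) x * .sigmoid(x)
.softplus <- function(x) {
  ax <- abs(x)
  (x + ax) / 2 + log1p(exp(-ax))
}
.F_MIN <- 1e-4  # floor added to softplus(f_raw); keeps NSE well-posed

#' Model configuration
#'
#' @param variant one of `"ani"`, `"aimnet"`, `"aimnet_mt"`, `"aimnet_nse"`.
#' @param elements element symbols the model is parametrized for.
#' @param d_afv length of the learnable atomic feature vectors (ignored for
#'   `ani`, which uses one-hot vectors of length `length(elements)`).
#' @param d_aim width of the shared AIM latent layer (default 144).
#' @param hidden_interaction integer vector of hidden widths of the shared
#'   interaction network (embedding -> ... -> AIM).
#' @param hidden_head integer vector of hidden widths of the output heads.
#' @param n_passes number of iterative passes t (default 3; forced to 1 for
#'   `ani`).
#' @param symfun a [symfun_params()].
#' @param seed integer seed recorded in the config and used by [init_model()].
#' @return Object of class `"model_config"`.
#' @export
model_config <- function(variant = c("aimnet_nse", "ani", "aimnet", "aimnet_mt"),
                         elements = c("H", "C", "N", "O"),
                         d_afv = 16L, d_aim = 144L,
                         hidden_interaction = 128L, hidden_head = 64L,
                         n_passes = 3L, symfun = symfun_params(),
                         seed = 1L) {
  variant <- match.arg(variant)
  elements <- as.character(elements)
  atomic_numbers(elements)
  if (variant == "ani") {
    d_afv <- length(elements)
    n_passes <- 1L
  }
  stopifnot(n_passes >= 1L, d_aim >= 1L, d_afv >= 1L,
            inherits(symfun, "symfun_params"))
  structure(list(variant = variant, elements = elements,
                 d_afv = as.integer(d_afv), d_aim = as.integer(d_aim),
                 hidden_interaction = as.integer(hidden_interaction),
                 hidden_head = as.integer(hidden_head),
                 n_passes = as.integer(n_passes), symfun = symfun,
                 states = c("cation", "neutral", "anion"),
                 seed = as.integer(seed)),
            class = "model_config")
}

# ---- small MLP helpers (shared by all blocks) -------------------------------

.mlp_init <- function(dims, act_last = FALSE) {
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L]) / sqrt(dims[l]),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b, act_last = act_last)
}

.mlp_forward <- function(mlp, X, keep = FALSE) {
  L <- length(mlp$W)
  ins <- if (keep) vector("list", L) else NULL
  Zs <- if (keep) vector("list", L) else NULL
  Ss <- if (keep) vector("list", L) else NULL
  for (l in seq_len(L)) {
    if (keep) ins[[l]] <- X
    Z <- X %*% mlp$W[[l]]
    Z <- Z + rep(mlp$b[[l]], each = nrow(Z))
    if (l < L || mlp$act_last) {
      S <- .sigmoid(Z)
      if (keep) { Zs[[l]] <- Z; Ss[[l]] <- S }
      X <- Z * S
    } else {
      if (keep) Zs[[l]] <- Z
      X <- Z
    }
  }
  list(out = X, ins = ins, Zs = Zs, Ss = Ss)
}

.mlp_backward <- function(mlp, fwd, g_out) {
  L <- length(mlp$W)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gZ <- if (l < L || mlp$act_last) {
      S <- fwd$Ss[[l]]
      g_out * (S * (1 + fwd$Zs[[l]] * (1 - S)))
    } else g_out
    gW[[l]] <- crossprod(fwd$ins[[l]], gZ)
    gb[[l]] <- colSums(gZ)
    g_out <- tcrossprod(gZ, mlp$W[[l]])
  }
  list(gW = gW, gb = gb, g_in = g_out)
}

.update_input_dim <- function(cfg) {
  switch(cfg$variant,
         aimnet_nse = cfg$d_afv + 4L,   # [A | q_alpha, q_beta, f_alpha, f_beta]
         aimnet     = cfg$d_afv + 2L,   # [A | q_tilde]
         aimnet_mt  = cfg$d_afv + 6L,   # [A | q(cation), q(neutral), q(anion)]
         ani        = NA_integer_)
}

#' Initialize a model with random weights
#'
#' Weights are drawn from scaled normal distributions (biases zero) with the
#' RNG seeded from the config, so the same config always yields the same
#' model.  Per-element self-energy offsets start at zero and are fitted
#' during training.
#'
#' @param cfg a [model_config()].
#' @return Object of class `"neq_model"` with fields `config`, `params`,
#'   `sae` (named per-element self-energies, eV).
#' @export
init_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  sz <- symfun_size(cfg$symfun)
  L_embed <- sz$embedding_length(cfg$d_afv)
  p <- list()
  if (cfg$variant == "ani") {
    p$afv <- diag(length(cfg$elements))  # fixed one-hot
  } else {
    p$afv <- matrix(stats::rnorm(length(cfg$elements) * cfg$d_afv, sd = 1),
                    length(cfg$elements), cfg$d_afv)
  }
  # the shared trunk sees the environment embedding and the atom's own AFV
  int_dims <- c(L_embed + cfg$d_afv, cfg$hidden_interaction, cfg$d_aim)
  head_e <- c(cfg$d_aim, cfg$hidden_head, 1L)
  if (cfg$variant == "ani") {
    # per-element heads act on the embedding directly; no shared trunk
    p$energy_heads <- lapply(cfg$elements, function(e)
      .mlp_init(c(L_embed, cfg$hidden_head, 1L)))
    names(p$energy_heads) <- cfg$elements
  } else {
    p$interaction <- .mlp_init(int_dims, act_last = TRUE)
    if (cfg$variant == "aimnet_mt") {
      p$energy_heads <- lapply(cfg$states, function(s) .mlp_init(head_e))
      names(p$energy_heads) <- cfg$states
      p$charge_heads <- lapply(cfg$states, function(s)
        .mlp_init(c(cfg$d_aim, cfg$hidden_head, 2L)))
      names(p$charge_heads) <- cfg$states
    } else {
      p$energy_head <- .mlp_init(head_e)
      n_out <- if (cfg$variant == "aimnet_nse") 4L else 2L
      p$charge_head <- .mlp_init(c(cfg$d_aim, cfg$hidden_head, n_out))
    }
    din <- .update_input_dim(cfg)
    p$update <- list(W = matrix(stats::rnorm(din * cfg$d_afv) / sqrt(din),
                                din, cfg$d_afv),
                     b = numeric(cfg$d_afv))
  }
  sae <- stats::setNames(numeric(length(cfg$elements)), cfg$elements)
  structure(list(config = cfg, params = p, sae = sae), class = "neq_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.neq_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<neq_model> variant %s: %d elements, d_afv %d, d_aim %d, t %d, %d parameters\n",
              cfg$variant, length(cfg$elements), cfg$d_afv, cfg$d_aim,
              cfg$n_passes, np))
  invisible(x)
}

# map element symbols to AFV-table rows
.elem_index <- function(cfg, elements) {
  idx <- match(elements, cfg$elements)
  if (anyNA(idx))
    stop("element(s) not covered by this model: ",
         paste(unique(elements[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}

#' Run the model on one conformer
#'
#' Runs `n_passes` iterative passes and returns the prediction for the
#' requested spin state.  For the `aimnet_nse` variant the returned per-atom
#' channel charges sum to the requested molecular spin charges by
#' construction, for arbitrary (including untrained) weights.
#'
#' @param model a [init_model()] (or trained) model of variant `aimnet_nse`
#'   or `aimnet`.
#' @param conf a [conformer()].
#' @param state a [spin_state()] (ignored for variant `aimnet`, which is not
#'   charge-conditioned).
#' @return Object of class `"model_prediction"`: `energy` (total energy, eV,
#'   final-pass atomic energies plus self-energy offsets), `charges`
#'   (N x 2), `aim` (N x d_aim), and `passes`, a per-pass list of
#'   diagnostics (`energy`, `charges`, `q_tilde`, `f`).
#' @export
forward <- function(model, conf, state) {
  stopifnot(inherits(model, "neq_model"))
  if (!model$config$variant %in% c("aimnet_nse", "aimnet"))
    stop("forward() supports the aimnet_nse / aimnet variants; see ",
         "ani_baseline_forward() and mt_forward()", call. = FALSE)
  if (model$config$variant == "aimnet_nse") stopifnot(inherits(state, "spin_state"))
  batch <- .single_batch(model, conf, state)
  out <- .nn_forward(model, batch)
  pred <- structure(list(energy = out$energy[1],
                         charges = out$charges,
                         aim = out$aim,
                         passes = out$passes),
                    class = "model_prediction")
  pred
}

#' @export
print.model_prediction <- function(x, ...) {
  cat(sprintf("<model_prediction> E = %.6f eV, sum q = %+.6f e (alpha %+.4f, beta %+.4f)\n",
              x$energy, sum(x$charges), sum(x$charges[, 1]), sum(x$charges[, 2])))
  invisible(x)
}

#' Energy of the per-element baseline model
#'
#' Single-pass baseline: one-hot AFVs and independent per-element energy
#' heads, \eqn{E = \sum_i F^{(Z_i)}(G_i)} plus self-energy offsets.  No
#' charge conditioning.
#'
#' @param model an `ani`-variant model.
#' @param conf a [conformer()].
#' @return Total energy, eV.
#' @export
ani_baseline_forward <- function(model, conf) {
  stopifnot(inherits(model, "neq_model"), model$config$variant == "ani")
  cfg <- model$config
  idx <- .elem_index(cfg, conf$elements)
  raw <- compute_symmetry_functions(conf, cfg$symfun)
  G <- contract_embedding(raw, model$params$afv[idx, , drop = FALSE])
  e_at <- numeric(length(idx))
  for (e in unique(conf$elements)) {
    rows <- which(conf$elements == e)
    e_at[rows] <- .mlp_forward(model$params$energy_heads[[e]],
                               G[rows, , drop = FALSE])$out
  }
  sum(e_at) + sum(model$sae[conf$elements])
}

#' Multitask forward: concurrent predictions for the fixed state set
#'
#' Runs the shared trunk once and evaluates the per-state heads
#' (cation, neutral, anion) from the same AIM layer.  Charge sums are not
#' constrained for this variant; they approach the state charges only through
#' training.
#'
#' @param model an `aimnet_mt`-variant model.
#' @param conf a [conformer()].
#' @return Named list over states; each entry has `energy` (eV) and
#'   `charges` (N x 2).
#' @export
mt_forward <- function(model, conf) {
  stopifnot(inherits(model, "neq_model"), model$config$variant == "aimnet_mt")
  batch <- .single_batch(model, conf, state = NULL)
  out <- .nn_forward(model, batch)
  stats::setNames(lapply(model$config$states, function(s)
    list(energy = out$state_energy[[s]][1], charges = out$state_charges[[s]])),
    model$config$states)
}

.single_batch <- function(model, conf, state) {
  cfg <- model$config
  raw <- compute_symmetry_functions(conf, cfg$symfun)
  ops <- contraction_ops(raw)
  n <- length(conf$elements)
  list(n_atoms = n, B = 1L,
       elem_idx = .elem_index(cfg, conf$elements),
       elements = conf$elements,
       mol = rep(1L, n),
       ops = list(ops),
       channel_q = if (!is.null(state))
         matrix(c(state$q_alpha, state$q_beta), 1L) else matrix(0, 1L, 2L),
       sae_sum = sum(model$sae[conf$elements]))
}
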