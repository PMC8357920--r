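# Training: size-grouped minibatches, weighted multi-target MSE over passes,
# Adam with a reduce-on-plateau schedule, k-fold splits and ensembling.

#' Loss configuration
#'
#' The training objective is a weighted multi-target MSE,
#' \deqn{L = \sum_t w_t [w_E \, MSE(E^t) + w_q \, MSE(q^t)]}
#' summed over the iterative passes included in `nse_pass_mask`.  For the
#' charge-conditioned (`aimnet_nse`) variant only the last two passes enter
#' the loss by default, because the first pass runs without information about
#' the total spin charge; for the other variants all passes contribute.
#' Energy MSE is per molecule (eV^2), charge MSE per atom-channel (e^2);
#' the default `w_charge = 100` balances the ~100x smaller natural scale of
#' the charges.
#'
#' @param w_energy weight of the energy MSE term.
#' @param w_charge weight of the charge MSE term.
#' @param pass_weights optional per-pass weights (recycled/validated against
#'   the model's `n_passes` at training time; default uniform 1).
#' @param nse_pass_mask optional logical vector marking which passes
#'   contribute to the loss.
#' @return Object of class `"loss_config"`.
#' @export
loss_config <- function(w_energy = 1, w_charge = 100,
                        pass_weights = NULL, nse_pass_mask = NULL) {
  stopifnot(w_energy >= 0, w_charge >= 0, w_energy + w_charge > 0)
  structure(list(w_energy = w_energy, w_charge = w_charge,
                 pass_weights = pass_weights, nse_pass_mask = nse_pass_mask),
            class = "loss_config")
}

.resolve_loss_cfg <- function(lcfg, cfg) {
  TT <- cfg$n_passes
  pw <- lcfg$pass_weights %||% rep(1, TT)
  if (length(pw) != TT) stop("pass_weights must have length n_passes",
                             call. = FALSE)
  if (any(pw < 0)) stop("pass weights must be >= 0", call. = FALSE)
  mask <- lcfg$nse_pass_mask %||% {
    if (cfg$variant == "aimnet_nse" && TT >= 2L)
      seq_len(TT) > TT - 2L  # last two passes
    else rep(TRUE, TT)
  }
  if (length(mask) != TT) stop("nse_pass_mask must have length n_passes",
                               call. = FALSE)
  if (!any(mask & pw > 0)) stop("loss must include at least one pass",
                                call. = FALSE)
  list(w_energy = lcfg$w_energy, w_charge = lcfg$w_charge,
       pass_weights = pw, pass_mask = as.logical(mask))
}

#' Compose homogeneous-size minibatches
#'
#' Every batch contains only molecules with the same atom count (no padding),
#' every record appears exactly once per epoch, and both the within-group
#' permutation and the batch order are drawn from `seed`.
#'
#' @param ds a [mol_dataset()].
#' @param batch_size maximum records per batch (the remainder of a group
#'   forms a smaller batch).
#' @param seed integer seed.
#' @return List of batch index descriptors: each a list with `group` (the
#'   atom-count key) and `idx` (record indices within that group).
#' @export
make_batches <- function(ds, batch_size, seed = 1L) {
  stopifnot(inherits(ds, "mol_dataset"))
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (n_records(ds) == 0L) stop("empty dataset", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  batches <- list()
  for (key in names(ds$groups)) {
    nb <- length(ds$groups[[key]]$energy)
    if (nb == 0L) next
    perm <- sample.int(nb)
    for (start in seq(1L, nb, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, nb)]
      batches[[length(batches) + 1L]] <- list(group = key, idx = idx)
    }
  }
  batches[sample.int(length(batches))]
}

# featurize the records of one batch descriptor into an engine batch.
# geo_cache avoids re-featurizing the shared geometry of a conformer's
# several charge states (records sharing the id prefix before "/q").
.build_engine_batch <- function(model, ds, bdesc, geo_cache) {
  cfg <- model$config
  g <- ds$groups[[bdesc$group]]
  N <- g$n_atoms
  B <- length(bdesc$idx)
  elem_idx <- integer(B * N)
  ops <- vector("list", B)
  channel_q <- matrix(0, B, 2)
  sae_sum <- numeric(B)
  energy <- numeric(B)
  charges <- matrix(0, B * N, 2)
  for (k in seq_len(B)) {
    r <- bdesc$idx[k]
    el <- g$elements[r, ]
    coords <- matrix(g$coords[r, , ], ncol = 3)
    rows <- (k - 1L) * N + seq_len(N)
    elem_idx[rows] <- .elem_index(cfg, el)
    key <- sub("/q[^/]*$", "", g$id[r])
    key <- if (nzchar(key)) paste0(bdesc$group, "|", key) else ""
    op <- if (nzchar(key)) geo_cache[[key]] else NULL
    if (is.null(op)) {
      conf <- conformer(el, coords)
      op <- contraction_ops(compute_symmetry_functions(conf, cfg$symfun))
      if (nzchar(key)) geo_cache[[key]] <- op
    }
    ops[[k]] <- op
    st <- spin_state(g$charge[r], g$multiplicity[r],
                     sum(atomic_numbers(el)) - g$charge[r])
    channel_q[k, ] <- c(st$q_alpha, st$q_beta)
    sae_sum[k] <- sum(model$sae[el])
    energy[k] <- g$energy[r]
    charges[rows, ] <- g$charges[r, , ]
  }
  list(n_atoms = N, B = B, elem_idx = elem_idx,
       mol = rep(seq_len(B), each = N), ops = ops,
       channel_q = channel_q, sae_sum = sae_sum,
       labels = list(energy = energy, charges = charges))
}

#' Per-pass weighted multi-target loss of a model on labelled data
#'
#' @param model a `neq_model` (variants `aimnet_nse` / `aimnet`).
#' @param samples list of [labeled_sample()] (or a [mol_dataset()]).
#' @param lcfg a [loss_config()].
#' @return List with `loss` (scalar) and `components` (final-pass energy and
#'   charge MSE), plus per-pass terms.
#' @export
model_loss <- function(model, samples, lcfg = loss_config()) {
  ds <- if (inherits(samples, "mol_dataset")) samples else mol_dataset(samples)
  if (n_records(ds) == 0L) stop("empty batch", call. = FALSE)
  rl <- .resolve_loss_cfg(lcfg, model$config)
  cache <- new.env(parent = emptyenv())
  tot <- 0; n <- 0; comp <- c(0, 0)
  for (key in names(ds$groups)) {
    nb <- length(ds$groups[[key]]$energy)
    eb <- .build_engine_batch(model, ds, list(group = key, idx = seq_len(nb)),
                              cache)
    r <- .nn_loss_grad(model, eb, eb$labels, rl, want_grads = FALSE)
    tot <- tot + r$loss * nb
    comp <- comp + c(r$components$energy_mse, r$components$charge_mse) * nb
    n <- n + nb
  }
  list(loss = tot / n,
       components = list(energy_mse = comp[1] / n, charge_mse = comp[2] / n))
}

# multitask batches: one entry per conformer geometry, labels carried for the
# fixed state set {cation (+1), neutral (0), anion (-1)}.  Records are matched
# by the id prefix before "/q"; conformers missing a state are dropped.
.build_mt_batches <- function(model, ds, batch_size, geo_cache) {
  cfg <- model$config
  samples <- dataset_samples(ds)
  if (!length(samples)) stop("empty dataset", call. = FALSE)
  key <- sub("/q[^/]*$", "", vapply(samples, function(s) s$conformer$id, ""))
  state_q <- c(cation = 1L, neutral = 0L, anion = -1L)
  batches <- list()
  for (n in unique(vapply(samples, function(s) length(s$conformer$elements), 1L))) {
    sel <- which(vapply(samples, function(s) length(s$conformer$elements), 1L) == n)
    confs <- list()
    for (k in unique(key[sel])) {
      recs <- samples[sel[key[sel] == k]]
      qs <- vapply(recs, function(s) s$spin_state$charge, 1L)
      if (!all(state_q %in% qs)) next
      confs[[length(confs) + 1L]] <-
        stats::setNames(lapply(state_q, function(q) recs[[match(q, qs)]]),
                        names(state_q))
    }
    if (!length(confs)) next
    for (start in seq(1L, length(confs), by = batch_size)) {
      chunk <- confs[start:min(start + batch_size - 1L, length(confs))]
      B <- length(chunk)
      elem_idx <- integer(B * n); ops <- vector("list", B)
      sae_sum <- numeric(B)
      st_e <- lapply(state_q, function(q) numeric(B))
      st_q <- lapply(state_q, function(q) matrix(0, B * n, 2))
      for (b in seq_len(B)) {
        neu <- chunk[[b]]$neutral
        rows <- (b - 1L) * n + seq_len(n)
        elem_idx[rows] <- .elem_index(cfg, neu$conformer$elements)
        ops[[b]] <- contraction_ops(
          compute_symmetry_functions(neu$conformer, cfg$symfun))
        sae_sum[b] <- sum(model$sae[neu$conformer$elements])
        for (s in names(state_q)) {
          st_e[[s]][b] <- chunk[[b]][[s]]$energy
          st_q[[s]][rows, ] <- chunk[[b]][[s]]$charges
        }
      }
      batches[[length(batches) + 1L]] <-
        list(n_atoms = n, B = B, elem_idx = elem_idx,
             mol = rep(seq_len(B), each = n), ops = ops,
             channel_q = matrix(0, B, 2), sae_sum = sae_sum,
             labels = list(state_energy = st_e, state_charges = st_q))
    }
  }
  if (!length(batches))
    stop("no conformer has all three charge states labelled", call. = FALSE)
  batches
}

# ---- self-energies ----------------------------------------------------------

#' Fit per-element self-energy offsets by linear regression
#'
#' Regresses the labelled total energies on the element composition counts
#' (no intercept).  The offsets are subtracted from the learning targets and
#' added back at inference, so the network learns size-intensive residuals.
#'
#' @param ds a [mol_dataset()].
#' @param elements element symbols to fit (others get offset 0).
#' @return Named numeric vector of self-energies, eV per atom.
#' @export
fit_self_energies <- function(ds, elements = supported_elements()) {
  counts <- NULL; energy <- numeric(0)
  for (g in ds$groups) {
    cm <- t(apply(g$elements, 1L, function(el)
      tabulate(match(el, elements), nbins = length(elements))))
    if (length(g$energy) == 1L) cm <- matrix(cm, 1L)
    counts <- rbind(counts, cm)
    energy <- c(energy, g$energy)
  }
  keep <- colSums(counts) > 0
  fit <- stats::lm.fit(counts[, keep, drop = FALSE], energy)
  sae <- stats::setNames(numeric(length(elements)), elements)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  sae[keep] <- cf
  sae
}

# ---- flat parameter views for the optimizer --------------------------------

.flat_params <- function(model) {
  p <- model$params; out <- list()
  if (model$config$variant != "ani") out$afv <- p$afv
  add_mlp <- function(out, prefix, mlp) {
    for (l in seq_along(mlp$W)) {
      out[[paste0(prefix, ".W", l)]] <- mlp$W[[l]]
      out[[paste0(prefix, ".b", l)]] <- mlp$b[[l]]
    }
    out
  }
  if (!is.null(p$interaction)) out <- add_mlp(out, "interaction", p$interaction)
  if (!is.null(p$energy_head)) out <- add_mlp(out, "energy_head", p$energy_head)
  if (!is.null(p$charge_head)) out <- add_mlp(out, "charge_head", p$charge_head)
  for (s in names(p$energy_heads %||% list()))
    out <- add_mlp(out, paste0("energy_heads.", s), p$energy_heads[[s]])
  for (s in names(p$charge_heads %||% list()))
    out <- add_mlp(out, paste0("charge_heads.", s), p$charge_heads[[s]])
  if (!is.null(p$update)) {
    out$update.W <- p$update$W
    out$update.b <- p$update$b
  }
  out
}

.set_flat_params <- function(model, flat) {
  p <- model$params
  if (!is.null(flat$afv)) p$afv <- flat$afv
  set_mlp <- function(mlp, prefix) {
    for (l in seq_along(mlp$W)) {
      mlp$W[[l]] <- flat[[paste0(prefix, ".W", l)]]
      mlp$b[[l]] <- flat[[paste0(prefix, ".b", l)]]
    }
    mlp
  }
  if (!is.null(p$interaction))
    p$interaction <- set_mlp(p$interaction, "interaction")
  if (!is.null(p$energy_head)) p$energy_head <- set_mlp(p$energy_head, "energy_head")
  if (!is.null(p$charge_head)) p$charge_head <- set_mlp(p$charge_head, "charge_head")
  for (s in names(p$energy_heads %||% list()))
    p$energy_heads[[s]] <- set_mlp(p$energy_heads[[s]], paste0("energy_heads.", s))
  for (s in names(p$charge_heads %||% list()))
    p$charge_heads[[s]] <- set_mlp(p$charge_heads[[s]], paste0("charge_heads.", s))
  if (!is.null(p$update)) {
    p$update$W <- flat$update.W
    p$update$b <- flat$update.b
  }
  model$params <- p
  model
}

.flat_grads <- function(g, model) {
  out <- list()
  if (model$config$variant != "ani") out$afv <- g$afv
  add_mlp <- function(out, prefix, mg) {
    for (l in seq_along(mg$gW)) {
      out[[paste0(prefix, ".W", l)]] <- mg$gW[[l]]
      out[[paste0(prefix, ".b", l)]] <- mg$gb[[l]]
    }
    out
  }
  if (!is.null(g$interaction)) out <- add_mlp(out, "interaction", g$interaction)
  if (!is.null(g$energy_head)) out <- add_mlp(out, "energy_head", g$energy_head)
  if (!is.null(g$charge_head)) out <- add_mlp(out, "charge_head", g$charge_head)
  for (s in names(g$energy_heads %||% list()))
    out <- add_mlp(out, paste0("energy_heads.", s), g$energy_heads[[s]])
  for (s in names(g$charge_heads %||% list()))
    out <- add_mlp(out, paste0("charge_heads.", s), g$charge_heads[[s]])
  if (!is.null(g$update)) {
    out$update.W <- g$update$W
    out$update.b <- g$update$b
  }
  out
}

# ---- training loop ----------------------------------------------------------

#' Train a model
#'
#' Minibatch Adam on the weighted multi-target MSE with a reduce-on-plateau
#' learning-rate schedule.  Per-element self-energies are fitted on the
#' training portion before optimization.  The run is fully reproducible from
#' `seed`; a non-finite loss aborts with a diagnostic.  Validation molecules
#' are held out by molecule identity (the id prefix before the first "/"),
#' so all charge states and conformers of a molecule land on the same side
#' of the split.
#'
#' @param model an initialized `neq_model` (variant `aimnet_nse` or
#'   `aimnet`).
#' @param ds a [mol_dataset()] of labelled samples.
#' @param lcfg a [loss_config()].
#' @param epochs maximum number of epochs.
#' @param batch_size records per minibatch.
#' @param lr initial Adam learning rate.
#' @param lr_factor,patience,min_lr reduce-on-plateau schedule: multiply the
#'   learning rate by `lr_factor` after `patience` epochs without validation
#'   improvement, never below `min_lr`.
#' @param clip_norm global L2 gradient-norm clipping threshold (stabilizes
#'   occasional large minibatch gradients; `Inf` disables).
#' @param val_fraction fraction of molecules held out for validation.
#' @param seed integer seed for the split, batch composition and shuffling.
#' @param verbose print per-epoch progress.
#' @return List with `model` (best-validation weights), `history`
#'   (data.frame of per-epoch losses and learning rates) and `val_ids`
#'   (molecule keys of the validation split).
#' @export
train_model <- function(model, ds, lcfg = loss_config(), epochs = 50L,
                        batch_size = 64L, lr = 1e-3, lr_factor = 0.5,
                        patience = 10L, min_lr = 1e-5, clip_norm = 5,
                        val_fraction = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "neq_model"), inherits(ds, "mol_dataset"))
  if (model$config$variant %in% c("ani"))
    stop("the trainer supports the charge-predicting variants", call. = FALSE)
  rl <- .resolve_loss_cfg(lcfg, model$config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  split <- .split_by_molecule(ds, val_fraction)
  model$sae <- fit_self_energies(split$train, model$config$elements)

  geo_cache <- new.env(parent = emptyenv())
  if (model$config$variant == "aimnet_mt") {
    tr_batches <- .build_mt_batches(model, split$train, batch_size, geo_cache)
    val_batches <- if (n_records(split$val) > 0)
      .build_mt_batches(model, split$val, batch_size, geo_cache) else list()
  } else {
    tr_desc <- make_batches(split$train, batch_size, seed = seed)
    tr_batches <- lapply(tr_desc, function(bd)
      .build_engine_batch(model, split$train, bd, geo_cache))
    val_batches <- if (n_records(split$val) > 0) {
      vd <- make_batches(split$val, batch_size, seed = seed)
      lapply(vd, function(bd)
        .build_engine_batch(model, split$val, bd, geo_cache))
    } else list()
  }

  # fixed per-feature embedding scaling, estimated once at the initial AFVs;
  # a constant diagonal layer that conditions the optimization without
  # changing the model class
  if (is.null(model$embed_inv_scale)) {
    ss <- 0; nr <- 0
    for (eb in tr_batches[seq_len(min(20L, length(tr_batches)))]) {
      A <- model$params$afv[eb$elem_idx, , drop = FALSE]
      X <- .embed_batch(eb, A)
      ss <- ss + colSums(X^2); nr <- nr + nrow(X)
    }
    rms <- sqrt(ss / nr)
    model$embed_inv_scale <- ifelse(rms > 1e-3, 1 / rms, 1)
  }

  flat <- .flat_params(model)
  m_ad <- lapply(flat, function(x) x * 0)
  v_ad <- lapply(flat, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps_ad <- 1e-8
  step <- 0L
  cur_lr <- lr
  best_val <- Inf; best_flat <- flat; plateau <- 0L
  hist <- list()

  eval_set <- function(batches) {
    if (!length(batches)) return(c(NA, NA, NA))
    tot <- 0; n <- 0; comp <- c(0, 0)
    for (eb in batches) {
      r <- .nn_loss_grad(model, eb, eb$labels, rl, want_grads = FALSE)
      tot <- tot + r$loss * eb$B; n <- n + eb$B
      comp <- comp + c(r$components$energy_mse, r$components$charge_mse) * eb$B
    }
    c(tot / n, comp / n)
  }

  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(tr_batches))
    ep_loss <- 0; nrec <- 0
    for (bi in ord) {
      eb <- tr_batches[[bi]]
      r <- .nn_loss_grad(model, eb, eb$labels, rl)
      if (!is.finite(r$loss))
        stop(sprintf("training diverged at epoch %d (loss = %g); reduce the learning rate",
                     ep, r$loss), call. = FALSE)
      ep_loss <- ep_loss + r$loss * eb$B; nrec <- nrec + eb$B
      gf <- .flat_grads(r$grads, model)
      if (is.finite(clip_norm)) {
        gn <- sqrt(sum(vapply(gf, function(g) sum(g * g), 0)))
        if (gn > clip_norm) gf <- lapply(gf, function(g) g * (clip_norm / gn))
      }
      step <- step + 1L
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      for (nm in names(flat)) {
        g <- gf[[nm]]
        m_ad[[nm]] <- b1 * m_ad[[nm]] + (1 - b1) * g
        v_ad[[nm]] <- b2 * v_ad[[nm]] + (1 - b2) * g * g
        flat[[nm]] <- flat[[nm]] -
          cur_lr * (m_ad[[nm]] / c1) / (sqrt(v_ad[[nm]] / c2) + eps_ad)
      }
      model <- .set_flat_params(model, flat)
    }
    vl <- eval_set(val_batches)
    mon <- if (is.finite(vl[1])) vl[1] else ep_loss / nrec
    if (mon < best_val - 1e-12) {
      best_val <- mon; best_flat <- flat; plateau <- 0L
    } else {
      plateau <- plateau + 1L
      if (plateau >= patience && cur_lr > min_lr) {
        cur_lr <- max(min_lr, cur_lr * lr_factor)
        plateau <- 0L
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, lr = cur_lr,
                             train_loss = ep_loss / nrec,
                             val_loss = vl[1], val_energy_mse = vl[2],
                             val_charge_mse = vl[3])
    if (verbose)
      message(sprintf("epoch %3d  lr %.2g  train %.5g  val %.5g (E %.4g eV2, q %.4g e2)",
                      ep, cur_lr, ep_loss / nrec, vl[1], vl[2], vl[3]))
  }
  model <- .set_flat_params(model, best_flat)
  list(model = model, history = do.call(rbind, hist),
       val_ids = split$val_ids)
}

.molecule_key <- function(ids) sub("/.*$", "", ids)

.split_by_molecule <- function(ds, val_fraction) {
  samples <- dataset_samples(ds)
  ids <- vapply(samples, function(s) s$conformer$id, "")
  keys <- .molecule_key(ids)
  uk <- unique(keys)
  n_val <- round(val_fraction * length(uk))
  val_keys <- if (n_val > 0) sample(uk, n_val) else character(0)
  in_val <- keys %in% val_keys
  list(train = mol_dataset(samples[!in_val]),
       val = mol_dataset(samples[in_val]),
       val_ids = val_keys)
}

#' Disjoint k-fold split of molecule keys
#'
#' @param ds a [mol_dataset()].
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return List of k character vectors of molecule keys; folds are disjoint
#'   and their union covers the dataset.
#' @export
kfold_split <- function(ds, k = 5L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  samples <- dataset_samples(ds)
  uk <- unique(.molecule_key(vapply(samples, function(s) s$conformer$id, "")))
  uk <- sample(uk)
  split(uk, rep_len(seq_len(k), length(uk)))
}

#' Ensemble prediction: arithmetic mean over member models
#'
#' Energies and charges are averaged over the members.  For charge-conserving
#' members the mean of conserved channel sums is itself conserved.
#'
#' @param members list of trained `neq_model` objects with identical element
#'   tables and variants.
#' @param conf a [conformer()].
#' @param state a [spin_state()].
#' @return A `"model_prediction"` with averaged energy and charges.
#' @export
ensemble_predict <- function(members, conf, state) {
  stopifnot(length(members) >= 1)
  el0 <- members[[1]]$config$elements
  for (mm in members)
    if (!identical(mm$config$elements, el0) ||
        !identical(mm$config$variant, members[[1]]$config$variant))
      stop("ensemble members must share the element table and variant",
           call. = FALSE)
  preds <- lapply(members, forward, conf = conf, state = state)
  en <- mean(vapply(preds, function(p) p$energy, 0))
  q <- Reduce(`+`, lapply(preds, function(p) p$charges)) / length(preds)
  aim <- Reduce(`+`, lapply(preds, function(p) p$aim)) / length(preds)
  structure(list(energy = en, charges = q, aim = aim, passes = NULL),
            class = "model_prediction")
}
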