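# Internal batched execution engine.
#
# A batch holds molecules with the same atom count N (padding-free).  Atom
# rows are stacked molecule-major: row (b - 1) * N + a.  The geometric part
# of the featurization (the contraction operators) is precomputed per
# conformer; each pass is then two small dense matrix products per molecule
# plus shared dense MLPs over all atom rows.  The backward pass is the exact
# analytic reverse of the forward, including back-propagation through the
# spin-charge equilibration and through the AFV update chain across passes
# (verified against finite differences in the test suite).

.embed_batch <- function(batch, A) {
  N <- batch$n_atoms
  nr <- batch$ops[[1]]$n_radial; na <- batch$ops[[1]]$n_angular
  d <- ncol(A)
  X <- matrix(0, batch$B * N, (nr + na) * d)
  for (b in seq_len(batch$B)) {
    rows <- (b - 1L) * N + seq_len(N)
    X[rows, ] <- .embed_from_ops(batch$ops[[b]], A[rows, , drop = FALSE])
  }
  X
}

.embed_batch_backward <- function(batch, gX) {
  N <- batch$n_atoms
  gA <- NULL
  for (b in seq_len(batch$B)) {
    rows <- (b - 1L) * N + seq_len(N)
    g <- .embed_backward(batch$ops[[b]], gX[rows, , drop = FALSE])
    if (is.null(gA)) gA <- matrix(0, batch$B * N, ncol(g))
    gA[rows, ] <- g
  }
  gA
}

# forward over one batch; keep = TRUE retains activations for the backward
.nn_forward <- function(model, batch, keep = FALSE) {
  cfg <- model$config; p <- model$params
  N <- batch$n_atoms; B <- batch$B; R <- N * B
  mol <- batch$mol
  TT <- cfg$n_passes
  A <- p$afv[batch$elem_idx, , drop = FALSE]
  passes <- vector("list", TT)
  cache <- if (keep) vector("list", TT) else NULL
  out <- list()
  inv_scale <- model$embed_inv_scale  # fixed per-feature embedding scaling
  for (t in seq_len(TT)) {
    X <- .embed_batch(batch, A)
    if (!is.null(inv_scale)) X <- X * rep(inv_scale, each = R)
    X <- cbind(X, A)  # interaction input: [environment embedding | own AFV]
    intf <- .mlp_forward(p$interaction, X, keep)
    AIM <- intf$out
    cc <- list(A = A, X = X, intf = intf)
    if (cfg$variant == "aimnet_mt") {
      st_e <- list(); st_q <- list(); st_fwd_e <- list(); st_fwd_q <- list()
      for (s in cfg$states) {
        ef <- .mlp_forward(p$energy_heads[[s]], AIM, keep)
        chf <- .mlp_forward(p$charge_heads[[s]], AIM, keep)
        st_e[[s]] <- unname(drop(rowsum(ef$out, mol))) + batch$sae_sum
        st_q[[s]] <- chf$out
        st_fwd_e[[s]] <- ef; st_fwd_q[[s]] <- chf
      }
      q_all <- do.call(cbind, unname(st_q))          # R x 6
      upd_in <- cbind(A, q_all)
      cc <- c(cc, list(st_fwd_e = st_fwd_e, st_fwd_q = st_fwd_q,
                       st_e = st_e, st_q = st_q, upd_in = upd_in))
      passes[[t]] <- list(state_energy = st_e, state_charges = st_q)
      if (t < TT)
        A <- upd_in %*% p$update$W + rep(p$update$b, each = R)
      out$state_energy <- st_e; out$state_charges <- st_q
    } else {
      ef <- .mlp_forward(p$energy_head, AIM, keep)
      e_at <- ef$out
      E_mol <- unname(drop(rowsum(e_at, mol))) + batch$sae_sum
      chf <- .mlp_forward(p$charge_head, AIM, keep)
      if (cfg$variant == "aimnet_nse") {
        qt <- chf$out[, 1:2, drop = FALSE]
        fraw <- chf$out[, 3:4, drop = FALSE]
        f <- .softplus(fraw) + .F_MIN
        F_mol <- rowsum(f, mol)                      # B x 2
        resid <- batch$channel_q - rowsum(qt, mol)   # B x 2
        w <- f / F_mol[mol, , drop = FALSE]
        q <- qt + w * resid[mol, , drop = FALSE]
      } else {
        qt <- chf$out; fraw <- NULL; f <- NULL; w <- NULL
        F_mol <- NULL; resid <- NULL
        q <- qt
      }
      cc <- c(cc, list(ef = ef, chf = chf, qt = qt, fraw = fraw, f = f,
                       w = w, F_mol = F_mol, resid = resid, q = q,
                       E_mol = E_mol))
      passes[[t]] <- list(energy = E_mol, charges = q, q_tilde = qt, f = f)
      if (t < TT) {
        upd_in <- if (cfg$variant == "aimnet_nse") cbind(A, q, f)
                  else cbind(A, qt)
        cc$upd_in <- upd_in
        A <- upd_in %*% p$update$W + rep(p$update$b, each = R)
      }
      out$energy <- E_mol; out$charges <- q
    }
    out$aim <- AIM
    if (keep) cache[[t]] <- cc
  }
  out$passes <- passes
  out$cache <- cache
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.acc_mlp <- function(acc, g) {
  if (is.null(acc)) return(list(gW = g$gW, gb = g$gb))
  list(gW = Map(`+`, acc$gW, g$gW), gb = Map(`+`, acc$gb, g$gb))
}

# fused loss + gradient over one batch.
# labels: energy (B), charges (R x 2)  [nse / aimnet]
#         state_energy / state_charges lists over states  [mt]
# lcfg: list(w_energy, w_charge, pass_weights, pass_mask)
.nn_loss_grad <- function(model, batch, labels, lcfg, want_grads = TRUE) {
  cfg <- model$config; p <- model$params
  N <- batch$n_atoms; B <- batch$B; R <- N * B
  mol <- batch$mol
  TT <- cfg$n_passes
  fw <- .nn_forward(model, batch, keep = want_grads)

  loss <- 0
  comp <- list(energy_mse = 0, charge_mse = 0)  # final-pass components
  pass_terms <- vector("list", TT)
  for (t in seq_len(TT)) {
    if (!lcfg$pass_mask[t]) next
    wt <- lcfg$pass_weights[t]
    if (cfg$variant == "aimnet_mt") {
      e_mse <- 0; q_mse <- 0
      for (s in cfg$states) {
        e_mse <- e_mse + mean((fw$passes[[t]]$state_energy[[s]] -
                                 labels$state_energy[[s]])^2)
        q_mse <- q_mse + mean((fw$passes[[t]]$state_charges[[s]] -
                                 labels$state_charges[[s]])^2)
      }
    } else {
      e_mse <- mean((fw$passes[[t]]$energy - labels$energy)^2)
      q_mse <- mean((fw$passes[[t]]$charges - labels$charges)^2)
    }
    pass_terms[[t]] <- c(energy_mse = e_mse, charge_mse = q_mse)
    loss <- loss + wt * (lcfg$w_energy * e_mse + lcfg$w_charge * q_mse)
    if (t == TT) comp <- list(energy_mse = e_mse, charge_mse = q_mse)
  }
  if (!want_grads)
    return(list(loss = loss, components = comp, pass_terms = pass_terms))

  # ---- backward ----
  g <- list(afv = array(0, dim(p$afv)), interaction = NULL,
            energy_head = NULL, charge_head = NULL,
            energy_heads = list(), charge_heads = list(),
            update = list(W = array(0, dim(p$update$W %||% matrix(0, 1, 1))),
                          b = numeric(length(p$update$b %||% 0))))
  has_update <- !is.null(p$update)
  gA_next <- NULL   # gradient wrt A^{t+1}
  for (t in rev(seq_len(TT))) {
    cc <- fw$cache[[t]]
    wt <- if (lcfg$pass_mask[t]) lcfg$pass_weights[t] else 0

    gA_local <- matrix(0, R, cfg$d_afv)
    if (cfg$variant == "aimnet_mt") {
      gq_all <- matrix(0, R, 6L)
      if (!is.null(gA_next)) {
        gupd_in <- tcrossprod(gA_next, p$update$W)
        g$update$W <- g$update$W + crossprod(cc$upd_in, gA_next)
        g$update$b <- g$update$b + colSums(gA_next)
        gA_local <- gupd_in[, seq_len(cfg$d_afv), drop = FALSE]
        gq_all <- gupd_in[, cfg$d_afv + seq_len(6L), drop = FALSE]
      }
      gAIM <- matrix(0, R, cfg$d_aim)
      for (si in seq_along(cfg$states)) {
        s <- cfg$states[si]
        gE <- if (wt > 0)
          2 * wt * lcfg$w_energy * (cc$st_e[[s]] - labels$state_energy[[s]]) / B
          else numeric(B)
        ge_at <- matrix(gE[mol], ncol = 1)
        be <- .mlp_backward(p$energy_heads[[s]], cc$st_fwd_e[[s]], ge_at)
        g$energy_heads[[s]] <- .acc_mlp(g$energy_heads[[s]], be)
        gq <- gq_all[, (si - 1L) * 2L + 1:2, drop = FALSE]
        if (wt > 0)
          gq <- gq + 2 * wt * lcfg$w_charge *
            (cc$st_q[[s]] - labels$state_charges[[s]]) / (R * 2)
        bq <- .mlp_backward(p$charge_heads[[s]], cc$st_fwd_q[[s]], gq)
        g$charge_heads[[s]] <- .acc_mlp(g$charge_heads[[s]], bq)
        gAIM <- gAIM + be$g_in + bq$g_in
      }
    } else {
      gq <- matrix(0, R, 2L)
      gf <- matrix(0, R, 2L)
      if (!is.null(gA_next)) {
        gupd_in <- tcrossprod(gA_next, p$update$W)
        g$update$W <- g$update$W + crossprod(cc$upd_in, gA_next)
        g$update$b <- g$update$b + colSums(gA_next)
        gA_local <- gupd_in[, seq_len(cfg$d_afv), drop = FALSE]
        gq <- gupd_in[, cfg$d_afv + 1:2, drop = FALSE]
        if (cfg$variant == "aimnet_nse")
          gf <- gupd_in[, cfg$d_afv + 3:4, drop = FALSE]
      }
      gE <- if (wt > 0)
        2 * wt * lcfg$w_energy * (cc$E_mol - labels$energy) / B
        else numeric(B)
      if (wt > 0)
        gq <- gq + 2 * wt * lcfg$w_charge * (cc$q - labels$charges) / (R * 2)

      if (cfg$variant == "aimnet_nse") {
        # backward through q = qt + w * resid (per molecule, per channel):
        #   d q_i / d qt_j = delta_ij - w_i ;  d q_i / d f_j = resid/F (delta_ij - w_i)
        S_mol <- rowsum(gq * cc$w, mol)                # B x 2
        gqt <- gq - S_mol[mol, , drop = FALSE]
        rF <- (cc$resid / cc$F_mol)[mol, , drop = FALSE]
        gf <- gf + rF * gqt
        gfraw <- gf * .sigmoid(cc$fraw)
        g_ch_out <- cbind(gqt, gfraw)
      } else {
        g_ch_out <- gq
      }
      ge_at <- matrix(gE[mol], ncol = 1)
      be <- .mlp_backward(p$energy_head, cc$ef, ge_at)
      g$energy_head <- .acc_mlp(g$energy_head, be)
      bq <- .mlp_backward(p$charge_head, cc$chf, g_ch_out)
      g$charge_head <- .acc_mlp(g$charge_head, bq)
      gAIM <- be$g_in + bq$g_in
    }
    bi <- .mlp_backward(p$interaction, cc$intf, gAIM)
    g$interaction <- .acc_mlp(g$interaction, bi)
    L_emb <- ncol(bi$g_in) - cfg$d_afv
    gX <- bi$g_in[, seq_len(L_emb), drop = FALSE]
    gA_self <- bi$g_in[, L_emb + seq_len(cfg$d_afv), drop = FALSE]
    if (!is.null(model$embed_inv_scale))
      gX <- gX * rep(model$embed_inv_scale, each = R)
    gA_embed <- .embed_batch_backward(batch, gX)
    gA_total <- gA_local + gA_embed + gA_self
    if (t > 1L) {
      gA_next <- gA_total
    } else if (cfg$variant != "ani") {
      acc <- rowsum(gA_total, batch$elem_idx)
      g$afv[as.integer(rownames(acc)), ] <-
        g$afv[as.integer(rownames(acc)), , drop = FALSE] + acc
    }
  }
  if (!has_update) g$update <- NULL
  list(loss = loss, components = comp, pass_terms = pass_terms, grads = g)
}
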