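# Shared fixtures: random conformers with a minimum separation, rigid
# motions, and small models.  Everything is generated in code at test time.

random_conformer <- function(n, elements = c("H", "C", "N", "O"),
                             min_sep = 0.9, spread = 1.6, id = "") {
  el <- sample(elements, n, replace = TRUE)
  coords <- matrix(0, n, 3)
  if (n > 1) {
    for (i in 2:n) {
      repeat {
        cand <- coords[sample.int(i - 1L, 1L), ] + stats::rnorm(3, sd = spread)
        d <- sqrt(rowSums((coords[1:(i - 1), , drop = FALSE] -
                             matrix(cand, i - 1, 3, byrow = TRUE))^2))
        if (min(d) > min_sep) { coords[i, ] <- cand; break }
      }
    }
  }
  conformer(el, coords, id = id)
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3))) *
    sample(c(-1, 1), 1)  # allow improper too; features are invariant to both
}

rigid_motion <- function(conf) {
  R <- random_rotation()
  t <- stats::rnorm(3, sd = 5)
  conformer(conf$elements, conf$coords %*% R +
              matrix(t, nrow(conf$coords), 3, byrow = TRUE), id = conf$id)
}

tiny_model <- function(variant = "aimnet_nse", elements = c("H", "C", "N", "O"),
                       n_passes = 3L, seed = 42L, d_afv = 6L, d_aim = 10L) {
  init_model(model_config(variant, elements, d_afv = d_afv, d_aim = d_aim,
                          hidden_interaction = 12L, hidden_head = 8L,
                          n_passes = n_passes, seed = seed))
}

# brute-force one-hot reference for the embedding: per-species radial sums
# and per-species-pair angular sums, accumulated with explicit loops.
brute_force_onehot_embedding <- function(conf, params, species) {
  n <- length(conf$elements)
  nr <- length(params$radial_centers)
  na <- length(params$ang_dist_centers) * length(params$angle_centers)
  ns <- length(species)
  fc <- function(r, rc) if (r < rc) 0.5 * (cos(pi * r / rc) + 1) else 0
  emb <- matrix(0, n, (nr + na) * ns)
  for (i in seq_len(n)) {
    rad_block <- matrix(0, nr, ns)   # basis x species
    ang_block <- matrix(0, na, ns)
    for (j in seq_len(n)) {
      if (j == i) next
      rij <- sqrt(sum((conf$coords[i, ] - conf$coords[j, ])^2))
      if (rij < params$r_cut) {
        sj <- match(conf$elements[j], species)
        g <- exp(-params$eta_r * (rij - params$radial_centers)^2) *
          fc(rij, params$r_cut)
        rad_block[, sj] <- rad_block[, sj] + g
      }
    }
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j >= k || j == i || k == i) next
      rij <- sqrt(sum((conf$coords[i, ] - conf$coords[j, ])^2))
      rik <- sqrt(sum((conf$coords[i, ] - conf$coords[k, ])^2))
      if (rij >= params$ang_cut || rik >= params$ang_cut) next
      vj <- conf$coords[j, ] - conf$coords[i, ]
      vk <- conf$coords[k, ] - conf$coords[i, ]
      cth <- max(-1, min(1, sum(vj * vk) / (rij * rik)))
      theta <- acos(cth)
      gd <- exp(-params$eta_a * ((rij + rik) / 2 - params$ang_dist_centers)^2)
      ga <- 2^(1 - params$zeta) *
        (1 + cos(theta - params$angle_centers))^params$zeta
      g <- as.vector(outer(gd, ga)) * fc(rij, params$ang_cut) *
        fc(rik, params$ang_cut)
      # the pair feature of one-hot AFVs is the species-count vector of {j,k}
      for (sp in c(match(conf$elements[j], species),
                   match(conf$elements[k], species)))
        ang_block[, sp] <- ang_block[, sp] + g
    }
    emb[i, ] <- c(as.vector(rad_block), as.vector(ang_block))
  }
  emb
}
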