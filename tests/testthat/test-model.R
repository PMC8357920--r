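test_that("untrained charge-conditioned models conserve spin charges by construction", {
  set.seed(12)
  m <- tiny_model(seed = 99L)
  for (rep in 1:6) {
    conf <- random_conformer(sample(2:8, 1))
    Q <- sample(-1:1, 1)
    st <- spin_state_for(conf, Q)
    p <- forward(m, conf, st)
    expect_lt(abs(sum(p$charges[, 1]) - st$q_alpha), 1e-9)
    expect_lt(abs(sum(p$charges[, 2]) - st$q_beta), 1e-9)
    # every pass is individually conserved
    for (pass in p$passes) {
      expect_lt(abs(sum(pass$charges[, 1]) - st$q_alpha), 1e-9)
      expect_lt(abs(sum(pass$charges[, 2]) - st$q_beta), 1e-9)
    }
  }
})

test_that("energy and charges are invariant under rigid motions", {
  set.seed(13)
  m <- tiny_model()
  conf <- random_conformer(6)
  st <- spin_state_for(conf, 1)
  p0 <- forward(m, conf, st)
  for (rep in 1:5) {
    p1 <- forward(m, rigid_motion(conf), st)
    expect_lt(abs(p1$energy - p0$energy), 1e-6)
    expect_lt(max(abs(p1$charges - p0$charges)), 1e-6)
  }
})

test_that("predictions are equivariant under atom permutation", {
  set.seed(14)
  m <- tiny_model()
  conf <- random_conformer(7)
  st <- spin_state_for(conf, -1)
  p0 <- forward(m, conf, st)
  perm <- sample(7)
  pconf <- conformer(conf$elements[perm], conf$coords[perm, ])
  p1 <- forward(m, pconf, st)
  expect_lt(abs(p1$energy - p0$energy), 1e-9)
  expect_lt(max(abs(p1$charges - p0$charges[perm, ])), 1e-9)
})

test_that("far-separated identical fragments have identical first-pass AIM vectors", {
  set.seed(15)
  m <- tiny_model(n_passes = 1L)
  frag <- random_conformer(4)
  shift <- 2 * m$config$symfun$r_cut + 3
  both <- conformer(c(frag$elements, frag$elements),
                    rbind(frag$coords,
                          frag$coords + matrix(c(shift, 0, 0), 4, 3,
                                               byrow = TRUE)))
  p <- forward(m, both, spin_state_for(both, 0))
  expect_lt(max(abs(p$aim[1:4, ] - p$aim[5:8, ])), 1e-9)
})

test_that("model outputs are deterministic for fixed weights and input", {
  m <- tiny_model()
  set.seed(16)
  conf <- random_conformer(5)
  st <- spin_state_for(conf, 0)
  p1 <- forward(m, conf, st)
  p2 <- forward(m, conf, st)
  expect_identical(p1$energy, p2$energy)
  expect_identical(p1$charges, p2$charges)
})

test_that("the per-element baseline gives exactly the self-energy for a lone atom", {
  m <- tiny_model("ani", elements = c("H", "C"))
  m$sae <- c(H = -13.6, C = -100)
  conf <- conformer("H", matrix(0, 1, 3))
  # zero-neighbour embedding, zero-bias heads: E is the offset exactly
  expect_identical(ani_baseline_forward(m, conf), -13.6)
})

test_that("the baseline energy is permutation-invariant and species-routed", {
  set.seed(17)
  m <- tiny_model("ani")
  conf <- random_conformer(6)
  e0 <- ani_baseline_forward(m, conf)
  perm <- sample(6)
  e1 <- ani_baseline_forward(m,
                             conformer(conf$elements[perm], conf$coords[perm, ]))
  expect_lt(abs(e1 - e0), 1e-9)
  # perturbing the head of an element absent from the molecule changes nothing
  absent <- setdiff(m$config$elements, conf$elements)
  if (length(absent)) {
    m2 <- m
    m2$params$energy_heads[[absent[1]]]$b[[1]][] <- 77
    expect_identical(ani_baseline_forward(m2, conf), e0)
  }
})

test_that("multitask heads are deterministic and separated per state", {
  set.seed(18)
  m <- tiny_model("aimnet_mt")
  conf <- random_conformer(5)
  o1 <- mt_forward(m, conf)
  o2 <- mt_forward(m, conf)
  expect_identical(o1, o2)
  expect_named(o1, c("cation", "neutral", "anion"))
  # perturbing only the cation energy head leaves the other states unchanged
  m2 <- m
  m2$params$energy_heads$cation$b[[2]][] <- 5
  o3 <- mt_forward(m2, conf)
  expect_false(identical(o3$cation$energy, o1$cation$energy))
  expect_identical(o3$neutral, o1$neutral)
  expect_identical(o3$anion, o1$anion)
})

test_that("analytic gradients match finite differences through all passes", {
  set.seed(19)
  for (variant in c("aimnet_nse", "aimnet_mt")) {
    cfg <- model_config(variant, c("H", "C", "O"), d_afv = 5, d_aim = 7,
                        hidden_interaction = 9, hidden_head = 6,
                        n_passes = 3, seed = 3)
    m <- init_model(cfg)
    ds <- generate_dataset(3, c(2, 3), params = surrogate_params(c("H", "C", "O")),
                           seed = 11)
    m$sae <- fit_self_energies(ds, cfg$elements)
    rl <- neqnet:::.resolve_loss_cfg(loss_config(), cfg)
    eb <- if (variant == "aimnet_mt") {
      neqnet:::.build_mt_batches(m, ds, 8, new.env())[[1]]
    } else {
      neqnet:::.build_engine_batch(m, ds, make_batches(ds, 8, seed = 1)[[1]],
                                   new.env())
    }
    r <- neqnet:::.nn_loss_grad(m, eb, eb$labels, rl)
    flat <- neqnet:::.flat_params(m)
    gf <- neqnet:::.flat_grads(r$grads, m)
    eps <- 1e-4
    for (nm in names(flat)) {
      ks <- sample(length(flat[[nm]]), min(3, length(flat[[nm]])))
      for (k in ks) {
        f2 <- flat
        f2[[nm]][k] <- f2[[nm]][k] + eps
        lp <- neqnet:::.nn_loss_grad(neqnet:::.set_flat_params(m, f2), eb,
                                     eb$labels, rl, want_grads = FALSE)$loss
        f2[[nm]][k] <- flat[[nm]][k] - eps
        lm <- neqnet:::.nn_loss_grad(neqnet:::.set_flat_params(m, f2), eb,
                                     eb$labels, rl, want_grads = FALSE)$loss
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - gf[[nm]][k]) /
                    max(1e-4, abs(num), abs(gf[[nm]][k])), 5e-3)
      }
    }
  }
})

test_that("one-hot embedding equivalence propagates through the baseline head", {
  set.seed(20)
  species <- c("H", "C", "N", "O")
  p <- symfun_params(radial_centers = 0.8 + seq_len(4) * (5.2 - 0.8) / 4,
                     ang_dist_centers = 0.8 + seq_len(2) * (3.5 - 0.8) / 2,
                     angle_centers = seq(0, pi, length.out = 2))
  cfg <- model_config("ani", species, hidden_interaction = 8,
                      hidden_head = 6, symfun = p, seed = 8)
  m <- init_model(cfg)
  conf <- random_conformer(5)
  ref <- brute_force_onehot_embedding(conf, p, species)
  e_at <- numeric(5)
  for (i in seq_len(5)) {
    head <- m$params$energy_heads[[conf$elements[i]]]
    e_at[i] <- neqnet:::.mlp_forward(head, ref[i, , drop = FALSE])$out
  }
  expect_equal(ani_baseline_forward(m, conf),
               sum(e_at) + sum(m$sae[conf$elements]), tolerance = 1e-10)
})

test_that("checkpoints round-trip weights, config and self-energies", {
  set.seed(22)
  m <- tiny_model()
  m$sae <- c(H = -13.6, C = -100, N = -130, O = -160)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(neqnet:::.flat_params(m2), neqnet:::.flat_params(m))
  expect_identical(m2$sae, m$sae)
  conf <- random_conformer(4)
  st <- spin_state_for(conf, 0)
  expect_identical(forward(m2, conf, st)$energy, forward(m, conf, st)$energy)
})

test_that("multitask charge sums approach the state charges only through training", {
  set.seed(23)
  ds <- generate_dataset(100, c(2, 4), seed = 91)
  cfg <- model_config("aimnet_mt", c("H", "C", "N", "O"), d_afv = 8L,
                      d_aim = 32L, hidden_interaction = 48L,
                      hidden_head = 24L, n_passes = 3L, seed = 6L)
  m0 <- init_model(cfg)
  m0$sae <- fit_self_energies(ds, cfg$elements)
  fit <- train_model(m0, ds, epochs = 220L, batch_size = 16L, seed = 3L,
                     patience = 12L, val_fraction = 0)
  state_q <- c(cation = 1, neutral = 0, anion = -1)
  dev0 <- c(); dev1 <- c()
  samples <- dataset_samples(ds)
  neutrals <- samples[vapply(samples, function(s) s$spin_state$charge, 1L) == 0L]
  for (s in neutrals[seq(1, length(neutrals), by = 2)]) {
    o0 <- mt_forward(m0, s$conformer)
    o1 <- mt_forward(fit$model, s$conformer)
    for (st in names(state_q)) {
      dev0 <- c(dev0, abs(sum(o0[[st]]$charges) - state_q[st]))
      dev1 <- c(dev1, abs(sum(o1[[st]]$charges) - state_q[st]))
    }
  }
  # untrained sums are far off; trained sums are near-integral
  expect_gt(median(dev0), 0.05)
  expect_lt(median(dev1), 0.05)
})
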