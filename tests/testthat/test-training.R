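test_that("minibatches are homogeneous in size and conserve records", {
  ds <- generate_dataset(10, c(2, 4), seed = 8)
  bd <- make_batches(ds, 4, seed = 1)
  sizes_per_batch <- vapply(bd, function(b) b$group, "")
  counts <- integer(0)
  for (b in bd) {
    expect_true(all(b$idx >= 1 &
                      b$idx <= length(ds$groups[[b$group]]$energy)))
    counts <- c(counts, length(b$idx))
  }
  expect_identical(sum(counts), n_records(ds))
  # each record appears exactly once
  seen <- lapply(names(ds$groups), function(k)
    sort(unlist(lapply(bd[sizes_per_batch == k], `[[`, "idx"))))
  for (i in seq_along(seen))
    expect_identical(seen[[i]],
                     seq_along(ds$groups[[names(ds$groups)[i]]]$energy))
})

test_that("batch composition is deterministic in the seed and handles remainders", {
  ds <- generate_dataset(6, c(3, 3), n_conformers = 2, seed = 4)
  b1 <- make_batches(ds, 4, seed = 7)
  b2 <- make_batches(ds, 4, seed = 7)
  expect_identical(b1, b2)
  b3 <- make_batches(ds, 4, seed = 8)
  expect_false(identical(b1, b3))
  # 6 same-size records, batch 4 -> batches of 4 and 2
  one_group <- mol_dataset(dataset_samples(ds)[1:6])
  sizes <- sort(vapply(make_batches(one_group, 4, seed = 1),
                       function(b) length(b$idx), 1L))
  expect_identical(sizes, sort(c(2L, 4L)))
  expect_error(make_batches(ds, 0, seed = 1), "batch_size")
  expect_error(make_batches(mol_dataset(list()), 4, seed = 1), "empty")
})

test_that("the loss is zero for perfect predictions and linear in its weights", {
  set.seed(30)
  m <- tiny_model()
  ds <- generate_dataset(3, c(2, 3), seed = 2)
  # perfect predictions: score the surrogate labels against themselves by
  # constructing the loss by hand from model predictions
  samples <- dataset_samples(ds)[1:2]
  preds <- lapply(samples, function(s) forward(m, s$conformer, s$spin_state))
  # hand-computed final-pass MSEs on this 2-sample fixture
  e_mse <- mean((vapply(preds, `[[`, 0, "energy") -
                   vapply(samples, `[[`, 0, "energy"))^2)
  q_mse <- mean(c(vapply(seq_along(samples), function(i)
    (preds[[i]]$charges - samples[[i]]$charges)^2, preds[[1]]$charges * 0)))
  got <- model_loss(m, samples, loss_config(w_energy = 1, w_charge = 0,
                                            pass_weights = c(0, 0, 1)))
  expect_equal(got$loss, e_mse, tolerance = 1e-10)
  expect_equal(got$components$energy_mse, e_mse, tolerance = 1e-10)
  got_q <- model_loss(m, samples, loss_config(w_energy = 0, w_charge = 1,
                                              pass_weights = c(0, 0, 1)))
  expect_equal(got_q$loss, q_mse, tolerance = 1e-10)
  # labels equal to the model's own final-pass predictions give zero loss
  perfect <- lapply(seq_along(samples), function(i)
    labeled_sample(samples[[i]]$conformer, samples[[i]]$spin_state,
                   preds[[i]]$energy, preds[[i]]$charges))
  got0 <- model_loss(m, perfect, loss_config(pass_weights = c(0, 0, 1)))
  expect_equal(got0$loss, 0, tolerance = 1e-12)
  # doubling all pass weights doubles the loss
  l1 <- model_loss(m, samples, loss_config(pass_weights = c(1, 1, 1),
                                           nse_pass_mask = rep(TRUE, 3)))
  l2 <- model_loss(m, samples, loss_config(pass_weights = c(2, 2, 2),
                                           nse_pass_mask = rep(TRUE, 3)))
  expect_equal(l2$loss, 2 * l1$loss, tolerance = 1e-12)
})

test_that("training descends and is reproducible from the seed", {
  ds <- generate_dataset(30, c(2, 4), seed = 3)
  m <- tiny_model(seed = 5L)
  f1 <- train_model(m, ds, epochs = 6, batch_size = 16, seed = 2,
                    val_fraction = 0.15)
  expect_lt(tail(f1$history$train_loss, 1), f1$history$train_loss[1])
  f2 <- train_model(m, ds, epochs = 6, batch_size = 16, seed = 2,
                    val_fraction = 0.15)
  expect_identical(f1$history, f2$history)
  expect_identical(neqnet:::.flat_params(f1$model),
                   neqnet:::.flat_params(f2$model))
  # history is monotone in the learning-rate schedule sense
  expect_true(all(diff(f1$history$lr) <= 0))
})

test_that("training aborts with a diagnostic once the loss turns non-finite", {
  ds <- generate_dataset(10, c(2, 3), seed = 3)
  m <- tiny_model(seed = 5L)
  m$params$interaction$W[[1]][1, 1] <- NaN
  expect_error(train_model(m, ds, epochs = 3, batch_size = 8, seed = 1),
               "diverged")
})

test_that("validation split separates molecules, not records", {
  ds <- generate_dataset(20, c(2, 3), seed = 6)
  split <- local({
    set.seed(1)
    neqnet:::.split_by_molecule(ds, 0.25)
  })
  train_keys <- unique(sub("/.*$", "",
                           unlist(lapply(dataset_samples(split$train),
                                         function(s) s$conformer$id))))
  expect_length(intersect(train_keys, split$val_ids), 0)
  expect_identical(n_records(split$train) + n_records(split$val),
                   n_records(ds))
})

test_that("k-fold splits are disjoint and cover the dataset", {
  ds <- generate_dataset(23, c(2, 3), seed = 9)
  folds <- kfold_split(ds, k = 5, seed = 3)
  expect_length(folds, 5)
  all_keys <- unname(unlist(folds))
  expect_identical(sort(all_keys),
                   sort(unique(sub("/.*$", "",
                                   unlist(lapply(dataset_samples(ds),
                                                 function(s) s$conformer$id))))))
  expect_identical(anyDuplicated(all_keys), 0L)
})

test_that("ensembling averages members and cannot be worse than their mean MSE", {
  set.seed(33)
  members <- lapply(1:3, function(k) tiny_model(seed = 100L + k))
  conf <- random_conformer(5)
  st <- spin_state_for(conf, -1)
  preds <- lapply(members, forward, conf = conf, state = st)
  ens <- ensemble_predict(members, conf, st)
  expect_equal(ens$energy, mean(vapply(preds, `[[`, 0, "energy")),
               tolerance = 1e-14)
  expect_equal(ens$charges,
               (preds[[1]]$charges + preds[[2]]$charges + preds[[3]]$charges) / 3,
               tolerance = 1e-14)
  # conservation survives averaging
  expect_lt(abs(sum(ens$charges) - st$charge), 1e-9)
  # single member: identity
  solo <- ensemble_predict(members[1], conf, st)
  expect_identical(solo$energy, preds[[1]]$energy)
  # Jensen: ensemble squared error <= mean member squared error, per sample
  ds <- generate_dataset(6, c(2, 4), seed = 44)
  for (s in dataset_samples(ds)[1:6]) {
    es <- vapply(members, function(m)
      forward(m, s$conformer, s$spin_state)$energy, 0)
    expect_lte((mean(es) - s$energy)^2, mean((es - s$energy)^2) + 1e-12)
  }
  # mismatched element tables are rejected
  bad <- tiny_model(elements = c("H", "C"))
  expect_error(ensemble_predict(c(members, list(bad)), conf, st),
               "element table")
})

test_that("self-energy regression recovers per-element offsets", {
  # build labels that are exactly composition-linear
  set.seed(35)
  sae_true <- c(H = -13.6, C = -100, N = -130, O = -160)
  samples <- lapply(1:12, function(i) {
    conf <- random_conformer(sample(2:6, 1))
    st <- spin_state_for(conf, 0, multiplicity = NULL)
    labeled_sample(conf, st, sum(sae_true[conf$elements]),
                   matrix(0, length(conf$elements), 2))
  })
  sae <- fit_self_energies(mol_dataset(samples), names(sae_true))
  present <- unique(unlist(lapply(samples, function(s) s$conformer$elements)))
  expect_equal(sae[present], sae_true[present], tolerance = 1e-8)
})
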