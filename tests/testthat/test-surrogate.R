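test_that("a neutral homonuclear diatomic carries exactly zero charges", {
  conf <- conformer(c("O", "O"), rbind(c(0, 0, 0), c(1.21, 0, 0)))
  sol <- surrogate_solve(conf, spin_state_for(conf, 0))
  expect_equal(sol$charges, matrix(0, 2, 2), tolerance = 1e-12)
})

test_that("surrogate charges conserve the channel charges exactly", {
  set.seed(50)
  for (rep in 1:10) {
    conf <- random_conformer(sample(2:8, 1))
    Q <- sample(-1:1, 1)
    st <- spin_state_for(conf, Q)
    sol <- surrogate_solve(conf, st)
    expect_lt(abs(sum(sol$charges[, 1]) - st$q_alpha), 1e-10)
    expect_lt(abs(sum(sol$charges[, 2]) - st$q_beta), 1e-10)
  }
})

test_that("the two-atom solve matches the hand-derived KKT closed form", {
  p <- surrogate_params()
  conf <- conformer(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
  st <- spin_state_for(conf, 0)  # closed shell: no spin shift
  sol <- surrogate_solve(conf, st, p)
  # closed form: minimize b1 q1 + b2 q2 + 1/2 eta1 q1^2 + 1/2 eta2 q2^2
  #              + J q1 q2  s.t.  q1 + q2 = Qs
  chi <- neqnet:::.sur_lookup(p, conf$elements, "chi")
  eta <- neqnet:::.sur_lookup(p, conf$elements, "eta")
  gamma <- 4 * p$coulomb_scale / (eta[1] + eta[2])
  J <- p$coulomb_scale * exp(-1.2 / p$screening_length) /
    (1.2^3 + gamma^3)^(1 / 3)
  for (s in 1:2) {
    Qs <- if (s == 1) st$q_alpha else st$q_beta
    q1 <- ((eta[2] - J) * Qs + chi[2] - chi[1]) / (eta[1] + eta[2] - 2 * J)
    expect_lt(abs(sol$charges[1, s] - q1), 1e-10)
    expect_lt(abs(sol$charges[2, s] - (Qs - q1)), 1e-10)
  }
  # charged doublet: spin shift enters with opposite signs per channel
  st1 <- spin_state_for(conf, 1)
  sol1 <- surrogate_solve(conf, st1, p)
  sgn <- c(1, -1)
  shift <- neqnet:::.sur_lookup(p, conf$elements, "spin_shift")
  for (s in 1:2) {
    b <- chi + sgn[s] * shift
    Qs <- if (s == 1) st1$q_alpha else st1$q_beta
    q1 <- ((eta[2] - J) * Qs + b[2] - b[1]) / (eta[1] + eta[2] - 2 * J)
    expect_lt(abs(sol1$charges[1, s] - q1), 1e-10)
  }
})

test_that("surrogate energy is smooth in the coordinates", {
  set.seed(51)
  conf <- random_conformer(4, min_sep = 1.1)
  st <- spin_state_for(conf, 0)
  p <- surrogate_params()
  en <- function(x) {
    surrogate_solve(conformer(conf$elements, matrix(x, ncol = 3)), st,
                    p)$energy
  }
  x0 <- as.vector(conf$coords)
  # central finite differences converge as the step shrinks (Richardson)
  k <- sample(length(x0), 3)
  for (kk in k) {
    g <- vapply(c(1e-3, 1e-4), function(h) {
      xp <- x0; xp[kk] <- xp[kk] + h
      xm <- x0; xm[kk] <- xm[kk] - h
      (en(xp) - en(xm)) / (2 * h)
    }, 0)
    expect_lt(abs(g[1] - g[2]), 1e-3 * max(1, abs(g[2])))
  }
})

test_that("surrogate c-DFT reports are normalized and symmetric for symmetric molecules", {
  conf <- conformer(c("O", "O"), rbind(c(0, 0, 0), c(1.21, 0, 0)))
  rep_ <- surrogate_cdft(conf)
  expect_equal(sum(rep_$f_minus), 1, tolerance = 1e-10)
  expect_equal(sum(rep_$f_plus), 1, tolerance = 1e-10)
  expect_equal(rep_$f_minus[1], rep_$f_minus[2], tolerance = 1e-10)
  expect_equal(rep_$omega_zero[1], rep_$omega_zero[2], tolerance = 1e-10)
})

test_that("shifting every electronegativity by delta shifts molecular chi by delta", {
  set.seed(52)
  conf <- random_conformer(5, min_sep = 1.1)
  p0 <- surrogate_params()
  chi0 <- surrogate_cdft(conf, p0)$chi
  delta <- 0.7
  p1 <- p0
  p1$full_table$chi <- p1$full_table$chi + delta
  rep1 <- surrogate_cdft(conf, p1)
  expect_equal(rep1$chi, chi0 + delta, tolerance = 1e-8)
  # charges are unchanged by a uniform potential shift
  st <- spin_state_for(conf, 0)
  expect_equal(surrogate_solve(conf, st, p1)$charges,
               surrogate_solve(conf, st, p0)$charges, tolerance = 1e-10)
})

test_that("dataset generation is deterministic and follows the state scheme", {
  d1 <- generate_dataset(4, c(2, 4), seed = 77)
  d2 <- generate_dataset(4, c(2, 4), seed = 77)
  expect_identical(d1, d2)
  d3 <- generate_dataset(4, c(2, 4), seed = 78)
  expect_false(identical(d1, d3))
  samples <- dataset_samples(d1)
  # neutral parents: exactly three labelled states per conformer
  key <- sub("/q[^/]*$", "", vapply(samples, function(s) s$conformer$id, ""))
  for (k in unique(key)) {
    qs <- sort(vapply(samples[key == k], function(s) s$spin_state$charge, 1L))
    expect_identical(qs, c(-1L, 0L, 1L))
  }
  # anion parents: two states
  da <- generate_dataset(3, c(2, 3), parent_charge = -1, seed = 5)
  qs <- sort(unique(vapply(dataset_samples(da),
                           function(s) s$spin_state$charge, 1L)))
  expect_identical(qs, c(-1L, 0L))
})

test_that("generated labels satisfy the charge-sum invariant exactly", {
  ds <- generate_dataset(5, c(2, 5), seed = 13)
  for (s in dataset_samples(ds)) {
    st <- s$spin_state
    expect_lt(abs(sum(s$charges[, 1]) - st$q_alpha), 1e-10)
    expect_lt(abs(sum(s$charges[, 2]) - st$q_beta), 1e-10)
    # noisy labels still match the exact solve closely
    exact <- surrogate_solve(s$conformer, st)
    expect_lt(max(abs(s$charges - exact$charges)), 0.05)
    expect_lt(abs(s$energy - exact$energy), 0.1)
  }
})

test_that("element subsets are validated", {
  expect_error(surrogate_params(elements = c("H", "Xe")), "unsupported")
  expect_error(generate_dataset(2, c(2, 3),
                                params = surrogate_params("H")),
               "heavy element")
})
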