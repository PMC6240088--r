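test_that("fitted specialisation maps to clipped, product-form posteriors", {
  n <- 400
  src <- constant_sources(1, 0, n)
  src$states[, 2] <- rep(c(0L, 1L), n / 2)

  # no specialisation at all: flat beliefs
  flat <- empirical_posterior(matrix(0, n, 2), src)
  expect_true(all(flat$marginals == 0.5))
  expect_true(all(abs(flat$joint - 0.25) < 1e-12))

  # ramping curves: late full specialisation maps near the clip ceiling
  curves <- cbind(seq(0, 1, length.out = n), seq(0, 1, length.out = n))
  post <- empirical_posterior(curves, src, clip_eps = 1e-3)
  expect_true(all(post$joint >= 0 & post$joint <= 1))
  expect_equal(rowSums(post$joint), rep(1, n), tolerance = 1e-10)
  expect_true(all(post$marginals >= 1e-3 & post$marginals <= 1 - 1e-3))
  # source 1 always present: marginal rises towards 1 and ends at the anchor
  expect_gte(post$marginals[n, 1], 0.99)
  expect_lt(post$marginals[1, 1], 0.55)
  # epochs where source 2 is absent push its marginal below 1/2
  late_absent <- which(src$states[, 2] == 0 & seq_len(n) > n / 2)
  expect_true(all(post$marginals[late_absent, 2] < 0.5))

  # mean-field product in the joint order (00, 01, 10, 11)
  j <- vfemea:::joint_from_marginals(0.9, 0.2)
  expect_equal(j, c(0.08, 0.02, 0.72, 0.18), tolerance = 1e-12,
               ignore_attr = TRUE)
  m <- post$marginals[n %/% 2, ]
  expect_equal(post$joint[n %/% 2, ],
               vfemea:::joint_from_marginals(m[1], m[2]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # constant non-zero curve carries no learning signal
  expect_error(empirical_posterior(cbind(rep(1, n), rep(0, n)), src),
               "degenerate")
})

test_that("learning-curve matching is monotone and inverts known warps", {
  n <- 1024
  tt <- seq(0, 1, length.out = n)
  emp <- 1 / (1 + exp(-(tt - 0.5) / 0.08))

  # identical curves: essentially the identity mapping
  self <- suppressWarnings(match_learning_curves(emp, emp, n_select = 128))
  expect_equal(self$sim_epochs, self$empirical_epochs, tolerance = 2)
  expect_length(self$sim_epochs, 128)

  # simulated curve a 2x time-compressed copy: mapped index = empirical / 2
  sim <- emp[seq(2, n, by = 2)]
  comp <- suppressWarnings(match_learning_curves(emp, sim, n_select = 128))
  active <- emp[comp$empirical_epochs] > 0.02 & emp[comp$empirical_epochs] < 0.98
  expected_idx <- comp$empirical_epochs / 2
  expect_true(all(abs(comp$sim_epochs[active] - expected_idx[active]) <= 1.5))

  # monotone on rough random curves
  set.seed(5)
  for (r in 1:10) {
    e <- abs(stats::filter(rnorm(512), rep(1, 20), circular = TRUE)) * tt[1:512]
    s <- abs(stats::filter(rnorm(256), rep(1, 20), circular = TRUE))
    m <- suppressWarnings(match_learning_curves(e, s, n_select = 64))
    expect_true(all(diff(m$sim_epochs) >= 0))
    expect_true(all(diff(m$empirical_epochs) >= 0))
  }

  expect_error(match_learning_curves(rep(1, 10), emp), "non-constant")
})

test_that("empirical free energy matches the agent's own state-bound terms", {
  ex <- make_experiment(seed = 51, n_sessions = 1, epochs_per_session = 128)
  run <- run_training(ex$stimuli, n_epochs = 128, keep_counts = TRUE)

  # feed the agent's own posteriors back as the 'empirical' beliefs with an
  # identity epoch mapping: F must reproduce inaccuracy + state complexity
  sel <- seq(2, 128, by = 2)
  mapping <- structure(list(empirical_epochs = sel, sim_epochs = sel,
                            coefficients = c(offset = 0, scale = 1),
                            clamped = FALSE),
                       class = "epoch_mapping")
  post <- structure(list(marginals = run$marginals, joint = run$posterior,
                         anchors = c(1, 1), clip_eps = 1e-3),
                    class = "empirical_posterior")
  fe <- empirical_free_energy(ex$stimuli, post, mapping, run)
  agent_state_f <- run$free_energy$inaccuracy[sel] +
    run$free_energy$state_complexity[sel]
  expect_equal(fe$F, agent_state_f, tolerance = 1e-10)
  # decomposition identity at every epoch
  expect_equal(fe$F, -fe$accuracy + fe$complexity, tolerance = 1e-10)
})

test_that("smoothing yields a valid-region moving average and the 3-nat scale", {
  rec <- data.frame(accuracy = rep(-2, 50), complexity = rep(0.5, 50),
                    F = rep(2.5, 50))
  pl <- smooth_and_plane(rec, window = 32)
  expect_equal(nrow(pl), 19)
  expect_true(all(abs(pl$F - 2.5) < 1e-12))

  rnd <- data.frame(accuracy = rnorm(40), complexity = rnorm(40),
                    F = rnorm(40))
  ident <- smooth_and_plane(rnd, window = 1)
  expect_equal(ident$F, rnd$F)

  expect_equal(attr(pl, "odds_per_3nats"), exp(3))
  expect_equal(unname(attr(pl, "f_reference")["minus_3nats"]), 2.5 - 3)
  expect_error(smooth_and_plane(rnd, window = 41), "window")
})

test_that("closed-loop free energy falls while surrogate sources stay flat", {
  # one full synthetic loop at reduced scale: recording driven by the
  # agent's aligned posteriors, detection, mapping, free-energy trace
  cfg <- run_config(seed = 3, n_sessions = 4, epochs_per_session = 256,
                    sim_epochs = 512, n_select = 256, window = 32)
  man <- run_pipeline(cfg, outdir = file.path(withr::local_tempdir(), "run"),
                      write_figures = FALSE)
  fe_true <- man$results$free_energy$true$free_energy
  fe_sur <- man$results$free_energy$surrogate$free_energy
  first <- fe_true$epoch <= 256
  last <- fe_true$epoch > 1024 - 256
  expect_lt(mean(fe_true$F[last]), mean(fe_true$F[first]) - 1)
  # decomposition identity on every selected epoch, both branches
  for (fe in list(fe_true, fe_sur)) {
    expect_equal(fe$F, -fe$accuracy + fe$complexity, tolerance = 1e-10)
  }
  # surrogate branch: no systematic free-energy decrease
  first_s <- fe_sur$epoch <= 256
  last_s <- fe_sur$epoch > 1024 - 256
  expect_gt(mean(fe_sur$F[last_s]), mean(fe_sur$F[first_s]) - 1)
})
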