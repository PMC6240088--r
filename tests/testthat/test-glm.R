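test_that("the DCT basis is orthonormal with zero-mean oscillatory columns", {
  B <- dct_basis(256, 8)
  expect_equal(crossprod(B), diag(8), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(abs(colMeans(B[, -1])) < 1e-12))
  B1 <- dct_basis(100, 1)
  expect_equal(unique(round(B1, 12)), matrix(0.1), ignore_attr = TRUE)
  expect_error(dct_basis(10, 11), "n_components")
  expect_error(dct_basis(10, 0), "n_components")
})

test_that("the design matrix has the documented partition and degeneracy flags", {
  ex <- make_experiment(seed = 41, n_sessions = 2, epochs_per_session = 256)
  stim_electrode <- ex$stimuli$site_map[1] + 1L
  d <- build_design(ex$sources, ex$stimuli, electrode = stim_electrode)
  expect_equal(length(d$interest), 8)
  expect_equal(length(d$confound), 36)   # own + total + 32 drift + other + 1
  expect_false(d$rank_deficient)
  # centring: the constant-basis interaction column sums to zero, so the
  # interest partition carries no intercept component
  expect_lt(abs(sum(d$X[, d$interest[1]])), 1e-8)

  # non-stimulated electrode position: no own-site column
  free_pos <- setdiff(0:63, ex$stimuli$site_map)[1] + 1L
  d2 <- build_design(ex$sources, ex$stimuli, electrode = free_pos)
  expect_equal(length(d2$confound), 35)

  # constant source indicator: interaction degenerates, flag raised
  const_src <- constant_sources(1, 0, 512)
  const_src$session <- ex$sources$session
  d3 <- build_design(const_src, ex$stimuli, electrode = NA)
  expect_true(d3$rank_deficient)
})

test_that("the partial F statistic matches the nested-model identity", {
  ex <- make_experiment(seed = 42, n_sessions = 1, epochs_per_session = 512)
  d <- build_design(ex$sources, ex$stimuli, electrode = NA)
  set.seed(1)

  # response built purely from confounds: F vanishes
  beta_c <- rnorm(length(d$confound), sd = 0.3)
  y_conf <- as.numeric(d$X[, d$confound] %*% beta_c)
  f0 <- fit_glm(y_conf + 0, d)
  expect_lt(f0$F, 1e-8)

  # known interaction coefficients recovered within 3 SEs
  beta_i <- c(2, -1, 0.5, 0.3, 0, 0, 0, 0)
  y <- y_conf + as.numeric(d$X[, d$interest] %*% beta_i) + rnorm(512, sd = 0.5)
  fit <- fit_glm(y, d)
  XtXinv <- solve(crossprod(d$X))
  se <- sqrt(diag(XtXinv)[d$interest] * fit$sigma2)
  expect_true(all(abs(fit$coefficients[d$interest] - beta_i) < 3 * se))
  # oracle cross-check of F against R's anova on the same partition
  m_full <- stats::lm(y ~ d$X - 1)
  m_red <- stats::lm(y ~ d$X[, d$confound] - 1)
  tab <- stats::anova(m_red, m_full)
  expect_equal(fit$F, tab$F[2], tolerance = 1e-10)
  expect_equal(fit$p_value, tab$`Pr(>F)`[2], tolerance = 1e-10)

  # fitted specialisation reconstructs from the coefficients exactly
  expect_equal(fit$curve, as.numeric(d$dct_interest %*%
                                       fit$coefficients[d$interest]),
               tolerance = 1e-12)
  expect_equal(fit$present - fit$absent, fit$curve, tolerance = 1e-12)

  expect_error(fit_glm(rep(1, 512), d), "zero-variance")
})

test_that("adding confound combinations to a response leaves F unchanged", {
  ex <- make_experiment(seed = 43, n_sessions = 1, epochs_per_session = 256)
  d <- build_design(ex$sources, ex$stimuli, electrode = NA)
  set.seed(3)
  y <- rnorm(256)
  f1 <- fit_glm(y, d)$F
  shift <- as.numeric(d$X[, d$confound] %*% rnorm(length(d$confound)))
  f2 <- fit_glm(y + shift, d)$F
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("null responses give calibrated partial-F p-values", {
  ex <- make_experiment(seed = 44, n_sessions = 1, epochs_per_session = 512)
  d <- build_design(ex$sources, ex$stimuli, electrode = NA)
  set.seed(7)
  p <- replicate(300, fit_glm(rnorm(512), d)$p_value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
})

test_that("F maps place values on the grid and localise planted signals", {
  ex <- make_experiment(seed = 45, n_sessions = 2, epochs_per_session = 256)
  g <- matrix(0, 64, 2); g[23, 1] <- 0.6
  spec <- recording_spec(baseline = 5, specialisation_gain = g,
                         learning_curve = "sigmoid", sigmoid_midpoint = -10)
  rec <- generate_recording(ex$stimuli, ex$sources, spec = spec, seed = 45)
  an <- analyse_specialisation(rec, ex$sources, ex$stimuli, test_source = 1)
  expect_equal(dim(an$f_map), c(8L, 8L))
  expect_equal(which.max(an$F), 23L)
  pos <- which(unclass(an$f_map) == max(an$F), arr.ind = TRUE)
  expect_equal(unname((pos[1] - 1) * 8 + (pos[2] - 1)), 22)  # 0-based row-major

  m <- f_map(c(5, 9), positions = c(0, 63))
  expect_equal(m[1, 1], 5)
  expect_equal(m[8, 8], 9)
  expect_equal(sum(!is.na(m)), 2)
  expect_error(f_map(-1, 0), "F values")
})

test_that("the three selection rules agree on the extracted learning curve", {
  ex <- make_experiment(seed = 46, n_sessions = 4, epochs_per_session = 256)
  spec <- recording_spec(learning_curve = "sigmoid")
  rec <- generate_recording(ex$stimuli, ex$sources, spec = spec, seed = 46)
  an <- analyse_specialisation(rec, ex$sources, ex$stimuli, test_source = 1)

  max_f <- select_responses(an, "max_f")
  expect_true(max_f$selected %in% 1:8)          # planted source-1 electrodes
  # partial F grows with the epoch count; at this scaled-down run length a
  # proportionally lower threshold selects the same planted electrodes
  thr <- select_responses(an, "threshold_mean", threshold = 30)
  expect_true(all(thr$selected %in% 1:8))
  cva_sel <- select_responses(an, "cva")
  expect_false(cva_sel$empty)

  expect_gt(cor(max_f$curve, thr$curve), 0.8)
  expect_gt(cor(max_f$curve, cva_sel$curve), 0.8)
  expect_gt(cor(thr$curve, cva_sel$curve), 0.8)

  none <- select_responses(an, "threshold_mean", threshold = Inf)
  expect_true(none$empty)
  expect_length(none$selected, 0)
})

test_that("canonical variates concentrate on signals and are rotation invariant", {
  ex <- make_experiment(seed = 47, n_sessions = 1, epochs_per_session = 512)
  d <- build_design(ex$sources, ex$stimuli, electrode = NA)
  set.seed(11)
  Y <- matrix(rnorm(512 * 16), 512, 16)
  Y[, 3] <- Y[, 3] + 10 * rowSums(d$X[, d$interest[1:4]])
  cv <- cva(Y, d)
  expect_equal(which.max(abs(cv$weights)), 3L)
  expect_lt(cv$p_value, 0.05)

  Q <- qr.Q(qr(matrix(rnorm(256), 16, 16)))
  cv_rot <- cva(Y %*% Q, d)
  expect_equal(abs(cv_rot$variate), abs(cv$variate), tolerance = 1e-8)

  # null calibration
  set.seed(12)
  rejected <- replicate(100, cva(matrix(rnorm(512 * 24), 512, 24), d)$p_value < 0.05)
  expect_lte(mean(rejected), 0.10)
})
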