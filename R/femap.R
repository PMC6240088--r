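# Mapping detected specialisation to empirical posterior beliefs and
# empirical variational free energy: learning-curve matching between the
# recorded and simulated systems, per-epoch accuracy/complexity
# decomposition, and the variational information plane.

# Mean-field joint over the 4 states (order 00, 01, 10, 11) from the two
# per-source presence marginals; vectorised over epochs.
#' @keywords internal
joint_from_marginals <- function(m1, m2) {
  out <- cbind(s00 = (1 - m1) * (1 - m2), s01 = (1 - m1) * m2,
               s10 = m1 * (1 - m2), s11 = m1 * m2)
  if (nrow(out) == 1) out[1, ] else out
}

#' Empirical posterior beliefs from fitted specialisation
#'
#' Converts the GLM's fitted specialisation into per-epoch posterior
#' expectations about each source. The fitted specialisation magnitude
#' (present-minus-absent predicted response) is rescaled so that the
#' asymptotic response maps to a posterior expectation of one and the flat
#' prior (no specialisation) maps to 0.5: the scaling anchor is the 95th
#' percentile of the curve over the late training epochs, robust to
#' outliers. At each epoch the posterior deviates from 0.5 towards presence
#' when the source was present and towards absence when it was absent, in
#' proportion to the current specialisation. Marginals are clipped to
#' `[clip_eps, 1 - clip_eps]`; the joint is the product of the two
#' marginals (mean field), in the state order (0,0), (0,1), (1,0), (1,1).
#'
#' An all-zero curve (no specialisation at all) yields flat marginals of
#' 0.5; a constant non-zero (zero-range) curve carries no learning signal
#' and is an error.
#'
#' @param curves epochs x 2 matrix (or list of two vectors) of per-source
#'   specialisation curves (`glm_fit$curve`).
#' @param sources the `source_train` of the experiment (signs the per-epoch
#'   deviation).
#' @param clip_eps clip bound for the marginals (default 1e-3).
#' @param late_fraction fraction of final epochs over which the anchor is
#'   taken (default 0.25).
#' @return object of class `empirical_posterior`: list with `marginals`
#'   (epochs x 2), `joint` (epochs x 4), `anchors` (length 2), `clip_eps`.
#' @export
empirical_posterior <- function(curves, sources, clip_eps = 1e-3,
                                late_fraction = 0.25) {
  if (is.list(curves) && !is.data.frame(curves)) {
    curves <- do.call(cbind, curves)
  }
  curves <- as.matrix(curves)
  stopifnot(inherits(sources, "source_train"), ncol(curves) == 2)
  n <- nrow(curves)
  if (nrow(sources$states) != n) {
    stop("curves and sources must cover the same epochs", call. = FALSE)
  }
  if (!all(is.finite(curves))) stop("curves must be finite", call. = FALSE)
  if (clip_eps <= 0 || clip_eps >= 0.5) {
    stop("clip_eps must be in (0, 0.5)", call. = FALSE)
  }
  late <- seq.int(max(1L, n - ceiling(late_fraction * n) + 1L), n)
  marg <- matrix(NA_real_, n, 2)
  anchors <- numeric(2)
  for (src in 1:2) {
    cv <- curves[, src]
    if (all(abs(cv) < .Machine$double.eps * 100)) {
      marg[, src] <- 0.5
      anchors[src] <- 0
      next
    }
    if (diff(range(cv)) == 0) {
      stop(sprintf("degenerate (zero-range) curve for source %d", src),
           call. = FALSE)
    }
    anchor <- stats::quantile(cv[late], 0.95, names = FALSE)
    if (!is.finite(anchor) || anchor <= 0) {
      # no positive late specialisation (e.g. surrogate-source fits): scale
      # by the fluctuation magnitude so beliefs wobble around the flat prior
      anchor <- stats::quantile(abs(cv)[late], 0.95, names = FALSE)
    }
    if (anchor <= 0) {
      marg[, src] <- 0.5
      anchors[src] <- 0
      next
    }
    anchors[src] <- anchor
    sgn <- 2 * sources$states[, src] - 1
    m <- 0.5 + sgn * 0.5 * cv / anchor
    marg[, src] <- pmin(pmax(m, clip_eps), 1 - clip_eps)
  }
  joint <- joint_from_marginals(marg[, 1], marg[, 2])
  colnames(marg) <- c("s1", "s2")
  structure(
    list(marginals = marg, joint = joint, anchors = anchors,
         clip_eps = clip_eps),
    class = "empirical_posterior"
  )
}

#' @export
print.empirical_posterior <- function(x, ...) {
  cat(sprintf("empirical_posterior: %d epochs; mean P(present) = %.3f (s1), %.3f (s2)\n",
              nrow(x$marginals), mean(x$marginals[, 1]), mean(x$marginals[, 2])))
  invisible(x)
}

#' Match empirical and simulated learning curves
#'
#' Aligns the time course of learning between the recorded system and the
#' simulation. Learning progress is defined as the monotone non-decreasing
#' envelope (running maximum) of the absolute specialisation curve, which
#' makes the epoch correspondence well-defined despite epoch-to-epoch
#' fluctuation. The simulated envelope is resampled onto the empirical time
#' axis and the empirical envelope is regressed on it (least-squares scale
#' and offset). For `n_select` equally spaced empirical epochs, each
#' epoch's progress is mapped through the regression and matched to the
#' simulation epoch with the nearest progress, ties broken toward the
#' earlier epoch; the mapping is monotone by construction (a final running
#' maximum guards against rounding).
#'
#' @param empirical numeric specialisation curve of the recording (one value
#'   per empirical epoch).
#' @param simulated numeric specialisation curve of the simulation.
#' @param n_select number of equally spaced empirical epochs (default 512).
#' @return object of class `epoch_mapping`: list with `empirical_epochs`,
#'   `sim_epochs` (both length `n_select`), `coefficients` (offset, scale)
#'   of the progress regression.
#' @export
match_learning_curves <- function(empirical, simulated, n_select = 512L) {
  empirical <- as.numeric(empirical)
  simulated <- as.numeric(simulated)
  n_e <- length(empirical)
  n_s <- length(simulated)
  if (n_e < 2 || n_s < 2) stop("curves must have at least 2 epochs",
                               call. = FALSE)
  if (stats::sd(empirical) == 0 || stats::sd(simulated) == 0) {
    stop("curves must be non-constant", call. = FALSE)
  }
  env_e <- cummax(abs(empirical))
  env_s <- cummax(abs(simulated))

  # simulated envelope on the empirical time axis
  sim_rs <- stats::approx(seq(0, 1, length.out = n_s), env_s,
                          xout = seq(0, 1, length.out = n_e))$y
  cf <- stats::lm.fit(cbind(1, sim_rs), env_e)$coefficients
  a <- cf[1]; b <- cf[2]
  if (!is.finite(b) || b <= 0) {
    warning("non-positive progress regression slope; matching on normalised progress")
    a <- min(env_e) - min(env_s) * diff(range(env_e)) / max(diff(range(env_s)), .Machine$double.eps)
    b <- diff(range(env_e)) / max(diff(range(env_s)), .Machine$double.eps)
  }

  sel <- unique(round(seq(1, n_e, length.out = n_select)))
  if (length(sel) < n_select) {
    # short experiments: allow repeats to keep the contract of n_select rows
    sel <- round(seq(1, n_e, length.out = n_select))
  }
  target <- (env_e[sel] - a) / b
  lo <- min(env_s); hi <- max(env_s)
  clamped <- any(target < lo) || any(target > hi)
  if (clamped) {
    warning("matched progress outside the simulated range; clamping to endpoints")
    target <- pmin(pmax(target, lo), hi)
  }
  # nearest simulated epoch; ties toward the earlier epoch
  sim_idx <- vapply(target, function(p) {
    d <- abs(env_s - p)
    which(d <= min(d) + 1e-15)[1]
  }, integer(1))
  sim_idx <- cummax(sim_idx)

  structure(
    list(empirical_epochs = as.integer(sel), sim_epochs = as.integer(sim_idx),
         coefficients = c(offset = unname(a), scale = unname(b)),
         clamped = clamped),
    class = "epoch_mapping"
  )
}

#' @export
print.epoch_mapping <- function(x, ...) {
  cat(sprintf("epoch_mapping: %d selected epochs; empirical %d..%d -> simulation %d..%d\n",
              length(x$empirical_epochs),
              min(x$empirical_epochs), max(x$empirical_epochs),
              min(x$sim_epochs), max(x$sim_epochs)))
  invisible(x)
}

#' Empirical free energy of one epoch
#'
#' Free energy of an outcome vector under an empirical posterior and the
#' simulation's expected log likelihood:
#' `F = -s . lnA . o + s . ln s - s . ln D`. The parameter-complexity term
#' is omitted (reported as 0): the likelihood beliefs come from the
#' simulation and are fixed from the viewpoint of the empirical posterior.
#'
#' @param o length-32 binary outcome vector.
#' @param s_joint length-4 empirical joint posterior.
#' @param lnA expected log likelihood array at the matched epoch.
#' @param prior length-4 state prior.
#' @return `free_energy_record` with `param_complexity = 0`.
#' @export
empirical_fe_epoch <- function(o, s_joint, lnA, prior = state_prior()) {
  loglik <- state_log_evidence(lnA, o, prior = c(1, 1, 1, 1))
  terms <- s_joint * loglik
  terms[s_joint == 0] <- 0   # 0 * -Inf: zero-probability states cost nothing
  inaccuracy <- -sum(terms)
  state_complexity <- sum(xlogx(s_joint)) - sum(s_joint * log(prior))
  structure(
    list(inaccuracy = inaccuracy, state_complexity = state_complexity,
         param_complexity = 0,
         total = inaccuracy + state_complexity,
         param_form = "omitted"),
    class = "free_energy_record"
  )
}

#' Empirical free energy over the matched epochs
#'
#' Evaluates the empirical free energy at every selected epoch of an epoch
#' mapping: the outcome vector comes from the actual stimulus record, the
#' posterior from the empirical posterior beliefs, and the expected log
#' likelihood from the simulation's Dirichlet counts at the matched epoch
#' (the agent run must have been trained with `keep_counts = TRUE`).
#'
#' @param stimuli the `stimulus_train` of the experiment.
#' @param posterior an `empirical_posterior` covering all empirical epochs.
#' @param mapping an `epoch_mapping`.
#' @param agent_run an `agent_run` with a stored `counts_trajectory`.
#' @param perm length-4 state relabelling aligning the simulation's state
#'   labels with the labels of the empirical posterior (see
#'   [resolve_state_permutation()]); blind learning fixes labels only up to
#'   permutation, and the two labelings must agree before `s . lnA . o` is
#'   meaningful. Default identity.
#' @param prior length-4 state prior.
#' @return data.frame with one row per selected epoch: `epoch`,
#'   `sim_epoch`, `accuracy` (`s . lnA . o`, nats), `complexity`
#'   (`s . ln s - s . ln D`, nats), `F` (`-accuracy + complexity`).
#' @export
empirical_free_energy <- function(stimuli, posterior, mapping, agent_run,
                                  perm = 1:4, prior = state_prior()) {
  stopifnot(inherits(stimuli, "stimulus_train"),
            inherits(posterior, "empirical_posterior"),
            inherits(mapping, "epoch_mapping"),
            inherits(agent_run, "agent_run"))
  traj <- agent_run$counts_trajectory
  if (is.null(traj)) {
    stop("agent_run must be trained with keep_counts = TRUE", call. = FALSE)
  }
  if (max(mapping$sim_epochs) > nrow(traj)) {
    stop("matched simulation epochs exceed the stored count trajectory",
         call. = FALSE)
  }
  n_sel <- length(mapping$empirical_epochs)
  out <- matrix(NA_real_, n_sel, 3)
  lnA_cache <- list()
  for (i in seq_len(n_sel)) {
    t_emp <- mapping$empirical_epochs[i]
    t_sim <- mapping$sim_epochs[i]
    key <- as.character(t_sim)
    lnA <- lnA_cache[[key]]
    if (is.null(lnA)) {
      a_t <- dirichlet_likelihood(array(traj[t_sim, ], dim = c(32, 2, 2, 2)))
      lnA <- relabel_lnA(expected_log_likelihood(a_t), perm)
      lnA_cache[[key]] <- lnA
    }
    rec <- empirical_fe_epoch(stimuli$outcomes[t_emp, ],
                              posterior$joint[t_emp, ], lnA, prior)
    out[i, ] <- c(-rec$inaccuracy, rec$state_complexity, rec$total)
  }
  data.frame(epoch = mapping$empirical_epochs,
             sim_epoch = mapping$sim_epochs,
             accuracy = out[, 1], complexity = out[, 2], F = out[, 3])
}

#' Smooth free-energy records into an information-plane trajectory
#'
#' Simple moving average (window default 32 epochs, valid region only) of
#' accuracy, complexity and free energy, emitted as the trajectory in the
#' variational information plane (accuracy against complexity). The
#' returned object carries the 3-nat reference: a free-energy drop of 3
#' nats corresponds to an evidence odds factor of exp(3), about 20 to 1.
#'
#' @param records data.frame as returned by [empirical_free_energy()] (or
#'   any with columns `accuracy`, `complexity`, `F`).
#' @param window moving-average window in epochs (default 32; 1 is the
#'   identity).
#' @return object of class `info_plane`: data.frame with `index`,
#'   `accuracy`, `complexity`, `F`, and attributes `window`,
#'   `f_reference` (first smoothed F and the same minus 3 nats),
#'   `odds_per_3nats`.
#' @export
smooth_and_plane <- function(records, window = 32L) {
  need <- c("accuracy", "complexity", "F")
  if (!all(need %in% colnames(records))) {
    stop("records must have accuracy, complexity and F columns", call. = FALSE)
  }
  n <- nrow(records)
  if (window < 1 || window > n) {
    stop("window must be between 1 and the number of records", call. = FALSE)
  }
  # valid-region moving average via cumulative sums
  ma <- function(x) {
    cs <- cumsum(c(0, x))
    (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  }
  out <- data.frame(
    index = seq_len(n - window + 1),
    accuracy = ma(records$accuracy),
    complexity = ma(records$complexity),
    F = ma(records$F)
  )
  attr(out, "window") <- window
  attr(out, "f_reference") <- c(start = out$F[1], minus_3nats = out$F[1] - 3)
  attr(out, "odds_per_3nats") <- exp(3)
  class(out) <- c("info_plane", "data.frame")
  out
}

#' @export
print.info_plane <- function(x, ...) {
  ref <- attr(x, "f_reference")
  cat(sprintf("info_plane: %d smoothed epochs (window %d)\n",
              nrow(x), attr(x, "window")))
  cat(sprintf("  F: %.3f -> %.3f nats (3-nat reference at %.3f; exp(3) = %.0f : 1 odds)\n",
              x$F[1], x$F[nrow(x)], ref["minus_3nats"],
              attr(x, "odds_per_3nats")))
  invisible(x)
}
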