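# The Bayes-optimal encoder: variational inference over the 4 joint source
# states, Dirichlet learning of the likelihood mapping, and exact
# free-energy bookkeeping.
#
# Conventions. The joint state of the two binary sources is a length-4
# categorical in the fixed order (s1, s2) = (0,0), (0,1), (1,0), (1,1).
# Dirichlet counts share the (site, outcome, s1, s2) layout of the
# likelihood array, dim (32, 2, 2, 2).

JOINT_STATES <- cbind(s1 = c(0L, 0L, 1L, 1L), s2 = c(0L, 1L, 0L, 1L))

#' Dirichlet beliefs over the likelihood mapping
#'
#' Constructs the conjugate Dirichlet parameterisation of beliefs about the
#' stimulation likelihood. Counts are indexed (site, outcome, s1 level, s2
#' level); the default prior sets every concentration count to 1 (a low
#' confidence prior, as if each outcome had been seen once).
#'
#' @param counts optional initial counts, dim (32, 2, 2, 2), strictly
#'   positive; defaults to the prior counts.
#' @param prior_counts prior counts a0, same shape; default all 1.
#' @return object of class `dirichlet_likelihood` with elements `counts` and
#'   `prior_counts`.
#' @export
dirichlet_likelihood <- function(counts = NULL, prior_counts = NULL) {
  if (is.null(prior_counts)) {
    prior_counts <- array(1, dim = c(32, 2, 2, 2))
  }
  if (!identical(dim(prior_counts), c(32L, 2L, 2L, 2L)) ||
      any(prior_counts <= 0)) {
    stop("prior_counts must be strictly positive with dim (32, 2, 2, 2)",
         call. = FALSE)
  }
  if (is.null(counts)) counts <- prior_counts
  if (!identical(dim(counts), c(32L, 2L, 2L, 2L)) || any(counts <= 0)) {
    stop("counts must be strictly positive with dim (32, 2, 2, 2)",
         call. = FALSE)
  }
  structure(list(counts = counts, prior_counts = prior_counts),
            class = "dirichlet_likelihood")
}

#' @export
print.dirichlet_likelihood <- function(x, ...) {
  added <- sum(x$counts) - sum(x$prior_counts)
  cat(sprintf("dirichlet_likelihood: %.0f observations accumulated (%.1f epochs)\n",
              added, added / 32))
  invisible(x)
}

#' Posterior expectation of the log likelihood
#'
#' Computes E[ln A] under the Dirichlet posterior: for every (site, outcome,
#' state) cell, `digamma(a) - digamma(sum over outcomes of a)`. This is the
#' quantity the inference step uses in place of the unknown log likelihood.
#'
#' @param a a `dirichlet_likelihood`.
#' @return numeric array, dim (32, 2, 2, 2), finite everywhere.
#' @export
expected_log_likelihood <- function(a) {
  stopifnot(inherits(a, "dirichlet_likelihood"))
  counts <- a$counts
  if (any(counts <= 0)) stop("Dirichlet counts must be strictly positive",
                             call. = FALSE)
  tot <- counts[, 1, , ] + counts[, 2, , ]   # sum over outcomes, dim (32,2,2)
  lnA <- counts
  lnA[, 1, , ] <- digamma(counts[, 1, , ]) - digamma(tot)
  lnA[, 2, , ] <- digamma(counts[, 2, , ]) - digamma(tot)
  lnA
}

#' Uniform prior over the joint source state
#'
#' The product of independent Cat(0.5, 0.5) priors per source: uniform over
#' the 4 joint states.
#'
#' @return length-4 probability vector in the joint-state order
#'   (0,0), (0,1), (1,0), (1,1).
#' @export
state_prior <- function() {
  p <- rep(0.25, 4)
  names(p) <- c("s00", "s01", "s10", "s11")
  p
}

# Log evidence for each of the 4 joint states given one outcome vector:
# ln D + sum_i lnA[i, o_i, k, l]. Both the stimulated (o = 1) and the
# non-stimulated (o = 0) outcome terms enter: absence of stimulation is
# informative. Works with -Inf entries (exact zeros in a known likelihood).
#' @keywords internal
state_log_evidence <- function(lnA, o, prior = state_prior()) {
  if (length(o) != 32) stop("outcome vector must have length 32", call. = FALSE)
  stop_if_not_binary(o, "outcomes")
  j <- o + 1L
  v <- log(prior)
  for (st in 1:4) {
    k <- JOINT_STATES[st, 1] + 1L
    l <- JOINT_STATES[st, 2] + 1L
    terms <- lnA[cbind(1:32, j, k, l)]
    # 0 * -Inf would be NaN only via multiplication; plain summation keeps
    # -Inf, which softmax maps to probability zero.
    v[st] <- v[st] + sum(terms)
  }
  v
}

#' Exact posterior over the joint source state
#'
#' One-step softmax inference: the posterior over the 4 joint states is
#' `softmax(ln D + sum_i lnA[i, o_i, ., .])`, where the sum runs over all 32
#' sites and includes the terms for non-stimulated sites (the outcome is
#' one-hot over absent/present per site).
#'
#' @param lnA expected log likelihood array, dim (32, 2, 2, 2); exact zeros
#'   in a known likelihood may be passed as `-Inf`.
#' @param o length-32 binary outcome vector.
#' @param prior length-4 state prior (default uniform).
#' @return object of class `posterior_state`: list with `joint` (length-4
#'   simplex), `marginals` (list of two length-2 vectors), `v` (log
#'   expectations, normalised so that `softmax(v) == joint`).
#' @export
infer_states <- function(lnA, o, prior = state_prior()) {
  if (length(prior) != 4 || abs(sum(prior) - 1) > 1e-8) {
    stop("prior must be a length-4 probability vector", call. = FALSE)
  }
  v <- state_log_evidence(lnA, o, prior)
  joint <- softmax(v)
  new_posterior_state(joint, v)
}

#' @keywords internal
new_posterior_state <- function(joint, v = log(joint), converged = TRUE,
                                iterations = NA_integer_) {
  names(joint) <- c("s00", "s01", "s10", "s11")
  marg <- list(
    s1 = c(absent = joint[1] + joint[2], present = joint[3] + joint[4]),
    s2 = c(absent = joint[1] + joint[3], present = joint[2] + joint[4])
  )
  marg <- lapply(marg, function(m) { names(m) <- c("absent", "present"); m })
  structure(list(joint = joint, marginals = marg, v = v,
                 converged = converged, iterations = iterations),
            class = "posterior_state")
}

#' @export
print.posterior_state <- function(x, ...) {
  cat("posterior_state over (s1, s2):\n")
  print(round(x$joint, 4))
  cat(sprintf("  P(s1 = 1) = %.4f, P(s2 = 1) = %.4f\n",
              x$marginals$s1["present"], x$marginals$s2["present"]))
  invisible(x)
}

#' Within-epoch relaxation to the posterior
#'
#' The neuronally plausible route to the same fixed point as
#' [infer_states()]: a discrete-time gradient flow on the log expectation v
#' driven by prediction error. Each iteration computes
#' `epsilon = (ln D + lnA . o) - v`, moves `v <- v + step * epsilon`, and
#' reads out the firing rate `s = softmax(v)`. At convergence epsilon is
#' constant across states up to the additive normalising constant, and s
#' equals the one-step softmax posterior.
#'
#' @inheritParams infer_states
#' @param step step size in (0, 1]; `step = 1` reaches the fixed point in a
#'   single iteration.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on `max|epsilon - mean(epsilon)|`.
#' @return a `posterior_state` (with `converged` flag and `iterations`) whose
#'   `trace` element records the iterates: matrices `v`, `epsilon`, `s`
#'   (iterations x 4), used downstream as simulated within-epoch responses.
#' @export
relax_to_posterior <- function(lnA, o, prior = state_prior(), step = 0.25,
                               max_iter = 16L, tol = 1e-8) {
  if (step <= 0 || step > 1) stop("step must be in (0, 1]", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  target <- state_log_evidence(lnA, o, prior)
  # states with -Inf log evidence (exact zeros in a known likelihood) are
  # clamped; the gradient flow runs on the remaining components
  finite_t <- is.finite(target)
  if (!any(finite_t)) stop("all states have zero likelihood", call. = FALSE)
  v <- log(prior)
  tr_v <- tr_e <- tr_s <- matrix(NA_real_, max_iter, 4)
  converged <- FALSE
  it <- 0L
  for (i in seq_len(max_iter)) {
    eps <- target - v
    eps[!finite_t] <- -Inf
    v[finite_t] <- v[finite_t] + step * eps[finite_t]
    v[!finite_t] <- -Inf
    s <- softmax(v)
    tr_v[i, ] <- v; tr_e[i, ] <- eps; tr_s[i, ] <- s
    it <- i
    ef <- eps[finite_t]
    if (max(abs(ef - mean(ef))) < tol) {
      converged <- TRUE
      break
    }
  }
  out <- new_posterior_state(softmax(v), v, converged = converged,
                             iterations = it)
  out$trace <- list(v = tr_v[seq_len(it), , drop = FALSE],
                    epsilon = tr_e[seq_len(it), , drop = FALSE],
                    s = tr_s[seq_len(it), , drop = FALSE])
  out
}

#' Hebbian Dirichlet count update
#'
#' Accumulates evidence about the likelihood mapping: for every site i the
#' count cell of the observed outcome is incremented by the posterior state
#' expectation, `a[i, o_i, k, l] <- a[i, o_i, k, l] + s[k, l]`. The added
#' mass per site per epoch is exactly 1. This is the associative (Hebbian)
#' plasticity rule: co-occurrence of an outcome and an inferred state
#' strengthens the corresponding connection.
#'
#' @param a a `dirichlet_likelihood`.
#' @param o length-32 binary outcome vector.
#' @param s a `posterior_state` (or length-4 simplex vector).
#' @return the updated `dirichlet_likelihood`.
#' @export
update_counts <- function(a, o, s) {
  stopifnot(inherits(a, "dirichlet_likelihood"))
  if (inherits(s, "posterior_state")) s <- s$joint
  if (length(s) != 4 || abs(sum(s) - 1) > 1e-8 || any(s < -1e-12)) {
    stop("s must be a length-4 simplex vector", call. = FALSE)
  }
  if (length(o) != 32) stop("outcome vector must have length 32", call. = FALSE)
  stop_if_not_binary(o, "outcomes")
  # joint order (00, 01, 10, 11) laid out as [k+1, l+1]
  s_mat <- matrix(c(s[1], s[3], s[2], s[4]), 2, 2)
  counts <- a$counts
  for (i in 1:32) {
    j <- o[i] + 1L
    counts[i, j, , ] <- counts[i, j, , ] + s_mat
  }
  dirichlet_likelihood(counts, a$prior_counts)
}

# Exact KL divergence between two Dirichlet distributions with parameter
# vectors a (posterior) and b (prior), summed over independent rows.
#' @keywords internal
dirichlet_kl <- function(a, b) {
  # a, b: matrices rows x categories
  sa <- rowSums(a); sb <- rowSums(b)
  sum(lgamma(sa) - lgamma(sb)) -
    sum(lgamma(a) - lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(sa)))
}

# The truncated parameter-complexity expression
# sum_i { (a - a0) . lnA - ln Beta(a) }: the exact KL minus the constant
# sum_i ln Beta(a0). Both forms are exposed (see free_energy).
#' @keywords internal
param_complexity_truncated <- function(a) {
  lnA <- expected_log_likelihood(a)
  diff <- a$counts - a$prior_counts
  rows <- dirichlet_rows(a$counts)
  ln_beta <- sum(lgamma(rows)) - sum(lgamma(rowSums(rows)))
  sum(diff * lnA) - ln_beta
}

# Flatten counts to rows of the per-(site, k, l) Dirichlet over outcomes.
#' @keywords internal
dirichlet_rows <- function(counts) {
  cbind(as.vector(counts[, 1, , ]), as.vector(counts[, 2, , ]))
}

#' Variational free energy of one epoch
#'
#' Computes the epoch free energy and its decomposition:
#' \describe{
#'   \item{inaccuracy}{`-s . lnA . o`, the negative expected log likelihood
#'     of the observed outcomes under the posterior (nats).}
#'   \item{state_complexity}{`s . ln s - s . ln D`, the KL divergence from
#'     the state prior; with the uniform prior this is `s . ln s + ln 4`,
#'     bounded in [0, ln 4].}
#'   \item{param_complexity}{the KL divergence between the Dirichlet
#'     posterior and prior over the likelihood mapping, exact by default;
#'     `param_form = "truncated"` instead returns
#'     `sum_i {(a - a0) . lnA - ln Beta(a)}`, which differs from the exact
#'     KL by the constant `+ sum_i ln Beta(a0)`.}
#'   \item{total}{the sum of the three terms.}
#' }
#' Free energy upper-bounds the negative log evidence `-ln P(o)`; the bound
#' is tight at the exact posterior.
#'
#' @param o length-32 binary outcome vector.
#' @param s a `posterior_state` or length-4 simplex.
#' @param a a `dirichlet_likelihood`.
#' @param prior length-4 state prior.
#' @param param_form `"exact"` (default) or `"truncated"`.
#' @return object of class `free_energy_record`: list with `inaccuracy`,
#'   `state_complexity`, `param_complexity`, `total` (all in nats).
#' @export
free_energy <- function(o, s, a, prior = state_prior(),
                        param_form = c("exact", "truncated")) {
  param_form <- match.arg(param_form)
  stopifnot(inherits(a, "dirichlet_likelihood"))
  if (inherits(s, "posterior_state")) s <- s$joint
  lnA <- expected_log_likelihood(a)
  loglik <- state_log_evidence(lnA, o, prior = c(1, 1, 1, 1)) # ln-prior 0
  inaccuracy <- -sum(s * loglik)
  state_complexity <- sum(xlogx(s)) - sum(s * log(prior))
  pc <- if (param_form == "exact") {
    dirichlet_kl(dirichlet_rows(a$counts), dirichlet_rows(a$prior_counts))
  } else {
    param_complexity_truncated(a)
  }
  structure(
    list(inaccuracy = inaccuracy, state_complexity = state_complexity,
         param_complexity = pc,
         total = inaccuracy + state_complexity + pc,
         param_form = param_form),
    class = "free_energy_record"
  )
}

#' @export
print.free_energy_record <- function(x, ...) {
  cat(sprintf("free energy: %.4f nats (inaccuracy %.4f + state complexity %.4f + parameter complexity %.4f)\n",
              x$total, x$inaccuracy, x$state_complexity, x$param_complexity))
  invisible(x)
}

#' Log evidence of an outcome vector by enumeration
#'
#' `-ln P(o)` marginalised over the 4 joint states by direct enumeration,
#' with the outcome likelihood taken as the posterior-expected probabilities
#' `E[A]` (counts normalised over outcomes). Used as the reference bound for
#' free energy.
#'
#' @param o length-32 binary outcome vector.
#' @param a a `dirichlet_likelihood` or a probability `likelihood_array`.
#' @param prior length-4 state prior.
#' @return scalar, nats.
#' @export
neg_log_evidence <- function(o, a, prior = state_prior()) {
  probs <- if (inherits(a, "dirichlet_likelihood")) {
    tot <- a$counts[, 1, , ] + a$counts[, 2, , ]
    p <- a$counts
    p[, 1, , ] <- a$counts[, 1, , ] / tot
    p[, 2, , ] <- a$counts[, 2, , ] / tot
    p
  } else {
    a
  }
  lp <- log(probs)
  v <- state_log_evidence(lp, o, prior)
  -logsumexp(v)
}

#' Run the agent over a stimulus train
#'
#' The full learning loop. Per epoch: relax to the posterior over the joint
#' source state given the epoch's outcomes (within-epoch neuronal dynamics),
#' update the Dirichlet counts with the Hebbian rule, then record the epoch
#' free energy under the updated beliefs.
#'
#' Exactly symmetric initial beliefs (all counts equal) are a repelling
#' fixed point of blind learning: the uniform posterior distributes every
#' update identically over the four states and no state ever specialises.
#' By default the starting counts therefore carry a small uniform jitter
#' above the unit prior (`counts = 1 + U(0, init_jitter)`), which breaks
#' the tie without informing the agent about the true labelling; which
#' state adopts which role is decided by this jitter and the early stimuli.
#'
#' @param stimuli a `stimulus_train`.
#' @param n_epochs number of epochs to run (default 512, at most the length
#'   of the train).
#' @param a0 starting beliefs; the default adds the symmetry-breaking
#'   jitter to the unit-count prior. Pass `dirichlet_likelihood()` for
#'   exactly symmetric counts.
#' @param init_jitter upper bound of the uniform jitter on the default
#'   starting counts (default 0.01); drawn from a stream derived from the
#'   stimulus seed.
#' @param restarts number of jitter initialisations to try (default 1).
#'   Like any mixture learner the agent can settle in a poor local optimum
#'   of the free energy; with `restarts > 1` the run with the lowest
#'   epoch-averaged state free energy (inaccuracy + state complexity) over
#'   its final 64 epochs is kept — model selection by the agent's own
#'   objective, blind to the true labelling. Ignored when `a0` is given.
#' @param prior state prior.
#' @param step,max_iter,tol relaxation solver settings.
#' @param learn if `FALSE`, skip the count updates (no-plasticity control:
#'   inference runs on the fixed initial beliefs).
#' @param keep_counts if `TRUE`, store the full per-epoch count trajectory
#'   (needed to evaluate empirical free energy at matched epochs).
#' @param keep_traces if `TRUE`, keep the within-epoch solver traces for the
#'   first `trace_epochs` epochs as simulated firing rates.
#' @param trace_epochs number of epochs for which traces are kept.
#' @param param_form free-energy parameter-complexity form (see
#'   [free_energy()]).
#' @return object of class `agent_run`: list with
#'   \item{posterior}{epochs x 4 matrix of converged joint expectations}
#'   \item{marginals}{epochs x 2 matrix of P(source present)}
#'   \item{free_energy}{data.frame epoch, inaccuracy, state_complexity,
#'     param_complexity, total}
#'   \item{a}{final `dirichlet_likelihood`}
#'   \item{counts_trajectory}{if kept, epochs x 256 matrix of flattened
#'     counts after each epoch's update}
#'   \item{firing_rates}{if kept, list of per-epoch solver traces (s
#'     iterates), plus `unit_traces`: concatenated presence/absence unit
#'     rates for the two sources over solver iterations}
#' @export
run_training <- function(stimuli, n_epochs = 512L, a0 = NULL,
                         init_jitter = 0.01, restarts = 1L,
                         prior = state_prior(), step = 0.25, max_iter = 16L,
                         tol = 1e-8, learn = TRUE,
                         keep_counts = FALSE, keep_traces = FALSE,
                         trace_epochs = 128L,
                         param_form = c("exact", "truncated")) {
  param_form <- match.arg(param_form)
  stopifnot(inherits(stimuli, "stimulus_train"))
  if (is.null(a0) && restarts > 1) {
    runs <- lapply(seq_len(restarts), function(r) {
      purpose <- if (r == 1) "agent_init" else paste0("agent_init", r)
      jitter <- with_seed(derive_seed(stimuli$seed %||% 1L, purpose), {
        stats::runif(256, 0, init_jitter)
      })
      a0_r <- dirichlet_likelihood(array(1 + jitter, dim = c(32, 2, 2, 2)))
      run_training(stimuli, n_epochs = n_epochs, a0 = a0_r,
                   prior = prior, step = step, max_iter = max_iter,
                   tol = tol, learn = learn, keep_counts = keep_counts,
                   keep_traces = keep_traces, trace_epochs = trace_epochs,
                   param_form = param_form)
    })
    tail_n <- min(64L, n_epochs)
    scores <- vapply(runs, function(r) {
      fe <- r$free_energy
      idx <- seq.int(n_epochs - tail_n + 1L, n_epochs)
      mean(fe$inaccuracy[idx] + fe$state_complexity[idx])
    }, numeric(1))
    best <- runs[[which.min(scores)]]
    best$restart_scores <- scores
    return(best)
  }
  if (is.null(a0)) {
    jitter <- with_seed(derive_seed(stimuli$seed %||% 1L, "agent_init"), {
      stats::runif(256, 0, init_jitter)
    })
    a0 <- dirichlet_likelihood(array(1 + jitter, dim = c(32, 2, 2, 2)))
  }
  if (n_epochs > nrow(stimuli$outcomes)) {
    stop("n_epochs exceeds available stimulus epochs", call. = FALSE)
  }
  a <- a0
  post <- matrix(NA_real_, n_epochs, 4,
                 dimnames = list(NULL, c("s00", "s01", "s10", "s11")))
  fe <- matrix(NA_real_, n_epochs, 4)
  counts_traj <- if (keep_counts) matrix(NA_real_, n_epochs, 256) else NULL
  traces <- if (keep_traces) vector("list", min(trace_epochs, n_epochs)) else NULL
  for (t in seq_len(n_epochs)) {
    o <- stimuli$outcomes[t, ]
    lnA <- expected_log_likelihood(a)
    ps <- relax_to_posterior(lnA, o, prior, step = step,
                             max_iter = max_iter, tol = tol)
    if (learn) a <- update_counts(a, o, ps)
    rec <- free_energy(o, ps, a, prior, param_form = param_form)
    post[t, ] <- ps$joint
    fe[t, ] <- c(rec$inaccuracy, rec$state_complexity, rec$param_complexity,
                 rec$total)
    if (keep_counts) counts_traj[t, ] <- as.vector(a$counts)
    if (keep_traces && t <= length(traces)) traces[[t]] <- ps$trace$s
  }
  marginals <- cbind(s1 = post[, 3] + post[, 4], s2 = post[, 2] + post[, 4])
  fe_df <- data.frame(epoch = seq_len(n_epochs), inaccuracy = fe[, 1],
                      state_complexity = fe[, 2], param_complexity = fe[, 3],
                      total = fe[, 4])
  firing <- NULL
  if (keep_traces) {
    # presence/absence unit rates per source, concatenated across epochs
    unit <- do.call(rbind, lapply(seq_along(traces), function(t) {
      s <- traces[[t]]
      data.frame(epoch = t, iteration = seq_len(nrow(s)),
                 s1_absent = s[, 1] + s[, 2], s1_present = s[, 3] + s[, 4],
                 s2_absent = s[, 1] + s[, 3], s2_present = s[, 2] + s[, 4])
    }))
    firing <- list(joint_traces = traces, unit_traces = unit)
  }
  structure(
    list(posterior = post, marginals = marginals, free_energy = fe_df,
         a = a, counts_trajectory = counts_traj, firing_rates = firing,
         config = list(n_epochs = n_epochs, step = step, max_iter = max_iter,
                       tol = tol, param_form = param_form)),
    class = "agent_run"
  )
}

#' @export
print.agent_run <- function(x, ...) {
  n <- nrow(x$posterior)
  k <- min(64L, n)
  fs <- x$free_energy$inaccuracy + x$free_energy$state_complexity
  cat(sprintf("agent_run: %d epochs\n", n))
  cat(sprintf("  mean state free energy, first %d epochs: %.2f nats; last %d: %.2f nats\n",
              k, mean(fs[seq_len(k)]), k, mean(fs[(n - k + 1):n])))
  invisible(x)
}

#' Learned likelihood (posterior mean)
#'
#' Normalises Dirichlet counts over outcomes to give the posterior-mean
#' likelihood array.
#'
#' @param a a `dirichlet_likelihood`.
#' @return array, dim (32, 2, 2, 2).
#' @export
posterior_mean_likelihood <- function(a) {
  stopifnot(inherits(a, "dirichlet_likelihood"))
  tot <- a$counts[, 1, , ] + a$counts[, 2, , ]
  p <- a$counts
  p[, 1, , ] <- a$counts[, 1, , ] / tot
  p[, 2, , ] <- a$counts[, 2, , ] / tot
  p
}

# All 24 bijections of the 4 joint states, rows of a permutation matrix
# q: relabelled state j corresponds to learned state q[j].
#' @keywords internal
state_permutations <- function() {
  g <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  g <- g[apply(g, 1, function(r) length(unique(r)) == 4), , drop = FALSE]
  dimnames(g) <- NULL
  g
}

# Pool-averaged stimulation table: 2 pools x 4 states of mean P(o = 1).
# The per-site estimates carry binomial noise; the pooled table is the
# natural resolution of the protocol (sites within a pool share their
# likelihood row).
#' @keywords internal
pool_table <- function(probs) {
  p1 <- probs[, 2, , ]        # P(o = 1), dim (32, 2, 2)
  dim(p1) <- c(32, 4)         # states flattened (00, 10, 01, 11)
  p1 <- p1[, c(1, 3, 2, 4)]   # reorder to joint order (00, 01, 10, 11)
  rbind(pool1 = colMeans(p1[1:16, ]), pool2 = colMeans(p1[17:32, ]))
}

#' Resolve the state-labelling permutation of a learned likelihood
#'
#' Blind learning treats the four joint source states as exchangeable
#' mixture components: nothing in the model ties a learned state to a
#' particular true state, so the learned likelihood is identified only up
#' to a permutation of the four states. `resolve_state_permutation()`
#' compares the learned pool-averaged stimulation table with a reference
#' under all 24 relabellings and returns the best match.
#' `resolve_source_permutation()` restricts the search to the two
#' relabellings that preserve the product structure of two sources
#' (identity, and swapping source 1 with source 2, which exchanges the
#' (0,1) and (1,0) joint states).
#'
#' @param a learned `dirichlet_likelihood`.
#' @param reference reference likelihood array (default [true_likelihood()]).
#' @return list with `perm` (length-4 permutation: relabelled state j is
#'   learned state `perm[j]`, joint order (0,0), (0,1), (1,0), (1,1)),
#'   `error` (max absolute deviation of the pool-averaged table under the
#'   best relabelling), `source_perm` (logical: the best relabelling is a
#'   pure source permutation), `permuted` (logical: sources swapped), and
#'   `probs` (the relabelled posterior-mean likelihood array).
#' @export
resolve_state_permutation <- function(a, reference = true_likelihood()) {
  resolve_permutation_impl(a, reference, state_permutations())
}

#' @rdname resolve_state_permutation
#' @export
resolve_source_permutation <- function(a, reference = true_likelihood()) {
  resolve_permutation_impl(a, reference,
                           rbind(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L)))
}

#' @keywords internal
resolve_permutation_impl <- function(a, reference, perms) {
  p <- posterior_mean_likelihood(a)
  tab <- pool_table(p)
  ref_tab <- pool_table(reference)
  errs <- apply(perms, 1, function(q) max(abs(tab[, q] - ref_tab)))
  i <- which.min(errs)
  q <- perms[i, ]
  # apply the relabelling to the full array: joint order index -> (k, l)
  kl <- cbind(k = c(1L, 1L, 2L, 2L), l = c(1L, 2L, 1L, 2L))
  probs <- p
  for (j in 1:4) {
    probs[, , kl[j, 1], kl[j, 2]] <- p[, , kl[q[j], 1], kl[q[j], 2]]
  }
  list(perm = q, error = unname(errs[i]),
       source_perm = all(q == 1:4) || all(q == c(1L, 3L, 2L, 4L)),
       permuted = all(q == c(1L, 3L, 2L, 4L)),
       probs = probs)
}

# Apply a joint-state relabelling to a (32, 2, 2, 2) array: relabelled
# state j takes the slice of original state perm[j] (joint order).
#' @keywords internal
relabel_lnA <- function(x, perm) {
  if (all(perm == 1:4)) return(x)
  kl <- cbind(k = c(1L, 1L, 2L, 2L), l = c(1L, 2L, 1L, 2L))
  out <- x
  for (j in 1:4) {
    out[, , kl[j, 1], kl[j, 2]] <- x[, , kl[perm[j], 1], kl[perm[j], 2]]
  }
  out
}

#' Relabel per-epoch joint posteriors
#'
#' Applies a state relabelling (as returned by
#' [resolve_state_permutation()]) to an epochs x 4 matrix of joint
#' posterior expectations, and recomputes the source marginals.
#'
#' @param posterior epochs x 4 joint posterior matrix (joint order).
#' @param perm length-4 permutation vector.
#' @return list with `joint` (relabelled matrix) and `marginals`
#'   (epochs x 2 presence probabilities).
#' @export
relabel_posterior <- function(posterior, perm) {
  joint <- posterior[, perm, drop = FALSE]
  colnames(joint) <- c("s00", "s01", "s10", "s11")
  list(joint = joint,
       marginals = cbind(s1 = joint[, 3] + joint[, 4],
                         s2 = joint[, 2] + joint[, 4]))
}

#' Write / read an agent snapshot
#'
#' Serialises the agent's Dirichlet counts, configuration and per-epoch
#' traces. Counts and config go to a JSON archive; the free-energy and
#' posterior traces to a TSV (epoch, s_00, s_01, s_10, s_11, inaccuracy,
#' state_complexity, param_complexity, F).
#'
#' @param run an `agent_run`.
#' @param path base path; writes `<path>.json` and `<path>_trace.tsv`.
#' @return base path, invisibly; the reader returns a list with `counts`,
#'   `prior_counts`, `config`, `trace`.
#' @export
write_agent_snapshot <- function(run, path) {
  stopifnot(inherits(run, "agent_run"))
  jsonlite::write_json(
    list(counts = as.vector(run$a$counts),
         prior_counts = as.vector(run$a$prior_counts),
         dim = dim(run$a$counts), config = run$config),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  trace <- data.frame(
    epoch = run$free_energy$epoch,
    s_00 = run$posterior[, 1], s_01 = run$posterior[, 2],
    s_10 = run$posterior[, 3], s_11 = run$posterior[, 4],
    inaccuracy = run$free_energy$inaccuracy,
    state_complexity = run$free_energy$state_complexity,
    param_complexity = run$free_energy$param_complexity,
    F = run$free_energy$total
  )
  utils::write.table(trace, paste0(path, "_trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_agent_snapshot
#' @export
read_agent_snapshot <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dm <- as.integer(meta$dim)
  list(
    a = dirichlet_likelihood(array(meta$counts, dim = dm),
                             array(meta$prior_counts, dim = dm)),
    config = meta$config,
    trace = utils::read.delim(paste0(path, "_trace.tsv"))
  )
}
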