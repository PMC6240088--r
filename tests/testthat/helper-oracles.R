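# Shared fixtures and independent oracles used across the test files.

# Small experiment: sources + stimuli drawn from the true protocol.
make_experiment <- function(seed = 1, n_sessions = 2, epochs_per_session = 64) {
  sources <- sample_sources(n_sessions, epochs_per_session, seed = seed)
  stimuli <- sample_stimuli(sources, true_likelihood(), seed = seed)
  list(sources = sources, stimuli = stimuli)
}

# A source train pinned to one joint state in every epoch (for conditional
# checks of the generative process).
constant_sources <- function(s1, s2, n) {
  structure(
    list(states = cbind(s1 = rep(as.integer(s1), n),
                        s2 = rep(as.integer(s2), n)),
         session = rep(1L, n), epoch_seconds = 1.0, seed = 0L),
    class = "source_train"
  )
}

# Brute-force Bayes over the 4 joint states with plain products of
# probabilities -- independent of the softmax/log-space route in the
# package. `probs` is a (32, 2, 2, 2) probability array.
enumerate_posterior <- function(probs, o, prior = rep(0.25, 4)) {
  states <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  lik <- numeric(4)
  for (st in 1:4) {
    p <- 1
    for (i in 1:32) {
      p <- p * probs[i, o[i] + 1L, states[st, 1] + 1L, states[st, 2] + 1L]
    }
    lik[st] <- p
  }
  w <- lik * prior
  w / sum(w)
}

# Marginal outcome probability P(o) by the same enumeration.
enumerate_marginal <- function(probs, o, prior = rep(0.25, 4)) {
  states <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  total <- 0
  for (st in 1:4) {
    p <- prior[st]
    for (i in 1:32) {
      p <- p * probs[i, o[i] + 1L, states[st, 1] + 1L, states[st, 2] + 1L]
    }
    total <- total + p
  }
  total
}

# Random strictly positive likelihood beliefs (Dirichlet counts) and the
# lnA they imply.
random_counts <- function(seed) {
  set.seed(seed)
  dirichlet_likelihood(array(runif(256, 0.2, 5), dim = c(32, 2, 2, 2)))
}

# Draw one outcome vector from the true generative process at a given state.
draw_outcome <- function(s1, s2, seed) {
  A <- true_likelihood()
  set.seed(seed)
  p1 <- vapply(1:32, function(i) A[i, 2, s1 + 1L, s2 + 1L], numeric(1))
  as.integer(runif(32) < p1)
}
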