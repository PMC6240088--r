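# The stochastic stimulation protocol: two hidden binary sources mixed onto
# 32 electrode sites of an 8x8 multi-electrode array through a fixed
# categorical likelihood.

#' Sample hidden source trains
#'
#' Draws the per-epoch states of the two hidden binary sources that drive the
#' stimulation protocol. Each source is an independent Bernoulli(1/2) draw in
#' every one-second epoch; epochs are organised into sessions (the rest
#' periods between sessions carry no epochs and are represented only as
#' session boundaries).
#'
#' @param n_sessions number of stimulation sessions (default 100).
#' @param epochs_per_session epochs per session (default 256, one per second).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return an object of class `source_train`: a list with
#'   \item{states}{integer matrix, epochs x 2, entries 0/1 (columns s1, s2)}
#'   \item{session}{integer vector, session index (1-based) per epoch}
#'   \item{epoch_seconds}{epoch duration in seconds (1)}
#' @examples
#' src <- sample_sources(2, 64, seed = 1)
#' colMeans(src$states)
#' @export
sample_sources <- function(n_sessions = 100, epochs_per_session = 256,
                           seed = 1L) {
  if (length(n_sessions) != 1 || n_sessions < 1 ||
      n_sessions != round(n_sessions)) {
    stop("n_sessions must be a positive integer", call. = FALSE)
  }
  if (length(epochs_per_session) != 1 || epochs_per_session < 1 ||
      epochs_per_session != round(epochs_per_session)) {
    stop("epochs_per_session must be a positive integer", call. = FALSE)
  }
  n <- n_sessions * epochs_per_session
  states <- with_seed(derive_seed(seed, "sources"), {
    matrix(sample(c(0L, 1L), 2 * n, replace = TRUE), ncol = 2)
  })
  colnames(states) <- c("s1", "s2")
  structure(
    list(states = states,
         session = rep(seq_len(n_sessions), each = epochs_per_session),
         epoch_seconds = 1.0,
         seed = seed),
    class = "source_train"
  )
}

#' @export
print.source_train <- function(x, ...) {
  cat(sprintf("source_train: %d epochs over %d sessions\n",
              nrow(x$states), max(x$session)))
  cat(sprintf("  source means: s1 = %.3f, s2 = %.3f\n",
              mean(x$states[, 1]), mean(x$states[, 2])))
  invisible(x)
}

#' Number of epochs in a train
#' @param x a `source_train` or `stimulus_train`.
#' @return integer epoch count.
#' @export
n_epochs <- function(x) {
  if (inherits(x, "source_train")) return(nrow(x$states))
  if (inherits(x, "stimulus_train")) return(nrow(x$outcomes))
  stop("n_epochs: unsupported object", call. = FALSE)
}

#' The true stimulation likelihood
#'
#' Returns the fixed likelihood array of the stimulation protocol: the
#' probability that electrode site i is stimulated (o = 1) given the joint
#' state of the two sources. Sites 1..16 (pool 1) are stimulated with
#' probability 3/4 when only source 1 is present and 1/4 when only source 2
#' is present; sites 17..32 (pool 2) have those probabilities swapped. No
#' site is stimulated when both sources are absent, and every site is
#' stimulated when both are present.
#'
#' @return a `likelihood_array`: numeric array with dim (32, 2, 2, 2) indexed
#'   (site i, outcome j in 0/1, s1 level k in 0/1, s2 level l in 0/1); R
#'   indices are value + 1. For every (i, k, l) the slice over j sums to 1.
#' @examples
#' A <- true_likelihood()
#' A[1, 2, 2, 1]   # P(o = 1 | s1 = 1, s2 = 0) at a pool-1 site: 0.75
#' @export
true_likelihood <- function() {
  A <- array(NA_real_, dim = c(32, 2, 2, 2),
             dimnames = list(NULL, c("o0", "o1"), c("s1_0", "s1_1"),
                             c("s2_0", "s2_1")))
  # P(o = 1 | k, l), indexed [k, l] with levels 0,1
  p1_pool1 <- matrix(c(0, 0.75, 0.25, 1), nrow = 2)   # [[0, .25], [.75, 1]]
  p1_pool2 <- matrix(c(0, 0.25, 0.75, 1), nrow = 2)   # [[0, .75], [.25, 1]]
  for (i in 1:32) {
    p1 <- if (i <= 16) p1_pool1 else p1_pool2
    A[i, 2, , ] <- p1
    A[i, 1, , ] <- 1 - p1
  }
  structure(A, class = c("likelihood_array", "array"))
}

#' @keywords internal
check_likelihood_array <- function(A) {
  if (!is.array(A) || !identical(dim(A), c(32L, 2L, 2L, 2L))) {
    stop("likelihood array must have dim (32, 2, 2, 2)", call. = FALSE)
  }
  sums <- apply(A, c(1, 3, 4), sum)
  if (any(abs(sums - 1) > 1e-8) || any(A < -1e-12) || any(A > 1 + 1e-12)) {
    stop("likelihood array entries must be probabilities summing to 1 over outcomes",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample stimulation outcomes from sources
#'
#' Given a source train and a likelihood array, draws the binary stimulation
#' outcome of each of the 32 sites in every epoch, independently across sites
#' and epochs with P(o_i = 1) taken from the likelihood at the epoch's joint
#' source state.
#'
#' @param sources a `source_train`.
#' @param A a likelihood array as returned by [true_likelihood()].
#' @param seed integer seed.
#' @param site_map optional site map (see [assign_sites()]) recorded with the
#'   train; defaults to `assign_sites(seed)`.
#' @return a `stimulus_train`: list with
#'   \item{outcomes}{integer matrix, epochs x 32, entries 0/1}
#'   \item{site_map}{32 distinct 0-based row-major positions on the 8x8 grid}
#'   \item{session}{session index per epoch}
#' @export
sample_stimuli <- function(sources, A = true_likelihood(), seed = 1L,
                           site_map = NULL) {
  stopifnot(inherits(sources, "source_train"))
  check_likelihood_array(A)
  if (is.null(site_map)) site_map <- assign_sites(seed)
  check_site_map(site_map)
  n <- nrow(sources$states)
  k <- sources$states[, 1] + 1L    # s1 level index
  l <- sources$states[, 2] + 1L    # s2 level index
  # P(o_i = 1) per epoch: n x 32
  p1 <- matrix(NA_real_, n, 32)
  for (i in 1:32) {
    p1[, i] <- A[i, 2, , ][cbind(k, l)]
  }
  outcomes <- with_seed(derive_seed(seed, "stimuli"), {
    matrix(as.integer(stats::runif(n * 32) < p1), n, 32)
  })
  colnames(outcomes) <- paste0("o_", 1:32)
  structure(
    list(outcomes = outcomes, site_map = site_map,
         session = sources$session, seed = seed),
    class = "stimulus_train"
  )
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("stimulus_train: %d epochs x 32 sites, mean stimulation rate %.3f\n",
              nrow(x$outcomes), mean(x$outcomes)))
  invisible(x)
}

#' Assign the 32 stimulated sites on the 8x8 grid
#'
#' Selects the 32 stimulated electrode positions uniformly at random without
#' replacement from the 64 grid positions; the map is fixed for an
#' experiment. Positions are 0-based, row-major over the 8x8 array. Pool 1
#' is `site_map[1..16]`, pool 2 is `site_map[17..32]` (pools are defined by
#' site index, not geometry).
#'
#' @param seed integer seed.
#' @return integer vector of 32 distinct values in 0..63.
#' @export
assign_sites <- function(seed = 1L) {
  with_seed(derive_seed(seed, "sites"), {
    sort_pools(sample(0:63, 32, replace = FALSE))
  })
}

# Keep draw order (the random order defines pool membership); helper exists
# so the intent is explicit at the call site.
#' @keywords internal
sort_pools <- function(x) x

#' @keywords internal
check_site_map <- function(site_map) {
  if (length(site_map) != 32 || anyDuplicated(site_map) ||
      any(site_map < 0) || any(site_map > 63) ||
      any(site_map != round(site_map))) {
    stop("site_map must be 32 distinct 0-based positions in 0..63",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a stimulation experiment
#'
#' Serialises a source train plus the stimulus train it generated to a TSV
#' (columns epoch, session, s1, s2, o_1..o_32) with a JSON sidecar carrying
#' the site map and seeds. `read_stim_experiment()` inverts the writer.
#'
#' @param sources a `source_train`.
#' @param stimuli the matching `stimulus_train`.
#' @param path TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_stim_experiment()` returns `path` invisibly;
#'   `read_stim_experiment()` returns `list(sources =, stimuli =)`.
#' @export
write_stim_experiment <- function(sources, stimuli, path) {
  stopifnot(inherits(sources, "source_train"),
            inherits(stimuli, "stimulus_train"),
            nrow(sources$states) == nrow(stimuli$outcomes))
  df <- data.frame(epoch = seq_len(nrow(sources$states)),
                   session = sources$session,
                   s1 = sources$states[, 1], s2 = sources$states[, 2],
                   stimuli$outcomes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(site_map = stimuli$site_map,
         epoch_seconds = sources$epoch_seconds,
         seeds = list(sources = sources$seed, stimuli = stimuli$seed)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_stim_experiment
#' @export
read_stim_experiment <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  states <- as.matrix(df[, c("s1", "s2")])
  storage.mode(states) <- "integer"
  stop_if_not_binary(states, "source states")
  outcomes <- as.matrix(df[, paste0("o_", 1:32)])
  storage.mode(outcomes) <- "integer"
  stop_if_not_binary(outcomes, "outcomes")
  sources <- structure(
    list(states = states, session = df$session,
         epoch_seconds = meta$epoch_seconds,
         seed = meta$seeds$sources),
    class = "source_train"
  )
  stimuli <- structure(
    list(outcomes = outcomes, site_map = as.integer(meta$site_map),
         session = df$session, seed = meta$seeds$stimuli),
    class = "stimulus_train"
  )
  list(sources = sources, stimuli = stimuli)
}
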