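# Synthetic multi-electrode array recordings: per-electrode, per-epoch
# evoked spike counts containing stimulation-evoked activity, slow drift,
# count noise, and source-selective responses that grow with learning.

#' Recording specification
#'
#' Collects the parameters of the synthetic spike-count generator. Rates are
#' per one-second epoch; gains act on the log rate, so a gain g multiplies
#' the rate by exp(g) at full effect.
#'
#' @param n_electrodes number of recorded electrodes (64, the full grid).
#' @param baseline baseline rate per electrode (counts/epoch); scalar or
#'   length-`n_electrodes`. Default 5.
#' @param stim_gain log-rate increase when the electrode's own site is
#'   stimulated (scalar or per electrode). Default 1.
#' @param specialisation_gain electrodes x 2 matrix of log-rate gains at full
#'   specialisation (columns: source 1, source 2); `NULL` uses the default
#'   layout of [default_specialisation()].
#' @param drift_amplitude standard deviation of each random slow-drift
#'   cosine coefficient (log-rate units). Default 0.1.
#' @param drift_order number of low-order cosine components in the drift
#'   (default 4; 0 disables drift).
#' @param noise `"poisson"` (counts drawn from Poisson at the epoch rate) or
#'   `"none"` (the rate itself is returned, for closed-form checks).
#' @param learning_curve `"agent"` (specialisation driven by the agent's
#'   posterior, which sharpens as it learns; g(t) = 1) or `"sigmoid"`
#'   (parametric: the true source drives the response, scaled by a logistic
#'   curve g(t)).
#' @param sigmoid_midpoint,sigmoid_slope parameters of the parametric curve
#'   `g(t) = 1 / (1 + exp(-(t - midpoint)/slope))` with t the epoch fraction
#'   of training in [0, 1]. Defaults: midpoint 0.5, slope 0.1 — specialisation
#'   emerges around mid-training over roughly a quarter of the run.
#' @return object of class `recording_spec`.
#' @export
recording_spec <- function(n_electrodes = 64L,
                           baseline = 5,
                           stim_gain = 1,
                           specialisation_gain = NULL,
                           drift_amplitude = 0.1,
                           drift_order = 4L,
                           noise = c("poisson", "none"),
                           learning_curve = c("agent", "sigmoid"),
                           sigmoid_midpoint = 0.5,
                           sigmoid_slope = 0.1) {
  noise <- match.arg(noise)
  learning_curve <- match.arg(learning_curve)
  baseline <- rep_len(baseline, n_electrodes)
  stim_gain <- rep_len(stim_gain, n_electrodes)
  if (any(baseline < 0)) stop("baseline rates must be non-negative",
                              call. = FALSE)
  if (is.null(specialisation_gain)) {
    specialisation_gain <- default_specialisation(n_electrodes)
  }
  specialisation_gain <- as.matrix(specialisation_gain)
  if (nrow(specialisation_gain) != n_electrodes ||
      ncol(specialisation_gain) != 2 ||
      any(!is.finite(specialisation_gain))) {
    stop("specialisation_gain must be a finite n_electrodes x 2 matrix",
         call. = FALSE)
  }
  structure(
    list(n_electrodes = as.integer(n_electrodes), baseline = baseline,
         stim_gain = stim_gain, specialisation_gain = specialisation_gain,
         drift_amplitude = drift_amplitude, drift_order = as.integer(drift_order),
         noise = noise, learning_curve = learning_curve,
         sigmoid_midpoint = sigmoid_midpoint, sigmoid_slope = sigmoid_slope),
    class = "recording_spec"
  )
}

#' Default specialisation layout
#'
#' Eight electrodes specialise for source 1, the next eight for source 2,
#' the remainder carry no source-selective signal: specialisation is
#' distributed but dominated by a small number of electrodes.
#'
#' @param n_electrodes electrode count.
#' @param gain log-rate gain at full specialisation (default 0.5).
#' @return n_electrodes x 2 gain matrix.
#' @export
default_specialisation <- function(n_electrodes = 64L, gain = 0.5) {
  g <- matrix(0, n_electrodes, 2)
  g[1:8, 1] <- gain
  g[9:16, 2] <- gain
  colnames(g) <- c("source1", "source2")
  g
}

#' Generate a synthetic recording
#'
#' Simulates evoked spike counts at every electrode and epoch. The log rate
#' of electrode e at epoch t is
#' `ln(baseline_e) + stim_gain_e * o_site(e),t
#'  + sum_src gain_e,src * g(t) * 2 * (m_src,t - 0.5) + drift_e(t)`,
#' where `o_site(e),t` indicates stimulation of the electrode's own site,
#' `m_src,t` is the encoding signal for the source (the agent's marginal
#' posterior in agent mode; the true binary source in parametric mode), and
#' `g(t)` is the learning curve. The deviation term implements the encoding
#' assumption that firing-rate deviations from the mean are proportional to
#' the difference between posterior and flat-prior (0.5) expectations: a
#' fully confident posterior maps to +/- the full gain. Counts are Poisson
#' at the resulting rate (log link; rates are positive by construction).
#'
#' @param stimuli a `stimulus_train` (defines epochs and own-site
#'   stimulation via its `site_map`; electrodes whose grid position is not a
#'   stimulated site have a zero own-site regressor).
#' @param sources the matching `source_train`.
#' @param agent_posteriors optional epochs x 2 matrix of per-source presence
#'   probabilities (e.g. `agent_run$marginals`); required in agent mode and
#'   must cover all epochs.
#' @param spec a `recording_spec`.
#' @param seed integer seed.
#' @return object of class `response_matrix`: list with
#'   \item{counts}{electrodes x epochs matrix (integer counts, or real rates
#'     when `noise = "none"`)}
#'   \item{session}{session index per epoch}
#'   \item{ground_truth}{the spec, the learning curve g(t), the encoding
#'     signals used, and the per-electrode gain matrix}
#' @export
generate_recording <- function(stimuli, sources, agent_posteriors = NULL,
                               spec = recording_spec(), seed = 1L) {
  stopifnot(inherits(stimuli, "stimulus_train"),
            inherits(sources, "source_train"),
            inherits(spec, "recording_spec"))
  n_t <- nrow(stimuli$outcomes)
  if (nrow(sources$states) != n_t) {
    stop("sources and stimuli must cover the same epochs", call. = FALSE)
  }
  n_e <- spec$n_electrodes
  tt <- (seq_len(n_t) - 0.5) / n_t   # epoch fraction of training

  if (spec$learning_curve == "agent") {
    if (is.null(agent_posteriors)) {
      stop("agent-driven learning curve requires agent_posteriors",
           call. = FALSE)
    }
    m <- as.matrix(agent_posteriors)
    if (nrow(m) != n_t || ncol(m) != 2) {
      stop("agent_posteriors must be an epochs x 2 matrix covering all epochs",
           call. = FALSE)
    }
    g <- rep(1, n_t)
  } else {
    m <- sources$states
    g <- 1 / (1 + exp(-(tt - spec$sigmoid_midpoint) / spec$sigmoid_slope))
  }

  # own-site stimulation indicator per electrode: electrode at grid position
  # p is stimulated when p is one of the 32 mapped sites and that site fired
  own <- matrix(0L, n_e, n_t)
  for (idx in seq_along(stimuli$site_map)) {
    pos <- stimuli$site_map[idx] + 1L   # 1-based electrode index
    if (pos <= n_e) own[pos, ] <- stimuli$outcomes[, idx]
  }

  # source-selective deviation, electrodes x epochs
  dev1 <- spec$specialisation_gain[, 1] %o% (g * 2 * (m[, 1] - 0.5))
  dev2 <- spec$specialisation_gain[, 2] %o% (g * 2 * (m[, 2] - 0.5))

  seed_streams <- derive_seed(seed, "recording")
  drift <- matrix(0, n_e, n_t)
  if (spec$drift_order > 0 && spec$drift_amplitude > 0) {
    drift <- with_seed(derive_seed(seed, "drift"), {
      basis <- sapply(seq_len(spec$drift_order), function(k) {
        cos(pi * k * tt)
      })
      coef <- matrix(stats::rnorm(n_e * spec$drift_order,
                                  sd = spec$drift_amplitude),
                     n_e, spec$drift_order)
      coef %*% t(basis)
    })
  }

  log_rate <- log(spec$baseline) + spec$stim_gain * own + dev1 + dev2 + drift
  rate <- exp(log_rate)
  counts <- if (spec$noise == "poisson") {
    with_seed(seed_streams, {
      matrix(stats::rpois(n_e * n_t, as.vector(rate)), n_e, n_t)
    })
  } else {
    rate
  }
  rownames(counts) <- paste0("e", seq_len(n_e))
  structure(
    list(counts = counts, session = stimuli$session,
         ground_truth = list(spec = spec, learning_curve = g,
                             encoding_signal = m,
                             specialisation_gain = spec$specialisation_gain,
                             seed = seed)),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d electrodes x %d epochs, mean count %.2f\n",
              nrow(x$counts), ncol(x$counts), mean(x$counts)))
  invisible(x)
}

#' Surrogate (randomised) source trains
#'
#' Permutes the epoch order of each source train independently. Marginal
#' source rates are preserved exactly while the alignment between sources
#' and stimuli is destroyed — the nonparametric null control: any apparent
#' specialisation detected against surrogate sources is artefactual.
#'
#' @param sources a `source_train`.
#' @param seed integer seed.
#' @return a `source_train` with permuted states.
#' @export
surrogate_sources <- function(sources, seed = 1L) {
  stopifnot(inherits(sources, "source_train"))
  n <- nrow(sources$states)
  states <- with_seed(derive_seed(seed, "surrogate"), {
    cbind(sources$states[sample.int(n), 1],
          sources$states[sample.int(n), 2])
  })
  colnames(states) <- c("s1", "s2")
  out <- sources
  out$states <- states
  out$surrogate <- TRUE
  out
}

#' Write / read a response matrix
#'
#' TSV with electrode rows and epoch columns, plus a JSON sidecar holding
#' session structure and ground truth. The reader validates the schema
#' (integer, non-negative counts; consistent epoch counts) and reports the
#' offending line on failure, so externally supplied spike-count tables of
#' the same shape can be ingested.
#'
#' @param rm_ a `response_matrix`.
#' @param path TSV path; sidecar at `paste0(path, ".json")`.
#' @return the path invisibly; `read_response_matrix()` returns a
#'   `response_matrix`.
#' @export
write_response_matrix <- function(rm_, path) {
  stopifnot(inherits(rm_, "response_matrix"))
  df <- data.frame(electrode = seq_len(nrow(rm_$counts)), rm_$counts,
                   check.names = FALSE)
  colnames(df) <- c("electrode", paste0("t", seq_len(ncol(rm_$counts))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- rm_$ground_truth
  jsonlite::write_json(
    list(session = rm_$session,
         ground_truth = list(
           learning_curve = gt$learning_curve,
           specialisation_gain = gt$specialisation_gain,
           seed = gt$seed,
           noise = gt$spec$noise,
           learning_curve_mode = gt$spec$learning_curve
         )),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"electrode" %in% colnames(df)) {
    stop("response matrix TSV must have an 'electrode' column", call. = FALSE)
  }
  counts <- as.matrix(df[, setdiff(colnames(df), "electrode"), drop = FALSE])
  bad <- which(rowSums(counts < 0 | !is.finite(counts)) > 0)
  if (length(bad)) {
    stop(sprintf("negative or non-finite count on line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  }
  bad_int <- which(rowSums(counts != round(counts)) > 0)
  if (length(bad_int)) {
    stop(sprintf("non-integer count on line %d of %s", bad_int[1] + 1L, path),
         call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(session = rep(1L, ncol(counts)))
  }
  if (length(meta$session) != ncol(counts)) {
    stop("session metadata length does not match epoch count", call. = FALSE)
  }
  gt <- meta$ground_truth
  if (!is.null(gt$specialisation_gain)) {
    gt$specialisation_gain <- as.matrix(gt$specialisation_gain)
  }
  counts <- unname(counts)
  rownames(counts) <- paste0("e", seq_len(nrow(counts)))
  structure(
    list(counts = counts,
         session = as.integer(meta$session),
         ground_truth = gt),
    class = "response_matrix"
  )
}
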