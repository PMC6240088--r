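# Orchestration: one call runs simulate -> encode -> record -> detect ->
# free-energy-map, with both true and surrogate sources, and writes every
# table and figure plus a machine-readable manifest.

#' Pipeline run configuration
#'
#' Collects seeds, protocol sizes and module settings for a full pipeline
#' run. Defaults reproduce the study protocol (100 sessions of 256
#' one-second epochs; a 512-epoch simulation; 512 selected epochs smoothed
#' over 32); smaller sizes are useful for smoke tests.
#'
#' @param seed global seed, expanded into per-purpose streams.
#' @param n_sessions,epochs_per_session protocol size.
#' @param sim_epochs length of the analysis simulation (default 512).
#' @param n_select number of equally spaced epochs for the free-energy
#'   mapping (default 512).
#' @param window smoothing window in epochs (default 32).
#' @param clip_eps posterior clip bound.
#' @param mode selection rule passed to [select_responses()].
#' @param threshold F threshold for `threshold_mean`.
#' @param k_interest,k_drift GLM basis sizes.
#' @param restarts agent training restarts (see [run_training()]; default 3).
#' @param recording arguments for [recording_spec()] as a named list
#'   (stored, not evaluated, so the config serialises losslessly).
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L, n_sessions = 100L, epochs_per_session = 256L,
                       sim_epochs = 512L, n_select = 512L, window = 32L,
                       clip_eps = 1e-3,
                       mode = c("max_f", "threshold_mean", "cva"),
                       threshold = 80, k_interest = 8L, k_drift = 32L,
                       restarts = 3L, recording = list()) {
  mode <- match.arg(mode)
  cfg <- list(seed = as.integer(seed), n_sessions = as.integer(n_sessions),
              epochs_per_session = as.integer(epochs_per_session),
              sim_epochs = as.integer(sim_epochs),
              n_select = as.integer(n_select), window = as.integer(window),
              clip_eps = clip_eps, mode = mode, threshold = threshold,
              k_interest = as.integer(k_interest),
              k_drift = as.integer(k_drift),
              restarts = as.integer(restarts), recording = recording)
  sizes <- c(cfg$n_sessions, cfg$epochs_per_session, cfg$sim_epochs,
             cfg$n_select, cfg$window)
  if (any(sizes < 1)) stop("all sizes must be positive", call. = FALSE)
  if (cfg$sim_epochs > cfg$n_sessions * cfg$epochs_per_session) {
    stop("sim_epochs cannot exceed the total epoch count", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Write a default configuration file
#'
#' Serialises a configuration (default: the full-protocol defaults) to
#' JSON; [read_run_config()] restores it losslessly.
#'
#' @param path output path.
#' @param config a `run_config`.
#' @return the path, invisibly.
#' @export
init_config <- function(path, config = run_config()) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname init_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw$recording) == 0) raw$recording <- list()
  do.call(run_config, raw)
}

#' Load a spike-count response matrix from disk
#'
#' Ingestion path for externally supplied spike-count tables with the same
#' schema as [write_response_matrix()] output (electrode rows x epoch
#' columns, TSV, optional JSON sidecar). Alias of
#' [read_response_matrix()].
#'
#' @param path TSV path.
#' @return a `response_matrix`.
#' @export
load_response_matrix <- function(path) read_response_matrix(path)

#' Run the full analysis pipeline
#'
#' Executes all stages on a fresh synthetic experiment: (1) simulate the
#' stimulation protocol; (2) run the Bayes-optimal encoder over all epochs
#' (its posteriors drive the recording generator, its first `sim_epochs`
#' epochs form the analysis simulation); (3) generate the synthetic
#' multielectrode recording; (4) detect functional specialisation for both
#' sources with the GLM, against the true and against surrogate (permuted)
#' sources; (5) map specialisation to empirical posteriors and free-energy
#' trajectories in the information plane (true-source branch; the surrogate
#' branch is mapped too, as the null control). All numeric artefacts are
#' written as TSV/CSV with a JSON manifest; figures are PDFs mirroring
#' machine-readable tables.
#'
#' @param config a `run_config`.
#' @param outdir output directory (created if needed).
#' @param write_figures write PDF figures (default TRUE).
#' @return object of class `run_manifest`: list with `config`,
#'   `config_hash`, `files`, `timings` (seconds per stage), `warnings`, and
#'   `results` (the in-memory stage outputs).
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("vfemea_"),
                         write_figures = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  timings <- c()
  warns <- character(0)
  note <- function(f) files <<- c(files, f)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  seed <- config$seed

  # -- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    sources <- sample_sources(config$n_sessions, config$epochs_per_session,
                              seed = seed)
    stimuli <- sample_stimuli(sources, true_likelihood(), seed = seed)
    f <- file.path(outdir, "experiment.tsv")
    write_stim_experiment(sources, stimuli, f)
    note(f); note(paste0(f, ".json"))
    list(sources = sources, stimuli = stimuli)
  })

  # -- encode -----------------------------------------------------------
  enc <- stage("encode", {
    n_total <- nrow(sim$sources$states)
    run <- run_training(sim$stimuli, n_epochs = n_total, keep_counts = TRUE,
                        restarts = config$restarts)
    # blind learning fixes the state labels only up to permutation; for the
    # recording generator (which knows the ground truth it emulates) the
    # agent's states are aligned to the true generative states
    perm <- resolve_state_permutation(run$a)
    marg <- relabel_posterior(run$posterior, perm$perm)$marginals
    f <- file.path(outdir, "agent")
    write_agent_snapshot(run, f)
    note(paste0(f, ".json")); note(paste0(f, "_trace.tsv"))
    list(run = run, marginals = marg, perm = perm)
  })

  # -- record -----------------------------------------------------------
  rec <- stage("record", {
    spec <- do.call(recording_spec, config$recording)
    rm_ <- generate_recording(sim$stimuli, sim$sources,
                              agent_posteriors = enc$marginals,
                              spec = spec, seed = seed)
    f <- file.path(outdir, "responses.tsv")
    write_response_matrix(rm_, f)
    note(f); note(paste0(f, ".json"))
    rm_
  })

  # -- detect -----------------------------------------------------------
  det <- stage("detect", {
    surro <- surrogate_sources(sim$sources, seed = seed)
    branches <- list(true = sim$sources, surrogate = surro)
    out <- lapply(names(branches), function(br) {
      src <- branches[[br]]
      per_source <- lapply(1:2, function(ts) {
        an <- analyse_specialisation(rec, src, sim$stimuli, test_source = ts,
                                     k_interest = config$k_interest,
                                     k_drift = config$k_drift)
        sel <- select_responses(an, mode = config$mode,
                                threshold = config$threshold)
        tab <- data.frame(
          electrode = seq_along(an$F), F = an$F,
          df1 = vapply(an$fits, function(x) x$df[1], numeric(1)),
          df2 = vapply(an$fits, function(x) x$df[2], numeric(1)),
          p = vapply(an$fits, function(x) x$p_value, numeric(1)),
          amplitude = vapply(an$fits, function(x) max(abs(x$curve)),
                             numeric(1))
        )
        f1 <- file.path(outdir, sprintf("glm_%s_source%d.tsv", br, ts))
        utils::write.table(tab, f1, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        note(f1)
        f2 <- file.path(outdir, sprintf("fmap_%s_source%d.csv", br, ts))
        utils::write.table(unclass(an$f_map), f2, sep = ",", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        note(f2)
        list(analysis = an, selection = sel)
      })
      list(sources = src, per_source = per_source)
    })
    names(out) <- names(branches)
    out
  })

  # -- fe-map -----------------------------------------------------------
  fem <- stage("fe_map", {
    sim_run <- enc$run
    sim_marg <- enc$marginals[seq_len(config$sim_epochs), , drop = FALSE]
    out <- lapply(names(det), function(br) {
      branch <- det[[br]]
      # an empty threshold selection falls back to the max-F electrode so
      # the null branch can still be mapped
      curve_of <- function(x) {
        if (isTRUE(x$selection$empty)) {
          x$analysis$fits[[which.max(x$analysis$F)]]$curve
        } else {
          x$selection$curve
        }
      }
      curves <- vapply(branch$per_source, curve_of,
                       numeric(ncol(rec$counts)))
      post <- empirical_posterior(curves, branch$sources,
                                  clip_eps = config$clip_eps)
      sim_curve <- 2 * abs(sim_marg[, 1] - 0.5)
      mapping <- match_learning_curves(curves[, 1], sim_curve,
                                       n_select = config$n_select)
      fe <- empirical_free_energy(sim$stimuli, post, mapping, sim_run,
                                  perm = enc$perm$perm)
      plane <- smooth_and_plane(fe, window = config$window)
      f1 <- file.path(outdir, sprintf("free_energy_%s.tsv", br))
      fe_out <- fe
      fe_out$F_smoothed <- NA_real_
      valid <- seq_len(nrow(plane))
      fe_out$F_smoothed[valid + (config$window - 1) %/% 2] <- plane$F
      utils::write.table(fe_out, f1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note(f1)
      f2 <- file.path(outdir, sprintf("info_plane_%s.csv", br))
      utils::write.table(as.data.frame(plane)[, c("complexity", "accuracy")],
                         f2, sep = ",", quote = FALSE, row.names = FALSE)
      note(f2)
      list(posterior = post, mapping = mapping, free_energy = fe,
           plane = plane)
    })
    names(out) <- names(det)
    out
  })

  if (write_figures) {
    stage("figures", {
      f <- file.path(outdir, "figures.pdf")
      grDevices::pdf(f, width = 7, height = 5)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot_f_map(det$true$per_source[[1]]$analysis$f_map,
                 main = "F map, source 1 (true sources)")
      plot_learning_curve(det$true$per_source[[1]]$selection,
                          sim$sources, test_source = 1)
      plot_free_energy(fem$true$plane)
      plot_info_plane(fem$true$plane)
      plot_info_plane(fem$surrogate$plane,
                      main = "Information plane (surrogate sources)")
      note(f)
      NULL
    })
  }

  cfg_file <- file.path(outdir, "config.json")
  init_config(cfg_file, config)
  note(cfg_file)
  manifest <- structure(
    list(config = config,
         config_hash = unname(tools::md5sum(cfg_file)),
         files = sort(unique(files)),
         timings = unlist(timings), warnings = warns,
         results = list(experiment = sim, encoder = enc, recording = rec,
                        detection = det, free_energy = fem)),
    class = "run_manifest"
  )
  jsonlite::write_json(
    list(config_hash = manifest$config_hash, files = basename(manifest$files),
         timings = as.list(manifest$timings), warnings = warns),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: %d files, %.1f s total\n",
              length(x$files), sum(x$timings)))
  for (nm in names(x$timings)) {
    cat(sprintf("  %-10s %6.1f s\n", nm, x$timings[[nm]]))
  }
  if (length(x$warnings)) {
    cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  }
  invisible(x)
}

# ---- figures ----------------------------------------------------------

#' Plot an F map
#'
#' Greyscale image of the 8x8 F map; lighter cells are more significant.
#'
#' @param m an `f_map`.
#' @param main title.
#' @return invisibly, `m`.
#' @export
plot_f_map <- function(m, main = "F map") {
  z <- unclass(m)
  z[is.na(z)] <- 0
  graphics::image(1:8, 1:8, t(z[8:1, ]), col = grDevices::grey.colors(64),
                  xlab = "grid column", ylab = "grid row", main = main,
                  axes = FALSE)
  graphics::axis(1, at = 1:8); graphics::axis(2, at = 1:8, labels = 8:1)
  invisible(m)
}

#' Plot the emergence of a selective response
#'
#' Epoch responses split by the presence (red) / absence (cyan) of the
#' tested source, with the fitted specialisation traces overlaid.
#'
#' @param selection a `response_selection`.
#' @param sources the experiment `source_train`.
#' @param test_source tested source.
#' @return invisibly, `selection`.
#' @export
plot_learning_curve <- function(selection, sources, test_source = 1) {
  if (isTRUE(selection$empty)) {
    graphics::plot.new()
    graphics::title("empty selection")
    return(invisible(selection))
  }
  y <- selection$series
  s <- sources$states[, test_source]
  n <- length(y)
  idx <- seq_len(n)
  graphics::plot(idx, y, col = ifelse(s == 1, grDevices::adjustcolor("red", 0.25),
                                      grDevices::adjustcolor("cyan3", 0.25)),
                 pch = 16, cex = 0.3, xlab = "epoch", ylab = "response",
                 main = sprintf("Selective response, source %d (%s)",
                                test_source, selection$mode))
  mu <- mean(y)
  graphics::lines(idx, mu + selection$fit$present, col = "red", lwd = 2)
  graphics::lines(idx, mu + selection$fit$absent, col = "cyan3", lwd = 2)
  invisible(selection)
}

#' Plot the smoothed free-energy trajectory
#'
#' Smoothed empirical free energy with the start level and the 3-nat drop
#' reference (an odds factor of about 20:1).
#'
#' @param plane an `info_plane`.
#' @return invisibly, `plane`.
#' @export
plot_free_energy <- function(plane) {
  ref <- attr(plane, "f_reference")
  graphics::plot(plane$index, plane$F, type = "l", col = "red", lwd = 2,
                 xlab = "selected epoch", ylab = "free energy (nats)",
                 main = "Smoothed empirical free energy")
  graphics::abline(h = ref["start"], lty = 2)
  graphics::abline(h = ref["minus_3nats"], lty = 3)
  invisible(plane)
}

#' Plot the variational information plane
#'
#' Accuracy against complexity across learning; the colour ramp encodes
#' time.
#'
#' @param plane an `info_plane`.
#' @param main title.
#' @return invisibly, `plane`.
#' @export
plot_info_plane <- function(plane, main = "Variational information plane") {
  n <- nrow(plane)
  cols <- grDevices::hcl.colors(n, "viridis")
  graphics::plot(plane$complexity, plane$accuracy, col = cols, pch = 16,
                 cex = 0.6, xlab = "complexity (nats)",
                 ylab = "accuracy (nats)", main = main)
  invisible(plane)
}
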