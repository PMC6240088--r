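# Detection of emerging functional specialisation: GLM with discrete cosine
# temporal basis interactions, partial F statistics, F maps over the 8x8
# grid, electrode selection rules and canonical variates analysis.

#' Orthonormal DCT-II temporal basis
#'
#' Returns the first `n_components` columns of the orthonormal DCT-II basis
#' over the epoch index; column 0 is the constant, higher columns are slow
#' cosines. Used both for the interest partition (emerging selectivity, 8
#' components) and for drift confounds (32 components).
#'
#' @param n_epochs number of rows (epochs).
#' @param n_components number of columns, between 1 and `n_epochs`.
#' @return `n_epochs` x `n_components` matrix with orthonormal columns.
#' @export
dct_basis <- function(n_epochs, n_components) {
  if (n_epochs < 1 || n_components < 1 || n_components > n_epochs) {
    stop("need 1 <= n_components <= n_epochs", call. = FALSE)
  }
  t_idx <- seq_len(n_epochs) - 0.5
  B <- vapply(seq_len(n_components) - 1L, function(k) {
    if (k == 0) rep(1 / sqrt(n_epochs), n_epochs)
    else sqrt(2 / n_epochs) * cos(pi * k * t_idx / n_epochs)
  }, numeric(n_epochs))
  colnames(B) <- paste0("dct", seq_len(n_components) - 1L)
  B
}

#' Build the specialisation design matrix
#'
#' Assembles the GLM design for one electrode and one tested source. The
#' effects of interest are the interactions between time (the first
#' `k_interest` orthonormal DCT columns, including the constant) and the
#' centred presence indicator of the tested source: they model a selective
#' response whose amplitude changes over training. Confounds are the
#' electrode's own-site stimulation indicator (when the electrode sits on a
#' stimulated site), the total stimulation count per epoch, `k_drift`
#' non-constant DCT drift columns, the centred main effect of the other
#' source, and the intercept. Centring the source indicator makes the
#' interaction partition orthogonal to the intercept by construction.
#'
#' @param sources a `source_train`.
#' @param stimuli a `stimulus_train`.
#' @param electrode 1-based electrode index on the 8x8 grid (1..64), or `NA`
#'   for a design without an own-site column (used for averaged or
#'   multivariate responses).
#' @param test_source which source's emerging selectivity is tested (1 or 2).
#' @param k_interest number of interest DCT components (default 8).
#' @param k_drift number of drift DCT components (default 32).
#' @return object of class `design_matrix`: list with `X` (epochs x
#'   columns), `interest` and `confound` column indices, `labels`,
#'   `test_source`, `indicator_mean` (mean of the tested source indicator),
#'   `dct_interest` (the raw interest basis), and `rank_deficient` flag.
#' @export
build_design <- function(sources, stimuli, electrode = NA,
                         test_source = 1, k_interest = 8, k_drift = 32) {
  stopifnot(inherits(sources, "source_train"),
            inherits(stimuli, "stimulus_train"))
  n <- nrow(sources$states)
  if (nrow(stimuli$outcomes) != n) {
    stop("sources and stimuli must have aligned epochs", call. = FALSE)
  }
  if (!test_source %in% c(1, 2)) stop("test_source must be 1 or 2",
                                      call. = FALSE)
  s_test <- sources$states[, test_source]
  s_other <- sources$states[, 3 - test_source]
  mbar <- mean(s_test)
  x_test <- s_test - mbar

  dct_int <- dct_basis(n, k_interest)
  interest <- dct_int * x_test
  colnames(interest) <- paste0("src", test_source, ":dct",
                               seq_len(k_interest) - 1L)

  own <- NULL
  if (!is.na(electrode)) {
    pos0 <- electrode - 1L
    hit <- match(pos0, stimuli$site_map)
    if (!is.na(hit)) {
      own <- matrix(stimuli$outcomes[, hit], ncol = 1,
                    dimnames = list(NULL, "own_site_stim"))
    }
  }
  total <- matrix(rowSums(stimuli$outcomes), ncol = 1,
                  dimnames = list(NULL, "total_stim"))
  drift <- dct_basis(n, k_drift + 1L)[, -1, drop = FALSE]
  colnames(drift) <- paste0("drift", seq_len(k_drift))
  other <- matrix(s_other - mean(s_other), ncol = 1,
                  dimnames = list(NULL, paste0("src", 3 - test_source,
                                               "_main")))
  intercept <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))

  conf <- cbind(own, total, drift, other, intercept)
  X <- cbind(interest, conf)
  interest_idx <- seq_len(ncol(interest))
  confound_idx <- ncol(interest) + seq_len(ncol(conf))
  rank_def <- qr(X)$rank < ncol(X)

  structure(
    list(X = X, interest = interest_idx, confound = confound_idx,
         labels = colnames(X), test_source = test_source,
         indicator_mean = mbar, dct_interest = dct_int,
         rank_deficient = rank_def),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d epochs, %d interest + %d confound columns (source %d)%s\n",
              nrow(x$X), length(x$interest), length(x$confound),
              x$test_source,
              if (x$rank_deficient) " [rank deficient]" else ""))
  invisible(x)
}

#' Fit the specialisation GLM to one response series
#'
#' Ordinary least squares with a partial (extra-sum-of-squares) F test of
#' the interest partition: `F = [(RSS_confounds - RSS_full)/p] /
#' [RSS_full/(n - rank(X))]`. The fitted interaction component is rendered
#' as the predicted response in the presence and absence of the tested
#' source; their difference per epoch is the learning curve of
#' specialisation.
#'
#' @param y numeric response per epoch (one electrode's counts, an averaged
#'   series, or a canonical variate).
#' @param design a `design_matrix`.
#' @return object of class `glm_fit`: list with `coefficients`, `sigma2`,
#'   `F`, `df` (c(p, n - rank)), `p_value`, `present`, `absent` (fitted
#'   interaction traces under the two source states), `curve`
#'   (present - absent, the per-epoch specialisation magnitude), `rss_full`,
#'   `rss_reduced`, and `rank_deficient` flag inherited from the design.
#' @export
fit_glm <- function(y, design) {
  stopifnot(inherits(design, "design_matrix"))
  y <- as.numeric(y)
  n <- nrow(design$X)
  if (length(y) != n) stop("response length must match design rows",
                           call. = FALSE)
  if (!all(is.finite(y))) stop("response must be finite", call. = FALSE)
  if (stats::var(y) == 0) stop("zero-variance response", call. = FALSE)

  X <- design$X
  qr_full <- qr(X)
  r_full <- qr_full$rank
  if (r_full < ncol(X)) {
    warning("near-singular design; coefficients from pivoted least squares")
  }
  beta <- qr.coef(qr_full, y)
  beta[is.na(beta)] <- 0
  res <- y - X %*% beta
  rss_full <- sum(res^2)

  Xc <- X[, design$confound, drop = FALSE]
  qr_red <- qr(Xc)
  rss_red <- sum(qr.resid(qr_red, y)^2)

  p_eff <- r_full - qr_red$rank
  df2 <- n - r_full
  if (p_eff < 1 || df2 < 1) {
    Fstat <- NA_real_
    pval <- NA_real_
  } else {
    Fstat <- max(0, ((rss_red - rss_full) / p_eff) / (rss_full / df2))
    pval <- stats::pf(Fstat, p_eff, df2, lower.tail = FALSE)
  }

  beta_int <- beta[design$interest]
  mix <- as.numeric(design$dct_interest %*% beta_int)
  mbar <- design$indicator_mean
  present <- mix * (1 - mbar)
  absent <- mix * (0 - mbar)

  structure(
    list(coefficients = beta, sigma2 = rss_full / max(df2, 1),
         F = Fstat, df = c(p_eff, df2), p_value = pval,
         present = present, absent = absent, curve = present - absent,
         rss_full = rss_full, rss_reduced = rss_red,
         test_source = design$test_source,
         rank_deficient = design$rank_deficient),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit (source %d): F(%d, %d) = %.2f, p = %.3g\n",
              x$test_source, x$df[1], x$df[2], x$F, x$p_value))
  invisible(x)
}

#' Fit the specialisation GLM at every electrode
#'
#' Convenience wrapper: builds the per-electrode design (they differ only in
#' the own-site stimulation confound) and fits every row of a response
#' matrix, for one tested source.
#'
#' @param recording a `response_matrix`.
#' @param sources,stimuli the experiment trains.
#' @param test_source tested source (1 or 2).
#' @param k_interest,k_drift basis sizes (see [build_design()]).
#' @return object of class `specialisation_analysis`: list with `fits` (one
#'   `glm_fit` per electrode), `F` (vector), `f_map` (8x8 matrix),
#'   `test_source`, and the inputs needed by [select_responses()].
#' @export
analyse_specialisation <- function(recording, sources, stimuli,
                                   test_source = 1, k_interest = 8,
                                   k_drift = 32) {
  stopifnot(inherits(recording, "response_matrix"))
  n_e <- nrow(recording$counts)
  fits <- vector("list", n_e)
  for (e in seq_len(n_e)) {
    d <- build_design(sources, stimuli, electrode = e,
                      test_source = test_source,
                      k_interest = k_interest, k_drift = k_drift)
    fits[[e]] <- fit_glm(recording$counts[e, ], d)
  }
  Fv <- vapply(fits, function(f) f$F, numeric(1))
  structure(
    list(fits = fits, F = Fv, f_map = f_map(Fv),
         test_source = test_source, k_interest = k_interest,
         k_drift = k_drift, recording = recording, sources = sources,
         stimuli = stimuli),
    class = "specialisation_analysis"
  )
}

#' @export
print.specialisation_analysis <- function(x, ...) {
  cat(sprintf("specialisation_analysis (source %d): max F = %.1f at electrode %d; %d electrodes with F > 80\n",
              x$test_source, max(x$F), which.max(x$F), sum(x$F > 80)))
  invisible(x)
}

#' F map over the electrode grid
#'
#' Places per-electrode F values at their grid coordinates (0-based
#' row-major positions on the 8x8 array). Positions without a value are
#' `NA`.
#'
#' @param f_values numeric vector of F statistics.
#' @param positions 0-based grid positions, one per value (default
#'   `seq_along(f_values) - 1`, i.e. all 64 electrodes in order).
#' @return 8x8 matrix of F values (class `f_map`).
#' @export
f_map <- function(f_values, positions = seq_along(f_values) - 1L) {
  if (length(f_values) != length(positions)) {
    stop("one position per F value required", call. = FALSE)
  }
  if (any(f_values < 0, na.rm = TRUE)) stop("F values must be >= 0",
                                            call. = FALSE)
  m <- matrix(NA_real_, 8, 8)
  # row-major 0-based: position p -> row p %/% 8 + 1, col p %% 8 + 1
  m[cbind(positions %/% 8 + 1L, positions %% 8 + 1L)] <- f_values
  structure(m, class = c("f_map", "matrix"))
}

#' Select specialised responses and extract the learning curve
#'
#' Summarises a specialisation analysis by one of the three data features:
#' \describe{
#'   \item{max_f}{the single electrode with the largest F value.}
#'   \item{threshold_mean}{the average response over electrodes whose F
#'     exceeds `threshold` (default 80), refitted with the GLM.}
#'   \item{cva}{the principal canonical variate over all electrodes (see
#'     [cva()]), refitted with the GLM.}
#' }
#'
#' @param analysis a `specialisation_analysis`.
#' @param mode selection rule.
#' @param threshold F threshold for `threshold_mean`.
#' @return object of class `response_selection`: list with `mode`,
#'   `selected` (electrode indices; empty when no electrode passes),
#'   `series` (the selected response per epoch), `fit` (its `glm_fit`) and
#'   `curve` (the per-epoch specialisation magnitude); `empty = TRUE` marks
#'   an empty selection.
#' @export
select_responses <- function(analysis,
                             mode = c("max_f", "threshold_mean", "cva"),
                             threshold = 80) {
  stopifnot(inherits(analysis, "specialisation_analysis"))
  mode <- match.arg(mode)
  rec <- analysis$recording
  mk_design <- function() {
    build_design(analysis$sources, analysis$stimuli, electrode = NA,
                 test_source = analysis$test_source,
                 k_interest = analysis$k_interest,
                 k_drift = analysis$k_drift)
  }
  if (mode == "max_f") {
    e <- which.max(analysis$F)
    out <- list(mode = mode, selected = e,
                series = as.numeric(rec$counts[e, ]),
                fit = analysis$fits[[e]],
                curve = analysis$fits[[e]]$curve, empty = FALSE)
  } else if (mode == "threshold_mean") {
    pass <- which(analysis$F > threshold)
    if (length(pass) == 0) {
      out <- list(mode = mode, selected = integer(0), series = NULL,
                  fit = NULL, curve = NULL, empty = TRUE)
    } else {
      series <- colMeans(rec$counts[pass, , drop = FALSE])
      fit <- fit_glm(series, mk_design())
      out <- list(mode = mode, selected = pass, series = series,
                  fit = fit, curve = fit$curve, empty = FALSE)
    }
  } else {
    d <- mk_design()
    cv <- cva(t(rec$counts), d)
    fit <- fit_glm(cv$variate, d)
    # the canonical variate's sign is arbitrary; orient it so the fitted
    # specialisation peaks positive (response larger when the source is
    # present), matching the electrode convention
    if (fit$curve[which.max(abs(fit$curve))] < 0) {
      cv$variate <- -cv$variate
      cv$weights <- -cv$weights
      fit <- fit_glm(cv$variate, d)
    }
    out <- list(mode = mode, selected = which.max(abs(cv$weights)),
                series = as.numeric(cv$variate), fit = fit,
                curve = fit$curve, cva = cv, empty = FALSE)
  }
  structure(out, class = "response_selection")
}

#' @export
print.response_selection <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat(sprintf("response_selection (%s): empty selection\n", x$mode))
  } else {
    cat(sprintf("response_selection (%s): %d electrode(s), peak |specialisation| %.3f\n",
                x$mode, length(x$selected), max(abs(x$curve))))
  }
  invisible(x)
}

#' Canonical variates analysis of multielectrode responses
#'
#' Finds the linear mixture of electrode responses maximally explained by
#' the interest partition of the design, after removing confounds from both
#' sides. Confounds are projected out; the principal canonical pair between
#' the adjusted responses and adjusted interest regressors is computed from
#' the singular value decomposition of the overlap of their orthonormal
#' bases (small singular directions of the response covariance are
#' truncated, a spectral form of ridge regularisation; the effective rank is
#' reported). Significance of the canonical correlations uses Bartlett's
#' chi-squared approximation with degrees of freedom corrected for the
#' confounds removed.
#'
#' @param Y epochs x electrodes response matrix.
#' @param design a `design_matrix` (its interest/confound partition is
#'   used).
#' @param cond_tol relative singular-value cutoff for the response subspace
#'   (default 1e-8).
#' @return object of class `cva_fit`: list with `weights` (electrode
#'   weights of the first canonical variate, unit-norm variate scaling),
#'   `variate` (epochs), `correlation` (first canonical correlation),
#'   `correlations` (all), `p_value` (Bartlett test of any canonical
#'   association), `rank_y` (retained response rank).
#' @export
cva <- function(Y, design, cond_tol = 1e-8) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n != nrow(design$X)) stop("Y rows must match design rows", call. = FALSE)
  Xc <- design$X[, design$confound, drop = FALSE]
  Xi <- design$X[, design$interest, drop = FALSE]
  qr_c <- qr(Xc)
  Ya <- qr.resid(qr_c, Y)
  Xa <- qr.resid(qr_c, Xi)

  sy <- svd(Ya)
  keep_y <- which(sy$d > cond_tol * max(sy$d))
  sx <- svd(Xa)
  keep_x <- which(sx$d > cond_tol * max(sx$d))
  if (length(keep_y) == 0 || length(keep_x) == 0) {
    stop("degenerate responses or interest partition", call. = FALSE)
  }
  Uy <- sy$u[, keep_y, drop = FALSE]
  Ux <- sx$u[, keep_x, drop = FALSE]
  sv <- svd(crossprod(Ux, Uy))
  rho <- pmin(pmax(sv$d, 0), 1)

  # first canonical variate in response space, unit norm
  variate <- Uy %*% sv$v[, 1]
  weights <- sy$v[, keep_y, drop = FALSE] %*%
    (sv$v[, 1] / sy$d[keep_y])

  p <- length(keep_x)
  q <- length(keep_y)
  n_eff <- n - qr_c$rank
  lambda <- prod(1 - rho[seq_len(min(p, q))]^2)
  stat <- -(n_eff - 1 - (p + q + 1) / 2) * log(max(lambda, .Machine$double.xmin))
  pval <- stats::pchisq(stat, df = p * q, lower.tail = FALSE)

  structure(
    list(weights = as.numeric(weights), variate = as.numeric(variate),
         correlation = rho[1], correlations = rho,
         p_value = pval, rank_y = q, rank_x = p),
    class = "cva_fit"
  )
}

#' @export
print.cva_fit <- function(x, ...) {
  cat(sprintf("cva_fit: first canonical correlation %.3f (p = %.3g), response rank %d\n",
              x$correlation, x$p_value, x$rank_y))
  invisible(x)
}
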