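#' Specification of one evoked response component
#'
#' Describes a spatially and temporally circumscribed evoked response: its
#' analysis window (start-inclusive, end-exclusive, within the -200..800 ms
#' epoch), the planted linear dependence of its window amplitude on the
#' predictors, and the noise model. Per participant, amplitudes are scaled
#' by a lognormal gain and shifted by a normal offset (the inter-individual
#' variation that within-participant z-scoring is meant to remove); trials
#' add Gaussian noise.
#'
#' @param name Component name.
#' @param peak_ms Peak latency in ms.
#' @param window_ms `c(start, end)` analysis window in ms.
#' @param baseline Baseline window amplitude (nAm).
#' @param beta Named numeric vector: amplitude change per unit of each
#'   predictor (standardized predictors give standardized effects).
#' @param noise_trial_sd Trial noise SD (nAm).
#' @param participant_gain_sdlog SD of the log of the participant gain
#'   (lognormal with median 1).
#' @param participant_offset_sd SD of the participant offset (nAm).
#' @param bump_sd_ms SD of the Gaussian bump used by
#'   [simulate_timecourses()].
#' @param epoch_ms Epoch bounds in ms.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, peak_ms, window_ms, baseline = 0,
                           beta = numeric(), noise_trial_sd = 0,
                           participant_gain_sdlog = 0.2,
                           participant_offset_sd = 2,
                           bump_sd_ms = 50,
                           epoch_ms = c(-200, 800)) {
  stopifnot(length(window_ms) == 2, window_ms[1] < window_ms[2])
  if (window_ms[1] < epoch_ms[1] || window_ms[2] > epoch_ms[2]) {
    stop("analysis window must lie within the epoch", call. = FALSE)
  }
  stopifnot(noise_trial_sd >= 0, participant_gain_sdlog >= 0,
            participant_offset_sd >= 0)
  structure(list(name = name, peak_ms = peak_ms, window_ms = window_ms,
                 baseline = baseline, beta = beta,
                 noise_trial_sd = noise_trial_sd,
                 participant_gain_sdlog = participant_gain_sdlog,
                 participant_offset_sd = participant_offset_sd,
                 bump_sd_ms = bump_sd_ms, epoch_ms = epoch_ms),
            class = "component_spec")
}

#' Solve the trial-noise SD for a target explained variance
#'
#' On standardized predictors with correlation matrix `corr`, the planted
#' linear effect explains `v = beta' corr beta` of the response variance;
#' the Gaussian noise SD that makes the population R-squared equal
#' `r_squared` is `sqrt(v (1 - R2) / R2)`. When the analysis averages
#' responses over `n_participants` before regressing (the item-level
#' pipeline), independent trial noise shrinks by `1 / n_participants` in
#' variance, so the per-trial SD achieving the item-level target is larger
#' by `sqrt(n_participants)`.
#'
#' @param beta Named standardized coefficients.
#' @param corr Correlation matrix covering `names(beta)`.
#' @param r_squared Target population R-squared (0 < R2 <= 1) at the
#'   item level.
#' @param n_participants Number of participants averaged over downstream
#'   (1 = calibrate at the level the regression runs on).
#' @return Noise standard deviation (same scale as the response).
#' @export
calibrate_noise_sd <- function(beta, corr, r_squared, n_participants = 1) {
  stopifnot(r_squared > 0, r_squared <= 1, n_participants >= 1)
  nm <- names(beta)
  if (!all(nm %in% rownames(corr))) stop("beta names missing from corr", call. = FALSE)
  v <- drop(t(beta) %*% corr[nm, nm, drop = FALSE] %*% beta)
  sqrt(v * (1 - r_squared) / r_squared) * sqrt(n_participants)
}

#' Draw standardized predictors with a given correlation structure
#'
#' Samples `n_items` rows from a multivariate normal with zero mean, unit
#' variances and the requested correlation matrix. A minimally indefinite
#' matrix (tiny negative eigenvalues from rounded printed correlations) is
#' repaired by clipping eigenvalues at zero and rescaling to unit diagonal,
#' with a warning; matrices indefinite beyond `repair_tol` are an error.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param n_items Number of rows.
#' @param seed Integer seed.
#' @param repair_tol Most negative admissible eigenvalue.
#' @return Tibble of predictor columns named from `corr`.
#' @export
simulate_predictors_from_correlations <- function(corr, n_items, seed,
                                                  repair_tol = 1e-6) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("diagonal must be 1", call. = FALSE)
  var_names <- colnames(corr) %||% paste0("x", seq_len(ncol(corr)))
  e <- eigen(corr, symmetric = TRUE)
  if (min(e$values) < -repair_tol) {
    stop("correlation matrix is not positive semi-definite (min eigenvalue ",
         format(min(e$values)), ")", call. = FALSE)
  }
  if (min(e$values) < 0) {
    warning("clipping ", sum(e$values < 0), " slightly negative eigenvalue(s)")
    e$values <- pmax(e$values, 0)
    corr <- e$vectors %*% diag(e$values) %*% t(e$vectors)
    d <- sqrt(diag(corr))
    corr <- corr / tcrossprod(d)
    e <- eigen(corr, symmetric = TRUE)
  }
  root <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  set.seed(derive_seed(seed, "predictor_draw"))
  z <- matrix(stats::rnorm(n_items * ncol(corr)), n_items) %*% root
  colnames(z) <- var_names
  tibble::as_tibble(z)
}

#' Simulate component window amplitudes for items by participants
#'
#' The window amplitude of item `i`, participant `s`, component `c` is
#' `gain[s, c] * (baseline[c] + sum_j beta[c, j] x[i, j] + trial noise) +
#' offset[s, c]`, deterministic given the seed.
#'
#' @param X Predictor tibble (or data frame); must contain every column a
#'   component's `beta` references, with no missing values there.
#' @param components List of [component_spec()]s.
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @param items Optional item identifiers (defaults to `X$item` or row
#'   numbers).
#' @return Tibble `item`, `participant`, `component`, `amplitude` (nAm)
#'   with attribute `units = "nAm"`.
#' @export
simulate_amplitudes <- function(X, components, n_participants, seed,
                                items = NULL) {
  if (inherits(components, "component_spec")) components <- list(components)
  items <- items %||% X[["item"]] %||% paste0("i", seq_len(nrow(X)))
  n_items <- nrow(X)
  set.seed(derive_seed(seed, "amplitudes"))
  out <- vector("list", length(components))
  for (k in seq_along(components)) {
    sp <- components[[k]]
    miss <- setdiff(names(sp$beta), names(X))
    if (length(miss) > 0) {
      stop("component ", sp$name, " references missing predictor(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    xb <- if (length(sp$beta) > 0) {
      xs <- as.matrix(X[names(sp$beta)])
      if (anyNA(xs)) {
        stop("component ", sp$name, " references a masked (NA) predictor column",
             call. = FALSE)
      }
      drop(xs %*% sp$beta)
    } else {
      rep(0, n_items)
    }
    gain <- exp(stats::rnorm(n_participants, 0, sp$participant_gain_sdlog))
    offset <- stats::rnorm(n_participants, 0, sp$participant_offset_sd)
    noise <- matrix(stats::rnorm(n_items * n_participants, 0, sp$noise_trial_sd),
                    n_items, n_participants)
    amp <- (sp$baseline + xb + noise) %*% diag(gain, n_participants) +
      matrix(offset, n_items, n_participants, byrow = TRUE)
    out[[k]] <- tibble::tibble(
      item = rep(items, n_participants),
      participant = rep(paste0("p", seq_len(n_participants)), each = n_items),
      component = sp$name,
      amplitude = as.vector(amp)
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "units") <- "nAm"
  res
}

#' Expand window amplitudes into evoked time courses
#'
#' Each amplitude becomes a Gaussian bump centered at the component's peak
#' latency, scaled so that the mean over the analysis window exactly
#' reproduces the input amplitude (start-inclusive, end-exclusive sampling
#' at 1 kHz over the -200..800 ms epoch). By default participants are
#' averaged per item first to keep the result compact; set
#' `by = "participant"` to keep the participant dimension.
#'
#' @param amplitudes Tibble from [simulate_amplitudes()] (columns `item`,
#'   `participant`, `component`, `amplitude`).
#' @param components List of [component_spec()]s (a named lookup by
#'   component name).
#' @param by `"item"` (average participants) or `"participant"`.
#' @return Tibble with columns `item` (, `participant`), `component`,
#'   `time_ms`, `amplitude`.
#' @export
simulate_timecourses <- function(amplitudes, components, by = c("item", "participant")) {
  by <- match.arg(by)
  if (inherits(components, "component_spec")) components <- list(components)
  names(components) <- vapply(components, function(s) s$name, character(1))
  base <- if (by == "item") {
    dplyr::summarise(amplitudes, amplitude = mean(.data$amplitude),
                     .by = c("item", "component"))
  } else {
    amplitudes
  }
  grp <- split(base, base$component)
  out <- lapply(names(grp), function(nm) {
    sp <- components[[nm]]
    if (is.null(sp)) stop("no component_spec for component ", nm, call. = FALSE)
    tt <- seq(sp$epoch_ms[1], sp$epoch_ms[2] - 1)
    g <- exp(-(tt - sp$peak_ms)^2 / (2 * sp$bump_sd_ms^2))
    win <- tt >= sp$window_ms[1] & tt < sp$window_ms[2]
    g <- g / mean(g[win]) # window mean of the trace equals the amplitude
    d <- grp[[nm]]
    idx <- rep(seq_len(nrow(d)), each = length(tt))
    res <- d[idx, setdiff(names(d), "amplitude")]
    res$time_ms <- rep(tt, nrow(d))
    res$amplitude <- rep(d$amplitude, each = length(tt)) * rep(g, nrow(d))
    res
  })
  dplyr::bind_rows(out)
}

#' Simulate lexical-decision behavior (reaction times and accuracy)
#'
#' Per trial: `RT = baseline + sum_j beta[j] x[i, j] + participant offset +
#' Gaussian noise`, truncated below at 1 ms. Correctness is Bernoulli with
#' a per-participant accuracy drawn around the configured mean (accuracy is
#' predictor-independent).
#'
#' @param X Predictor tibble.
#' @param rt_betas Named vector, ms per predictor unit.
#' @param rt_baseline Baseline RT in ms.
#' @param noise_sd Trial noise SD in ms.
#' @param participant_offset_sd Participant offset SD in ms.
#' @param accuracy_mean,accuracy_sd Mean and SD of the per-participant
#'   probability of a correct response (truncated to (0, 1]).
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @param items Optional item identifiers.
#' @return Tibble `participant`, `item`, `rt_ms`, `correct`.
#' @export
simulate_behavior <- function(X, rt_betas = numeric(), rt_baseline = 852,
                              noise_sd = 95, participant_offset_sd = 30,
                              accuracy_mean = 0.92, accuracy_sd = 0.04,
                              n_participants = 20, seed = 1, items = NULL) {
  stopifnot(accuracy_mean > 0, accuracy_mean <= 1)
  items <- items %||% X[["item"]] %||% paste0("i", seq_len(nrow(X)))
  n_items <- nrow(X)
  miss <- setdiff(names(rt_betas), names(X))
  if (length(miss) > 0) {
    stop("rt_betas references missing predictor(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  xb <- if (length(rt_betas) > 0) {
    drop(as.matrix(X[names(rt_betas)]) %*% rt_betas)
  } else {
    rep(0, n_items)
  }
  set.seed(derive_seed(seed, "behavior"))
  offset <- stats::rnorm(n_participants, 0, participant_offset_sd)
  p_corr <- pmin(pmax(stats::rnorm(n_participants, accuracy_mean, accuracy_sd),
                      1e-6), 1)
  rt <- rt_baseline + rep(xb, n_participants) +
    rep(offset, each = n_items) +
    stats::rnorm(n_items * n_participants, 0, noise_sd)
  rt <- pmax(rt, 1)
  correct <- stats::runif(n_items * n_participants) <
    rep(p_corr, each = n_items)
  tibble::tibble(
    participant = rep(paste0("p", seq_len(n_participants)), each = n_items),
    item = rep(items, n_participants),
    rt_ms = rt,
    correct = correct
  )
}

#' Flag trials that fail the behavioral validity rules
#'
#' A trial is kept iff the response was correct and the RT lies in
#' `[min_rt, max_rt]` ms; others are flagged with a reason (`incorrect`,
#' `too_fast` for anticipations before `min_rt`, `timeout` beyond
#' `max_rt`). The operation is idempotent.
#'
#' @param trials Tibble with columns `participant`, `item`, `rt_ms`,
#'   `correct`.
#' @param min_rt,max_rt Validity window in ms.
#' @return The trials tibble with added logical `rejected` and character
#'   `reason` (`NA` for kept trials) columns.
#' @export
apply_trial_filters <- function(trials, min_rt = 350, max_rt = 1500) {
  trials$reason <- dplyr::case_when(
    !trials$correct ~ "incorrect",
    trials$rt_ms < min_rt ~ "too_fast",
    trials$rt_ms > max_rt ~ "timeout",
    TRUE ~ NA_character_
  )
  trials$rejected <- !is.na(trials$reason)
  trials
}

#' Tabulate rejection reasons
#'
#' @param trials Output of [apply_trial_filters()].
#' @return Tibble `reason`, `n` (kept trials appear as reason `kept`).
#' @export
rejection_log <- function(trials) {
  if (!"reason" %in% names(trials)) trials <- apply_trial_filters(trials)
  trials |>
    dplyr::mutate(reason = dplyr::coalesce(.data$reason, "kept")) |>
    dplyr::count(.data$reason, name = "n") |>
    dplyr::arrange(.data$reason)
}

#' Retain participants with enough valid trials
#'
#' Participants contributing fewer than `min_valid` valid (correct,
#' in-window) trials out of `total` are excluded from the item-level
#' analysis.
#'
#' @param trials Output of [apply_trial_filters()] (filters are applied
#'   first if absent), typically restricted to word trials.
#' @param min_valid Minimum number of valid trials.
#' @param total Nominal number of trials per participant (recorded in the
#'   log).
#' @return Character vector of retained participant ids, with a `log`
#'   attribute tabulating valid counts per participant.
#' @export
apply_participant_filter <- function(trials, min_valid = 290, total = 360) {
  if (!"rejected" %in% names(trials)) trials <- apply_trial_filters(trials)
  tab <- trials |>
    dplyr::summarise(valid = sum(!.data$rejected), .by = "participant") |>
    dplyr::mutate(total = total, retained = .data$valid >= min_valid)
  retained <- tab$participant[tab$retained]
  attr(retained, "log") <- tab
  retained
}
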