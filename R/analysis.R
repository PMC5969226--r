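#' Average a time course over an analysis window
#'
#' Arithmetic mean of the samples with `window[1] <= time_ms < window[2]`
#' (start-inclusive, end-exclusive), per item (, participant) and
#' component.
#'
#' @param timecourses Tibble with `time_ms`, `amplitude` and any of `item`,
#'   `participant`, `component`.
#' @param window `c(start, end)` in ms; must lie inside the epoch spanned
#'   by the data.
#' @return Tibble with the grouping columns and the window-mean
#'   `amplitude`.
#' @export
window_average <- function(timecourses, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  rng <- range(timecourses$time_ms)
  if (window[1] < rng[1] || window[2] > rng[2] + 1) {
    stop("window [", window[1], ", ", window[2], ") outside epoch [",
         rng[1], ", ", rng[2] + 1, ")", call. = FALSE)
  }
  keys <- intersect(c("item", "participant", "component"), names(timecourses))
  timecourses |>
    dplyr::filter(.data$time_ms >= window[1], .data$time_ms < window[2]) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .by = dplyr::all_of(keys))
}

#' Z-score amplitudes within each participant and component
#'
#' Subtracts the mean over items and divides by the SD (n-1 denominator),
#' separately per participant x component. This removes per-participant
#' gain and offset: the output is invariant under any affine transform
#' `a * x + b` (a > 0) applied to one participant's amplitudes.
#'
#' @param amplitudes Tibble `item`, `participant`, `component`,
#'   `amplitude`.
#' @return Same shape with `amplitude` replaced by its within-participant
#'   z-score.
#' @export
zscore_within_participant <- function(amplitudes) {
  chk <- amplitudes |>
    dplyr::summarise(n = dplyr::n(), s = stats::sd(.data$amplitude),
                     .by = c("participant", "component"))
  if (any(chk$n < 2)) {
    bad <- chk[chk$n < 2, ]
    stop("need >= 2 items per participant x component (first offender: ",
         bad$participant[1], " / ", bad$component[1], ")", call. = FALSE)
  }
  if (any(chk$s == 0)) {
    bad <- chk[chk$s == 0, ]
    stop("zero amplitude variance for participant ", bad$participant[1],
         ", component ", bad$component[1], call. = FALSE)
  }
  amplitudes |>
    dplyr::mutate(
      amplitude = (.data$amplitude - mean(.data$amplitude)) / stats::sd(.data$amplitude),
      .by = c("participant", "component")
    )
}

#' Average z-scored amplitudes across participants per item
#'
#' Missing trials are simply absent rows and are excluded from the mean
#' (never zero-filled); the number of contributing participants is
#' recorded per cell.
#'
#' @param amplitudes Tibble `item`, `participant`, `component`,
#'   `amplitude` (typically z-scored).
#' @param items Optional vector of item ids that must all be present; an
#'   item with no data raises an error.
#' @return Tibble `item`, `component`, `amplitude`, `n_participants`.
#' @export
average_across_items <- function(amplitudes, items = NULL) {
  out <- amplitudes |>
    dplyr::summarise(amplitude = mean(.data$amplitude),
                     n_participants = dplyr::n(),
                     .by = c("item", "component"))
  if (!is.null(items)) {
    missing <- setdiff(items, out$item)
    if (length(missing) > 0) {
      stop("no amplitude data for item(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Simple (one-predictor) correlations with F-tests
#'
#' Pearson correlation of each available predictor column with the response,
#' with the equivalent simple-regression F statistic `r^2 (n-2) / (1-r^2)`
#' on `(1, n-2)` degrees of freedom. Predictor columns that are entirely
#' `NA` (masked for the item class) are skipped; zero-variance columns are
#' an error. Significance stars follow the two conventional thresholds
#' (`*` p < .05, `**` p < .001).
#'
#' @param X Tibble of predictor columns (numeric), rows aligned with `y`.
#' @param y Numeric response vector (item-level).
#' @return Tibble `predictor`, `n`, `r`, `df1`, `df2`, `statistic`,
#'   `p_value`, `stars`.
#' @export
simple_correlations <- function(X, y) {
  X <- X[vapply(X, is.numeric, logical(1))]
  keep <- !vapply(X, function(col) all(is.na(col)), logical(1))
  X <- X[keep]
  if (length(X) == 0) stop("no available predictor columns", call. = FALSE)
  rows <- lapply(names(X), function(nm) {
    x <- X[[nm]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3) stop("need >= 3 items for predictor ", nm, call. = FALSE)
    if (stats::sd(x[ok]) == 0) stop("zero variance in predictor ", nm, call. = FALSE)
    r <- stats::cor(x[ok], y[ok])
    f <- r^2 * (n - 2) / (1 - r^2)
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
    tibble::tibble(predictor = nm, n = n, r = r, df1 = 1, df2 = n - 2,
                   statistic = f, p_value = p,
                   stars = if (p < 0.001) "**" else if (p < 0.05) "*" else "")
  })
  dplyr::bind_rows(rows)
}

# standardized OLS residual sum of squares via QR; X already standardized
rss_of <- function(Xm, y) {
  fit <- stats::lm.fit(cbind(1, Xm), y)
  sum(fit$residuals^2)
}

#' Forward stepwise regression with standardized coefficients
#'
#' Predictors and response are z-scored internally (n-1 SD), then
#' candidates are added one at a time: at each step the candidate giving
#' the largest R-squared increase enters if its partial-F p-value is below
#' `alpha`; selection stops otherwise. Coefficients of the final model are
#' therefore standardized betas. Entirely-`NA` (masked) columns are
#' skipped; ties in the R-squared increase are resolved by column order.
#'
#' @param X Tibble of candidate predictor columns.
#' @param y Numeric response.
#' @param alpha Entry threshold for the partial-F test.
#' @return An object of class `stepwise_fit`; see [tidy.stepwise_fit()] and
#'   [glance.stepwise_fit()].
#' @export
forward_stepwise <- function(X, y, alpha = 0.05) {
  X <- X[vapply(X, is.numeric, logical(1))]
  X <- X[!vapply(X, function(col) all(is.na(col)), logical(1))]
  if (length(X) == 0) stop("no available predictor columns", call. = FALSE)
  cc <- stats::complete.cases(as.data.frame(X)) & !is.na(y)
  Xm <- scale(as.matrix(X)[cc, , drop = FALSE])
  yv <- drop(scale(y[cc]))
  n <- length(yv)
  cand <- colnames(Xm)
  selected <- character(0)
  steps <- list()
  tss <- sum(yv^2)
  rss_cur <- tss
  repeat {
    remaining <- setdiff(cand, selected)
    if (length(remaining) == 0) break
    rss_new <- vapply(remaining, function(nm) {
      rss_of(Xm[, c(selected, nm), drop = FALSE], yv)
    }, numeric(1))
    best <- which.min(rss_new) # ties: first in column order
    k <- length(selected) + 1
    df2 <- n - k - 1
    f <- (rss_cur - rss_new[best]) / (rss_new[best] / df2)
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
    if (!is.finite(p) || p >= alpha) break
    selected <- c(selected, remaining[best])
    steps[[k]] <- tibble::tibble(
      step = k, predictor = remaining[best],
      r_squared = 1 - rss_new[best] / tss,
      partial_f = f, p_value = p
    )
    rss_cur <- rss_new[best]
  }
  if (length(selected) > 0) {
    d <- svd(Xm[, selected, drop = FALSE], nu = 0, nv = 0)$d
    if (max(d) / min(d) > 1e8) {
      stop("selected predictors are collinear (condition number > 1e8)",
           call. = FALSE)
    }
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xm[, selected, drop = FALSE]), yv)
    beta <- fit$coefficients[selected]
    r2 <- 1 - sum(fit$residuals^2) / tss
    k <- length(selected)
    fstat <- (r2 / k) / ((1 - r2) / (n - k - 1))
    pval <- stats::pf(fstat, k, n - k - 1, lower.tail = FALSE)
  } else {
    beta <- stats::setNames(numeric(0), character(0))
    r2 <- 0
    fstat <- NA_real_
    pval <- NA_real_
    k <- 0L
  }
  structure(
    list(selected = selected, beta = beta,
         steps = if (length(steps)) dplyr::bind_rows(steps) else
           tibble::tibble(step = integer(), predictor = character(),
                          r_squared = numeric(), partial_f = numeric(),
                          p_value = numeric()),
         r_squared = r2, statistic = fstat, df = c(k, n - k - 1),
         p_value = pval, n = n, alpha = alpha),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit> ", length(x$selected), " predictor(s) selected, R2 = ",
      sprintf("%.3f", x$r_squared), "\n", sep = "")
  if (length(x$selected)) print(x$steps)
  invisible(x)
}

#' Tidy a stepwise fit
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (standardized beta), `step`,
#'   `partial_f`, `p_value` for each selected predictor.
#' @export
tidy.stepwise_fit <- function(x, ...) {
  if (length(x$selected) == 0) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          step = integer(), partial_f = numeric(),
                          p_value = numeric()))
  }
  tibble::tibble(term = x$selected, estimate = unname(x$beta[x$selected])) |>
    dplyr::left_join(x$steps |>
                       dplyr::select(term = "predictor", step = "step",
                                     partial_f = "partial_f",
                                     p_value = "p_value"),
                     by = "term")
}

#' One-row summary of a stepwise fit
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return Tibble `r_squared`, `statistic`, `df`, `df_residual`, `p_value`,
#'   `n_selected`, `n`.
#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, statistic = x$statistic,
                 df = x$df[1], df_residual = x$df[2], p_value = x$p_value,
                 n_selected = length(x$selected), n = x$n)
}

#' Tertile-binned grand-average curves for one predictor
#'
#' Items are sorted by the predictor; the lowest `bin_size`, the highest
#' `bin_size` and `bin_size` items centered on the median form three
#' disjoint bins (ties and the median bin position resolved by the fixed
#' item order). Curves are averaged over items (and participants when
#' present) per bin and component.
#'
#' @param predictors Tibble with `item` and the predictor column.
#' @param predictor Name of the predictor column.
#' @param curves Time-resolved tibble (`item`, optional `participant`,
#'   `component`, `time_ms`, `amplitude`).
#' @param bin_size Number of items per bin.
#' @return Tibble `bin` (`low`/`mid`/`high`), `component`, `time_ms`,
#'   `amplitude`, `n_items`.
#' @export
bin_by_predictor <- function(predictors, predictor, curves, bin_size = 60) {
  stopifnot(predictor %in% names(predictors))
  x <- predictors[[predictor]]
  n <- nrow(predictors)
  if (n < 3 * bin_size) {
    stop("need at least ", 3 * bin_size, " items for three disjoint bins of ",
         bin_size, call. = FALSE)
  }
  ord <- order(x, seq_len(n))
  low <- predictors$item[ord[seq_len(bin_size)]]
  high <- predictors$item[ord[(n - bin_size + 1):n]]
  mid_start <- floor((n - bin_size) / 2) + 1
  mid <- predictors$item[ord[mid_start:(mid_start + bin_size - 1)]]
  bins <- tibble::tibble(
    item = c(low, mid, high),
    bin = factor(rep(c("low", "mid", "high"), each = bin_size),
                 levels = c("low", "mid", "high"))
  )
  curves |>
    dplyr::inner_join(bins, by = "item") |>
    dplyr::summarise(amplitude = mean(.data$amplitude),
                     n_items = dplyr::n_distinct(.data$item),
                     .by = c("bin", "component", "time_ms"))
}

#' Run the full item-level analysis stage
#'
#' Reproduces the analysis pipeline on predictor, amplitude and trial
#' tables: behavioral validity filtering, participant exclusion,
#' within-participant z-scoring of window amplitudes restricted to valid
#' trials, cross-participant item averaging, then — separately for word and
#' pseudoword items, the latter using only the four predictors defined for
#' them — simple correlations and forward stepwise regression against each
#' component amplitude and the item-mean reaction time.
#'
#' @param predictors Tibble from [build_predictor_matrix()].
#' @param amplitudes Tibble `item`, `participant`, `component`,
#'   `amplitude`.
#' @param trials Tibble `participant`, `item`, `rt_ms`, `correct`.
#' @param alpha Stepwise entry threshold.
#' @param min_rt,max_rt Trial validity window (ms).
#' @param min_valid Minimum valid word trials per participant.
#' @return An object of class `item_analysis`: list with `simple`
#'   (predictor x target correlation table), `models` (per-target stepwise
#'   summaries), `stepwise` (selected terms with standardized betas),
#'   `item_responses` (item x component z-score means plus item-mean RT),
#'   `retained_participants`, `rejections`.
#' @export
analyze <- function(predictors, amplitudes, trials, alpha = 0.05,
                    min_rt = 350, max_rt = 1500, min_valid = 290) {
  stopifnot(all(c("item", "is_word") %in% names(predictors)))
  trials <- apply_trial_filters(trials, min_rt = min_rt, max_rt = max_rt)
  word_items <- predictors$item[predictors$is_word]
  wt <- trials[trials$item %in% word_items, ]
  retained <- apply_participant_filter(wt, min_valid = min_valid,
                                       total = length(word_items))
  kept <- trials[!trials$rejected & trials$participant %in% retained, ]
  rt_item <- kept |>
    dplyr::summarise(rt_ms = mean(.data$rt_ms), .by = "item")

  amp <- amplitudes[amplitudes$participant %in% retained, ]
  amp <- dplyr::semi_join(amp, kept, by = c("item", "participant"))
  item_amp <- amp |>
    zscore_within_participant() |>
    average_across_items()

  item_wide <- item_amp |>
    tidyr::pivot_wider(id_cols = "item", names_from = "component",
                       values_from = "amplitude") |>
    dplyr::left_join(rt_item, by = "item")
  components <- setdiff(unique(item_amp$component), NA)
  targets <- c(components, "rt_ms")

  simple_rows <- list()
  model_rows <- list()
  term_rows <- list()
  for (cls in c("words", "pseudowords")) {
    is_w <- cls == "words"
    rows <- predictors$is_word == is_w
    if (!any(rows)) next
    cols <- if (is_w) predictor_names() else pseudoword_predictors()
    Xc <- predictors[rows, intersect(cols, names(predictors))]
    resp <- item_wide[match(predictors$item[rows], item_wide$item), ]
    for (tg in targets) {
      y <- resp[[tg]]
      if (is.null(y) || all(is.na(y))) next
      sc <- simple_correlations(Xc, y)
      sc$class <- cls
      sc$target <- tg
      simple_rows[[length(simple_rows) + 1]] <- sc
      fit <- forward_stepwise(Xc, y, alpha = alpha)
      g <- glance(fit)
      g$class <- cls
      g$target <- tg
      model_rows[[length(model_rows) + 1]] <- g
      td <- tidy(fit)
      if (nrow(td) > 0) {
        td$class <- cls
        td$target <- tg
        term_rows[[length(term_rows) + 1]] <- td
      }
    }
  }
  structure(
    list(
      simple = dplyr::bind_rows(simple_rows) |>
        dplyr::relocate("class", "target"),
      models = dplyr::bind_rows(model_rows) |>
        dplyr::relocate("class", "target"),
      stepwise = dplyr::bind_rows(term_rows) |>
        dplyr::relocate("class", "target"),
      item_responses = item_wide,
      retained_participants = retained,
      rejections = rejection_log(trials)
    ),
    class = "item_analysis"
  )
}

#' @export
print.item_analysis <- function(x, ...) {
  cat("<item_analysis> ", nrow(x$item_responses), " items, ",
      length(x$retained_participants), " participants retained\n", sep = "")
  print(x$models)
  invisible(x)
}
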