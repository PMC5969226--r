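#' Train a character n-gram model on a frequency table
#'
#' Counts letter transitions with start padding (`^`) and an end symbol
#' (`$`), weighting each word by its token count, and applies additive
#' smoothing over the alphabet plus the end symbol when probabilities are
#' queried.
#'
#' @param freq Frequency table (`word`, `count`).
#' @param order N-gram order (>= 2); the model conditions on `order - 1`
#'   preceding letters.
#' @param smoothing Additive smoothing constant (>= 0).
#' @param alphabet Optional letter inventory; defaults to the letters
#'   observed in `freq`.
#' @return An object of class `ngram_model`.
#' @export
#' @examples
#' freq <- tibble::tibble(word = c("ab", "ac"), count = c(3L, 1L))
#' m <- train_ngram(freq, order = 2, smoothing = 1)
#' ngram_prob(m, "a", "b")
train_ngram <- function(freq, order = 3, smoothing = 0.1, alphabet = NULL) {
  assert_freq_table(freq)
  if (order < 2) stop("`order` must be >= 2", call. = FALSE)
  if (smoothing < 0) stop("`smoothing` must be >= 0", call. = FALSE)
  alphabet <- alphabet %||% sort(unique(unlist(strsplit(freq$word, ""))))
  if (any(c("^", "$") %in% alphabet)) stop("`^` and `$` are reserved symbols", call. = FALSE)
  counts <- new.env(parent = emptyenv())
  pad <- strrep("^", order - 1)
  for (i in seq_len(nrow(freq))) {
    chars <- c(strsplit(paste0(pad, freq$word[i]), "")[[1]], "$")
    w <- freq$count[i]
    for (j in order:length(chars)) {
      hist <- paste(chars[(j - order + 1):(j - 1)], collapse = "")
      sym <- chars[j]
      cur <- counts[[hist]]
      if (is.null(cur)) cur <- numeric(0)
      cur[sym] <- (if (is.na(cur[sym])) 0 else cur[sym]) + w
      counts[[hist]] <- cur
    }
  }
  structure(
    list(order = as.integer(order), smoothing = smoothing,
         alphabet = alphabet, counts = counts),
    class = "ngram_model"
  )
}

#' @export
print.ngram_model <- function(x, ...) {
  cat("<ngram_model> order ", x$order, ", |alphabet| ", length(x$alphabet),
      ", smoothing ", x$smoothing, "\n", sep = "")
  invisible(x)
}

#' Conditional next-symbol distribution of an n-gram model
#'
#' @param model An `ngram_model`.
#' @param history String of the `order - 1` preceding symbols (use `^` for
#'   positions before the word start).
#' @param symbol Optional single symbol; if given, returns its probability,
#'   otherwise the full named distribution over the alphabet plus `$`.
#' @return Numeric probability or named probability vector (sums to 1).
#' @export
ngram_prob <- function(model, history, symbol = NULL) {
  stopifnot(inherits(model, "ngram_model"))
  if (nchar(history) != model$order - 1) {
    stop("history must have ", model$order - 1, " symbols", call. = FALSE)
  }
  symbols <- c(model$alphabet, "$")
  cnt <- stats::setNames(rep(0, length(symbols)), symbols)
  seen <- model$counts[[history]]
  if (!is.null(seen)) cnt[names(seen)] <- seen
  tot <- sum(cnt) + model$smoothing * length(symbols)
  if (tot == 0) stop("unseen history with zero smoothing: ", history, call. = FALSE)
  p <- (cnt + model$smoothing) / tot
  if (is.null(symbol)) p else unname(p[symbol])
}

#' Generate pseudowords from a character n-gram model
#'
#' Samples letter strings whose lengths exactly match `length_targets` by
#' constraining each draw to non-terminal symbols until the target length is
#' reached (the end symbol's mass is renormalized away). Outputs are unique
#' and disjoint from `exclude`; generation is deterministic given `seed`.
#'
#' @param model An `ngram_model`.
#' @param length_targets Integer vector of required lengths, one per item.
#' @param seed Integer seed.
#' @param exclude Character vector of forbidden strings (e.g. the real-word
#'   stimulus set).
#' @param max_retries Rejection-sampling cap per item before erroring.
#' @return Tibble with columns `item`, `string`, `is_word` (all `FALSE`),
#'   `length`.
#' @export
generate_pseudowords <- function(model, length_targets, seed,
                                 exclude = character(), max_retries = 10000) {
  stopifnot(inherits(model, "ngram_model"))
  set.seed(derive_seed(seed, "pseudowords"))
  exclude <- unique(exclude)
  out <- character(length(length_targets))
  taken <- new.env(parent = emptyenv())
  for (x in exclude) assign(x, TRUE, envir = taken)
  for (i in seq_along(length_targets)) {
    L <- length_targets[i]
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      s <- sample_constrained_string(model, L)
      if (is.null(s)) next
      if (!is.null(taken[[s]])) next
      out[i] <- s
      assign(s, TRUE, envir = taken)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not generate a new pseudoword of length ", L,
           " within ", max_retries, " attempts", call. = FALSE)
    }
  }
  tibble::tibble(item = paste0("pw", seq_along(out)), string = out,
                 is_word = FALSE, length = nchar(out))
}

# one constrained draw; NULL if a dead-end history is hit (possible at
# smoothing 0 when only the end symbol has mass)
sample_constrained_string <- function(model, L) {
  hist <- strrep("^", model$order - 1)
  chars <- character(L)
  for (j in seq_len(L)) {
    p <- ngram_prob(model, hist)
    p <- p[names(p) != "$"]
    if (sum(p) <= 0) return(NULL)
    p <- p / sum(p)
    chars[j] <- sample(names(p), 1, prob = p)
    hist <- substr(paste0(hist, chars[j]), 2, model$order - 1 + 1)
    if (model$order == 2) hist <- chars[j]
  }
  paste(chars, collapse = "")
}
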