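#' Derive a stage-specific sub-seed from a global run seed
#'
#' All stochastic stages of a simulation run draw their seed from one global
#' integer so that a single `seed` argument reproduces every stage, while
#' different stages (corpus generation, pseudoword sampling, response noise,
#' ...) still use statistically unrelated streams.
#'
#' @param seed Global integer seed.
#' @param stage Character label of the stage (e.g. `"corpus"`, `"responses"`).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "corpus")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(stage) == 1)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  m <- 2147483629
  as.integer((abs(seed) %% m * 48271 + h * 16807 + 12345) %% m + 1)
}

log2p <- function(x) log(x, base = 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared canonical predictor column order (Table-style listing)
predictor_names <- function() {
  c("image_complexity", "length", "bigram_surprisal", "tpl",
    "mdl_surprisal", "lemma_surprisal", "surface_surprisal")
}

# predictors defined for pseudoword items (no lemma/frequency resources)
pseudoword_predictors <- function() {
  c("image_complexity", "length", "bigram_surprisal", "mdl_surprisal")
}

assert_freq_table <- function(freq, arg = "freq") {
  if (!is.data.frame(freq) || !all(c("word", "count") %in% names(freq))) {
    stop(sprintf("`%s` must be a data frame with columns `word` and `count`", arg),
         call. = FALSE)
  }
  if (nrow(freq) == 0) stop(sprintf("`%s` is empty", arg), call. = FALSE)
  if (any(freq$count < 1)) {
    stop(sprintf("`%s` has words with count < 1", arg), call. = FALSE)
  }
  invisible(freq)
}
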