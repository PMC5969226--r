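# shared fixtures, built in code and memoized across test files

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# 30 roots x {bare, -er, -s}, 10 tokens per type: planted ground truth for
# morph-boundary recovery
planted_roots <- function() {
  c("build", "paint", "work", "play", "talk", "walk", "read", "sing", "cook",
    "jump", "hunt", "farm", "mill", "bolt", "weld", "mend", "dust", "wash",
    "pack", "lift", "drag", "drop", "push", "pull", "spin", "bend", "fold",
    "clip", "glue", "trim")
}

planted_corpus <- function() {
  memo("planted", {
    roots <- planted_roots()
    words <- c(outer(roots, c("", "er", "s"), paste0))
    freq <- tibble::tibble(word = words, count = 10L)
    gold <- tibble::tibble(
      word = words,
      morphs = c(roots, paste(roots, "er"), paste(roots, "s")),
      lemma = rep(roots, 3)
    )
    list(freq = freq, gold = gold)
  })
}

planted_model <- function() memo("planted_model", mdl_train(planted_corpus()$freq, seed = 7))

# medium synthetic corpus + 360-item stimulus set used by predictor and
# simulation tests
demo_corpus <- function() memo("demo_corpus",
                               generate_corpus(demo_grammar(150, seed = 1), 2e5, seed = 11))

demo_stimuli <- function() memo("demo_stimuli",
                                sample_stimulus_set(demo_corpus()$frequencies, 360, seed = 5))

# independent per-string exhaustive decoder used as the Viterbi oracle;
# recomputes morph costs from the model's counts and character model
# without touching the package's decoding path
oracle_min_cost <- function(model, s) {
  n <- nchar(s)
  seg_cost <- function(morphs) {
    sum(vapply(morphs, function(m) {
      cnt <- model$morph_counts[m]
      if (!is.na(cnt)) {
        -log2(unname(cnt) / model$total_morph_tokens)
      } else {
        chars <- strsplit(m, "")[[1]]
        sum(-log2(model$char_model[chars])) - log2(model$char_model[["#"]])
      }
    }, numeric(1)))
  }
  best <- Inf
  for (b in 0:(2^(max(n - 1, 0)) - 1)) {
    cuts <- if (n > 1) which(bitwAnd(b, 2^(0:(n - 2))) > 0) else integer(0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, n)
    best <- min(best, seg_cost(substring(s, starts, ends)))
  }
  best
}
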