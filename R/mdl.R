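# ---- incremental two-part-code state ---------------------------------------
#
# The MDL objective is total_cost = lexicon_cost + corpus_cost with
#   corpus_cost  = -sum_m n(m) log2(n(m) / N_tok)          (pointer message)
#   lexicon_cost = -sum_c m(c) log2(m(c) / M)              (morph inventory)
# where n(m) are morph token counts, N_tok their sum, and m(c) counts of
# characters over the distinct lexicon entries including one end marker "#"
# per morph, M their sum. Both reduce to "total*log2(total) - sum x log2 x",
# so the training search keeps the two sums incrementally and evaluates any
# candidate move in O(morph length).

xlog2x <- function(x) ifelse(x > 0, x * log2(x), 0)

mdl_state_new <- function() {
  st <- new.env(parent = emptyenv())
  st$morphs <- new.env(parent = emptyenv())
  st$chars <- new.env(parent = emptyenv())
  st$n_tok <- 0
  st$s_corp <- 0
  st$m_char <- 0
  st$s_char <- 0
  st
}

st_char_delta <- function(st, morph, sign) {
  for (ch in c(strsplit(morph, "")[[1]], "#")) {
    old <- st$chars[[ch]] %||% 0
    new <- old + sign
    st$s_char <- st$s_char - xlog2x(old) + xlog2x(new)
    st$m_char <- st$m_char + sign
    if (new <= 0) rm(list = ch, envir = st$chars) else st$chars[[ch]] <- new
  }
}

st_add <- function(st, morph, k) {
  old <- st$morphs[[morph]] %||% 0
  if (old == 0) st_char_delta(st, morph, 1L)
  new <- old + k
  st$s_corp <- st$s_corp - xlog2x(old) + xlog2x(new)
  st$n_tok <- st$n_tok + k
  st$morphs[[morph]] <- new
  invisible(st)
}

st_remove <- function(st, morph, k) {
  old <- st$morphs[[morph]] %||% 0
  new <- old - k
  if (new < -1e-9) stop("internal: negative morph count for ", morph)
  st$s_corp <- st$s_corp - xlog2x(old) + xlog2x(new)
  st$n_tok <- st$n_tok - k
  if (new <= 1e-9) {
    rm(list = morph, envir = st$morphs)
    st_char_delta(st, morph, -1L)
  } else {
    st$morphs[[morph]] <- new
  }
  invisible(st)
}

st_total_cost <- function(st) {
  corp <- xlog2x(st$n_tok) - st$s_corp
  lex <- xlog2x(st$m_char) - st$s_char
  corp + lex
}

st_counts <- function(st) {
  n <- ls(st$morphs)
  stats::setNames(vapply(n, function(m) st$morphs[[m]], numeric(1)), n)
}

# ---- cost functions (from-scratch, used for reporting and as invariants) ---

#' Corpus (pointer-message) code length of a morph inventory
#'
#' `-sum_m n(m) log2(n(m)/N)` over morph token counts: the number of bits
#' needed to spell out the corpus as pointers into the morph lexicon, i.e.
#' `N` times the entropy of the morph token distribution.
#'
#' @param x An `mdl_model`, or a named numeric vector of morph token counts.
#' @return Code length in bits (nonnegative).
#' @export
#' @examples
#' corpus_cost(c(a = 5, b = 3, c = 2))
corpus_cost <- function(x) {
  counts <- if (inherits(x, "mdl_model")) x$morph_counts else x
  if (length(counts) == 0) stop("empty morph inventory", call. = FALSE)
  n <- sum(counts)
  -sum(counts * log2(counts / n))
}

#' Lexicon code length of a set of morphs
#'
#' Each distinct morph is spelled out character by character plus one end
#' marker `#`; character probabilities are maximum-likelihood estimates over
#' all lexicon entry characters and end markers.
#'
#' @param x An `mdl_model`, or a character vector of distinct morphs (a
#'   named count vector also works; only the names are used).
#' @return Code length in bits (nonnegative).
#' @export
#' @examples
#' lexicon_cost("ab") # three symbols a, b, '#' each at p = 1/3
lexicon_cost <- function(x) {
  morphs <- if (inherits(x, "mdl_model")) {
    names(x$morph_counts)
  } else if (!is.null(names(x))) names(x) else as.character(x)
  if (length(morphs) == 0) stop("empty lexicon", call. = FALSE)
  chars <- c(unlist(strsplit(morphs, "")), rep("#", length(morphs)))
  tab <- table(chars)
  -sum(tab * log2(tab / sum(tab)))
}

#' Total two-part code length
#'
#' @param x An `mdl_model` or named morph count vector.
#' @return `lexicon_cost(x) + corpus_cost(x)` in bits.
#' @export
mdl_total_cost <- function(x) lexicon_cost(x) + corpus_cost(x)

# ---- training ---------------------------------------------------------------

# greedy recursive binary resegmentation of `s` (count k); assumes none of
# s's morphs are currently counted; leaves the chosen morphs counted.
# Ties prefer no split, then the earliest split point.
resplit <- function(st, s, k) {
  st_add(st, s, k)
  best <- st_total_cost(st)
  n <- nchar(s)
  if (n == 1) return(s)
  st_remove(st, s, k)
  best_i <- 0L
  for (i in 1:(n - 1)) {
    l <- substr(s, 1, i)
    r <- substr(s, i + 1, n)
    st_add(st, l, k)
    st_add(st, r, k)
    ci <- st_total_cost(st)
    st_remove(st, l, k)
    st_remove(st, r, k)
    if (ci < best - 1e-9) {
      best <- ci
      best_i <- i
    }
  }
  if (best_i == 0L) {
    st_add(st, s, k)
    return(s)
  }
  l <- substr(s, 1, best_i)
  r <- substr(s, best_i + 1, n)
  st_add(st, r, k)
  seg_l <- resplit(st, l, k)
  st_remove(st, r, k)
  seg_r <- resplit(st, r, k)
  c(seg_l, seg_r)
}

#' Train an MDL morph segmentation model
#'
#' Greedy two-part-code minimization in the style of the baseline
#' recursive-splitting morph induction algorithm: every word type starts as
#' a single morph; each epoch visits the word types in a seeded shuffled
#' order and re-segments each one from scratch by recursive binary
#' splitting, accepting a split only when it lowers the total code length
#' (lexicon + pointer message). A word's re-segmentation is reverted if it
#' would raise the total cost, so the cost trajectory is nonincreasing.
#' Training stops when an epoch improves the cost by less than
#' `epsilon_bits` or after `max_epochs` epochs.
#'
#' @param freq Frequency table (`word`, `count`).
#' @param seed Integer seed for the visiting order.
#' @param epsilon_bits Convergence threshold on per-epoch improvement.
#' @param max_epochs Maximum number of epochs.
#' @param dampening How word token counts weight the pointer-message cost:
#'   `"types"` (default) counts each word type once, `"log"` uses
#'   `1 + log2(count)`, `"none"` uses raw token counts. Raw token counts
#'   make the pointer message dominate the lexicon term and leave frequent
#'   words unsegmented, so type-based training is the standard choice for
#'   morph induction; the trade-off is documented in the package vignette.
#' @return An object of class `mdl_model` with elements `morph_counts`,
#'   `total_morph_tokens`, `char_model` (letter + end-marker probabilities
#'   estimated over lexicon entries), `segmentations` (named list of morph
#'   vectors), `lexicon_cost_bits`, `corpus_cost_bits`, `total_cost_bits`,
#'   `cost_history` (bits after initialization and each epoch) and `config`.
#' @export
#' @examples
#' freq <- tibble::tibble(word = c("talo", "talossa"), count = c(10L, 5L))
#' m <- mdl_train(freq, seed = 1)
#' glance(m)
mdl_train <- function(freq, seed = 1, epsilon_bits = 0.1, max_epochs = 20,
                      dampening = c("types", "log", "none")) {
  assert_freq_table(freq)
  dampening <- match.arg(dampening)
  st <- mdl_state_new()
  seg <- stats::setNames(as.list(freq$word), freq$word)
  counts <- stats::setNames(dampen_counts(freq$count, dampening), freq$word)
  # unsegmented baseline (every word type a single morph)
  baseline <- mdl_total_cost(counts)
  # first pass: words enter the model one at a time and are recursively
  # split on entry; with an incrementally growing corpus term, shared
  # substrings become morphs early instead of being locked in whole.
  set.seed(derive_seed(seed, "mdl_epoch_1"))
  for (w in sample(freq$word)) seg[[w]] <- resplit(st, w, counts[[w]])
  history <- c(baseline, st_total_cost(st))
  for (epoch in 1 + seq_len(max_epochs - 1)) {
    set.seed(derive_seed(seed, paste0("mdl_epoch_", epoch)))
    order_w <- sample(freq$word)
    for (w in order_w) {
      k <- counts[[w]]
      old_seg <- seg[[w]]
      t0 <- st_total_cost(st)
      for (m in old_seg) st_remove(st, m, k)
      new_seg <- resplit(st, w, k)
      if (st_total_cost(st) > t0 + 1e-9) {
        for (m in new_seg) st_remove(st, m, k)
        for (m in old_seg) st_add(st, m, k)
      } else {
        seg[[w]] <- new_seg
      }
    }
    history <- c(history, st_total_cost(st))
    n_h <- length(history)
    if (history[n_h - 1] - history[n_h] < epsilon_bits) break
  }
  if (st_total_cost(st) > baseline) {
    # degenerate corpora where no segmentation helps: keep the baseline
    seg <- stats::setNames(as.list(freq$word), freq$word)
    st <- mdl_state_new()
    for (w in freq$word) st_add(st, w, counts[[w]])
    history <- c(history, st_total_cost(st))
  }
  new_mdl_model(st_counts(st), seg,
                config = list(seed = seed, epsilon_bits = epsilon_bits,
                              max_epochs = max_epochs, dampening = dampening),
                cost_history = history)
}

dampen_counts <- function(count, dampening) {
  switch(dampening,
         none = as.numeric(count),
         types = rep(1, length(count)),
         log = 1 + log2(as.numeric(count)))
}

new_mdl_model <- function(morph_counts, segmentations, config = list(),
                          cost_history = numeric()) {
  morph_counts <- morph_counts[order(names(morph_counts))]
  morphs <- names(morph_counts)
  chars <- c(unlist(strsplit(morphs, "")), rep("#", length(morphs)))
  tab <- table(chars)
  char_model <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  lex <- lexicon_cost(morph_counts)
  corp <- corpus_cost(morph_counts)
  structure(
    list(morph_counts = morph_counts,
         total_morph_tokens = sum(morph_counts),
         char_model = char_model,
         segmentations = segmentations,
         lexicon_cost_bits = lex,
         corpus_cost_bits = corp,
         total_cost_bits = lex + corp,
         cost_history = cost_history,
         config = config),
    class = "mdl_model"
  )
}

#' @export
print.mdl_model <- function(x, ...) {
  cat("<mdl_model> ", length(x$morph_counts), " morphs, ",
      x$total_morph_tokens, " morph tokens, total cost ",
      sprintf("%.2f", x$total_cost_bits), " bits\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the morph lexicon of an MDL model
#'
#' @param x An `mdl_model`.
#' @param ... Unused.
#' @return Tibble with columns `morph`, `count`, `surprisal_bits`
#'   (`-log2(count / total)`), sorted by descending count.
#' @export
tidy.mdl_model <- function(x, ...) {
  tibble::tibble(
    morph = names(x$morph_counts),
    count = unname(x$morph_counts),
    surprisal_bits = -log2(unname(x$morph_counts) / x$total_morph_tokens)
  ) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$morph)
}

#' One-row summary of an MDL model
#'
#' @param x An `mdl_model`.
#' @param ... Unused.
#' @return Tibble with morph inventory size, token total, the two code-length
#'   components and the number of training epochs run.
#' @export
glance.mdl_model <- function(x, ...) {
  tibble::tibble(
    n_morphs = length(x$morph_counts),
    total_morph_tokens = x$total_morph_tokens,
    lexicon_cost_bits = x$lexicon_cost_bits,
    corpus_cost_bits = x$corpus_cost_bits,
    total_cost_bits = x$total_cost_bits,
    epochs = max(0L, length(x$cost_history) - 1L)
  )
}

# ---- exhaustive oracle ------------------------------------------------------

# all segmentations of s ordered by (number of morphs, split vector)
all_segmentations <- function(s) {
  n <- nchar(s)
  if (n == 1) return(list(s))
  masks <- 0:(2^(n - 1) - 1)
  segs <- lapply(masks, function(b) {
    cuts <- which(bitwAnd(b, 2^(0:(n - 2))) > 0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, n)
    substring(s, starts, ends)
  })
  segs[order(lengths(segs), vapply(segs, function(x)
    paste(sprintf("%02d", cumsum(nchar(x))), collapse = ""), character(1)))]
}

#' Globally optimal MDL segmentation by exhaustive enumeration
#'
#' Brute-force oracle: enumerates every joint segmentation of all word types
#' and returns the configuration with minimal total two-part code length.
#' Intended for small test corpora; both the summed per-word segmentation
#' count and the joint product space are bounded.
#'
#' @param freq Frequency table (`word`, `count`).
#' @param max_joint Cap on the number of joint segmentation combinations.
#' @param dampening Count weighting, as in [mdl_train()].
#' @return An `mdl_model` at the global optimum.
#' @export
mdl_exhaustive <- function(freq, max_joint = 1e6,
                           dampening = c("types", "log", "none")) {
  assert_freq_table(freq)
  dampening <- match.arg(dampening)
  wcount <- dampen_counts(freq$count, dampening)
  per_word <- 2^(nchar(freq$word) - 1)
  if (sum(per_word) > 1e6) {
    stop("segmentation search space exceeds the per-word bound (sum ",
         format(sum(per_word), big.mark = ","), " > 1e6)", call. = FALSE)
  }
  if (prod(per_word) > max_joint) {
    stop("joint segmentation space ", format(prod(per_word), big.mark = ","),
         " exceeds `max_joint`", call. = FALSE)
  }
  seg_lists <- lapply(freq$word, all_segmentations)
  n_words <- nrow(freq)
  idx <- rep(1L, n_words)
  sizes <- lengths(seg_lists)
  best_cost <- Inf
  best_idx <- idx
  repeat {
    morphs <- unlist(purrr::map2(seg_lists, idx, function(sl, i) sl[[i]]))
    cnt <- rep(wcount, vapply(seq_len(n_words),
                                  function(i) length(seg_lists[[i]][[idx[i]]]),
                                  integer(1)))
    counts <- tapply(cnt, morphs, sum)
    cost <- mdl_total_cost(stats::setNames(as.numeric(counts), names(counts)))
    if (cost < best_cost - 1e-9) {
      best_cost <- cost
      best_idx <- idx
    }
    # advance mixed-radix counter
    j <- 1L
    while (j <= n_words) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > n_words) break
  }
  seg <- stats::setNames(purrr::map2(seg_lists, best_idx, function(sl, i) sl[[i]]),
                         freq$word)
  morphs <- unlist(seg)
  cnt <- rep(wcount, lengths(seg))
  counts <- tapply(cnt, morphs, sum)
  new_mdl_model(stats::setNames(as.numeric(counts), names(counts)), seg,
                config = list(oracle = TRUE, dampening = dampening))
}

# ---- Viterbi decoding -------------------------------------------------------

morph_pointer_cost <- function(model, m) {
  n <- model$morph_counts[m]
  if (!is.na(n)) return(-log2(unname(n) / model$total_morph_tokens))
  NA_real_
}

char_fallback_cost <- function(model, m) {
  chars <- strsplit(m, "")[[1]]
  p <- model$char_model[chars]
  if (anyNA(p)) {
    stop("character(s) outside the model's alphabet in \"", m, "\"", call. = FALSE)
  }
  sum(-log2(p)) - log2(model$char_model[["#"]])
}

#' Segment strings with a trained MDL model
#'
#' Viterbi decoding: minimizes the summed morph cost over all split points,
#' where a lexicon morph costs `-log2(n(m)/N)` bits and any other substring
#' falls back to the letter model (`-log2 p(char)` summed over its letters
#' plus one end marker). The fallback makes every letter string over the
#' model's alphabet segmentable, so pseudowords receive a word-likeness
#' score from the same code. Ties are broken toward fewer morphs, then the
#' leftmost-longest morph.
#'
#' @param model An `mdl_model`.
#' @param strings Character vector of letter strings.
#' @return Tibble with one row per string: `string`, `morphs` (space-joined),
#'   `n_morphs`, `morph_surprisals` (list column of per-morph bits) and
#'   `surprisal_bits` (their sum, the word surprisal).
#' @export
#' @examples
#' freq <- tibble::tibble(word = c("talo", "talot"), count = c(20L, 10L))
#' m <- mdl_train(freq)
#' mdl_segment(m, c("talo", "talota"))
mdl_segment <- function(model, strings) {
  stopifnot(inherits(model, "mdl_model"))
  rows <- lapply(strings, function(s) viterbi_one(model, s))
  tibble::tibble(
    string = strings,
    morphs = vapply(rows, function(r) paste(r$morphs, collapse = " "), character(1)),
    n_morphs = vapply(rows, function(r) length(r$morphs), integer(1)),
    morph_surprisals = lapply(rows, function(r) r$surprisals),
    surprisal_bits = vapply(rows, function(r) sum(r$surprisals), numeric(1))
  )
}

viterbi_one <- function(model, s) {
  if (!nzchar(s)) stop("cannot segment an empty string", call. = FALSE)
  n <- nchar(s)
  # precompute substring costs
  cost_sub <- matrix(NA_real_, n, n)
  for (i in 1:n) {
    for (j in i:n) {
      m <- substr(s, i, j)
      c_ptr <- morph_pointer_cost(model, m)
      cost_sub[i, j] <- if (is.na(c_ptr)) char_fallback_cost(model, m) else c_ptr
    }
  }
  best_cost <- c(rep(Inf, n), 0)
  best_nm <- c(rep(Inf, n), 0)
  choice <- integer(n)
  tol <- 1e-9
  for (i in n:1) {
    for (j in i:n) {
      cc <- cost_sub[i, j] + best_cost[j + 1]
      nm <- 1 + best_nm[j + 1]
      better <- cc < best_cost[i] - tol ||
        (abs(cc - best_cost[i]) <= tol &&
           (nm < best_nm[i] || (nm == best_nm[i] && TRUE)))
      # iterating j upward: accepting ties keeps the longest morph at i
      if (better) {
        best_cost[i] <- cc
        best_nm[i] <- nm
        choice[i] <- j
      }
    }
  }
  morphs <- character(0)
  i <- 1
  while (i <= n) {
    j <- choice[i]
    morphs <- c(morphs, substr(s, i, j))
    i <- j + 1
  }
  surps <- vapply(seq_along(morphs), function(k) {
    m <- morphs[k]
    c_ptr <- morph_pointer_cost(model, m)
    if (is.na(c_ptr)) char_fallback_cost(model, m) else c_ptr
  }, numeric(1))
  list(morphs = morphs, surprisals = unname(surps))
}

# ---- boundary evaluation ----------------------------------------------------

internal_boundaries <- function(morphs) {
  lens <- nchar(morphs)
  if (length(lens) < 2) return(integer(0))
  cumsum(lens)[-length(lens)]
}

#' Boundary precision, recall and F1 against gold segmentations
#'
#' Decodes each gold word with the model (Viterbi) and scores predicted
#' internal morph boundaries against the gold ones, micro-averaged over
#' words.
#'
#' @param model An `mdl_model`.
#' @param gold Tibble with columns `word` and `morphs` (space-joined gold
#'   segmentation).
#' @return Tibble with columns `precision`, `recall`, `f1`, `n_words`.
#' @export
evaluate_boundaries <- function(model, gold) {
  stopifnot(inherits(model, "mdl_model"))
  pred <- mdl_segment(model, gold$word)
  tp <- fp <- fn <- 0
  for (i in seq_len(nrow(gold))) {
    g <- internal_boundaries(strsplit(gold$morphs[i], " ")[[1]])
    p <- internal_boundaries(strsplit(pred$morphs[i], " ")[[1]])
    tp <- tp + length(intersect(p, g))
    fp <- fp + length(setdiff(p, g))
    fn <- fn + length(setdiff(g, p))
  }
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 n_words = nrow(gold))
}

# ---- serialization ----------------------------------------------------------

#' Save or load an MDL model as JSON
#'
#' The JSON carries morph counts, the stored training segmentations and the
#' training configuration; derived quantities (character model, code
#' lengths) are recomputed on load, so the round trip is lossless.
#'
#' @param model An `mdl_model`.
#' @param path File path.
#' @export
mdl_write <- function(model, path) {
  stopifnot(inherits(model, "mdl_model"))
  jsonlite::write_json(
    list(morph_counts = as.list(model$morph_counts),
         segmentations = model$segmentations,
         cost_history = model$cost_history,
         config = model$config),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname mdl_write
#' @return `mdl_read()` returns the reconstructed `mdl_model`.
#' @export
mdl_read <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- unlist(x$morph_counts)
  seg <- lapply(x$segmentations, as.character)
  new_mdl_model(counts, seg, config = as.list(x$config),
                cost_history = as.numeric(x$cost_history))
}
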