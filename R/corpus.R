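#' Define a concatenative morph grammar
#'
#' A grammar is the generative ground truth for synthetic corpora: words are
#' formed as `root + suffix_1 + ... + suffix_k`, roots are drawn with Zipfian
#' (power-law) probabilities over their rank, and each suffix slot is sampled
#' independently from its own categorical distribution. The empty string in a
#' slot yields the bare (shorter) form, so generated lexica mix mono- and
#' multimorphemic words the way inflecting languages do.
#'
#' @param roots Character vector of root strings (at least one).
#' @param suffix_slots List of character vectors, one per ordered suffix slot;
#'   the empty string `""` is allowed and means "no suffix in this slot".
#' @param root_zipf_exponent Positive exponent `a` of the root rank-frequency
#'   law `P(rank) \propto rank^{-a}`.
#' @param suffix_probabilities Optional list of numeric weight vectors
#'   parallel to `suffix_slots`; each is normalized to sum to 1. Defaults to
#'   uniform weights within each slot.
#' @param alphabet Character vector of allowed letters.
#' @return An object of class `morph_grammar`.
#' @export
#' @examples
#' g <- morph_grammar(c("talo", "auto"), list(c("", "ssa")))
#' g
morph_grammar <- function(roots, suffix_slots,
                          root_zipf_exponent = 1,
                          suffix_probabilities = NULL,
                          alphabet = letters) {
  if (length(roots) < 1) stop("grammar needs at least one root", call. = FALSE)
  if (length(suffix_slots) < 1) stop("grammar needs at least one suffix slot", call. = FALSE)
  if (root_zipf_exponent <= 0) stop("`root_zipf_exponent` must be positive", call. = FALSE)
  suffix_slots <- lapply(suffix_slots, as.character)
  used <- unlist(strsplit(c(roots, unlist(suffix_slots)), ""))
  bad <- setdiff(used, alphabet)
  if (length(bad) > 0) {
    stop("letters outside alphabet: ", paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (is.null(suffix_probabilities)) {
    suffix_probabilities <- lapply(suffix_slots, function(s) rep(1 / length(s), length(s)))
  }
  stopifnot(length(suffix_probabilities) == length(suffix_slots))
  suffix_probabilities <- purrr::map2(suffix_probabilities, suffix_slots, function(p, s) {
    stopifnot(length(p) == length(s), all(p >= 0), sum(p) > 0)
    p / sum(p)
  })
  structure(
    list(roots = roots, suffix_slots = suffix_slots,
         root_zipf_exponent = root_zipf_exponent,
         suffix_probabilities = suffix_probabilities,
         alphabet = alphabet),
    class = "morph_grammar"
  )
}

#' @export
print.morph_grammar <- function(x, ...) {
  cat("<morph_grammar> ", length(x$roots), " roots, ",
      length(x$suffix_slots), " suffix slot(s), zipf exponent ",
      x$root_zipf_exponent, "\n", sep = "")
  invisible(x)
}

#' A ready-made richly inflecting demo grammar
#'
#' Builds a grammar whose generated words span roughly 3 to 16 letters, with
#' root lengths 3-10 and two suffix slots carrying short agglutinative-style
#' endings. Used throughout the package as the default study lexicon.
#'
#' @param n_roots Number of roots.
#' @param seed Integer seed controlling the random root strings.
#' @return A `morph_grammar`.
#' @export
demo_grammar <- function(n_roots = 150, seed = 1) {
  set.seed(derive_seed(seed, "demo_grammar"))
  lens <- sample(3:10, n_roots, replace = TRUE)
  consonants <- strsplit("klmnprstv", "")[[1]]
  vowels <- strsplit("aeiouy", "")[[1]]
  roots <- character(n_roots)
  for (i in seq_len(n_roots)) {
    # alternate consonant/vowel so roots look pronounceable and rarely collide
    chars <- character(lens[i])
    for (j in seq_len(lens[i])) {
      chars[j] <- if (j %% 2 == 1) sample(consonants, 1) else sample(vowels, 1)
    }
    roots[i] <- paste(chars, collapse = "")
  }
  roots <- unique(roots)
  morph_grammar(
    roots = roots,
    suffix_slots = list(c("", "ssa", "lla", "sta", "lle"),
                        c("", "ni", "si", "nsa")),
    root_zipf_exponent = 1,
    suffix_probabilities = list(c(0.4, 0.15, 0.15, 0.15, 0.15),
                                c(0.55, 0.15, 0.15, 0.15)),
    alphabet = letters
  )
}

#' Generate a synthetic corpus with gold morph structure
#'
#' Samples `n_tokens` word tokens from a [morph_grammar()]: the root by a
#' Zipf law over root rank, then each suffix slot independently. Every
#' generated word type carries its gold segmentation (root plus the non-empty
#' suffixes, in order) and its lemma (the root).
#'
#' @param grammar A `morph_grammar`.
#' @param n_tokens Number of word tokens to draw (>= 1).
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @return A list of class `lexicon_corpus` with elements
#'   * `frequencies`: tibble with columns `word`, `count` (token counts),
#'   * `gold`: tibble with columns `word`, `morphs` (space-joined gold
#'     segmentation) and `lemma`.
#' @export
#' @examples
#' g <- morph_grammar(c("talo", "auto"), list(c("", "ssa")))
#' corp <- generate_corpus(g, n_tokens = 1000, seed = 42)
#' corp$frequencies
generate_corpus <- function(grammar, n_tokens, seed) {
  if (!inherits(grammar, "morph_grammar")) stop("`grammar` must be a morph_grammar", call. = FALSE)
  stopifnot(n_tokens >= 1)
  set.seed(derive_seed(seed, "generate_corpus"))
  n_roots <- length(grammar$roots)
  p_root <- seq_len(n_roots)^(-grammar$root_zipf_exponent)
  p_root <- p_root / sum(p_root)
  root_idx <- sample.int(n_roots, n_tokens, replace = TRUE, prob = p_root)
  parts <- list(grammar$roots[root_idx])
  for (k in seq_along(grammar$suffix_slots)) {
    slot <- grammar$suffix_slots[[k]]
    idx <- sample.int(length(slot), n_tokens, replace = TRUE,
                      prob = grammar$suffix_probabilities[[k]])
    parts[[k + 1]] <- slot[idx]
  }
  words <- do.call(paste0, parts)
  counts <- table(words)
  freq <- tibble::tibble(word = names(counts), count = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$word)

  seg <- do.call(cbind, parts)
  first <- !duplicated(words)
  gold <- tibble::tibble(
    word = words[first],
    morphs = apply(seg[first, , drop = FALSE], 1, function(m) {
      paste(m[nzchar(m)], collapse = " ")
    }),
    lemma = parts[[1]][first]
  ) |>
    dplyr::arrange(.data$word)

  structure(list(frequencies = freq, gold = gold), class = "lexicon_corpus")
}

#' @export
print.lexicon_corpus <- function(x, ...) {
  cat("<lexicon_corpus> ", nrow(x$frequencies), " word types, ",
      sum(x$frequencies$count), " tokens\n", sep = "")
  print(utils::head(x$frequencies, 5))
  invisible(x)
}

#' Per-million frequency of words in a frequency table
#'
#' @param freq Tibble with columns `word`, `count`.
#' @param words Optional character vector; defaults to all words in `freq`.
#' @return Named numeric vector of occurrences per million tokens.
#' @export
per_million <- function(freq, words = NULL) {
  assert_freq_table(freq)
  total <- sum(freq$count)
  words <- words %||% freq$word
  idx <- match(words, freq$word)
  if (anyNA(idx)) {
    stop("words absent from frequency table: ",
         paste(utils::head(words[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  stats::setNames(freq$count[idx] / total * 1e6, words)
}

#' Aggregate word frequencies into lemma frequencies
#'
#' The lemma frequency of a root is the summed token count of every word
#' form sharing that root; totals are conserved.
#'
#' @param gold Tibble with columns `word`, `lemma` (gold annotations).
#' @param freq Frequency table covering every annotated word.
#' @return Tibble with columns `lemma`, `count`.
#' @export
lemma_table <- function(gold, freq) {
  assert_freq_table(freq)
  missing <- setdiff(gold$word, freq$word)
  if (length(missing) > 0) {
    stop("gold annotations for words absent from frequency table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  dplyr::inner_join(gold[, c("word", "lemma")], freq, by = "word") |>
    dplyr::summarise(count = sum(.data$count), .by = "lemma") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$lemma)
}

#' Read and write tab-separated wordlists
#'
#' The wordlist dialect is UTF-8, one `count<TAB>word` pair per line, no
#' header; counts are positive integers.
#'
#' @param path File path.
#' @return `read_wordlist()` returns a tibble with columns `word`, `count`.
#' @export
read_wordlist <- function(path) {
  x <- utils::read.delim(path, header = FALSE, col.names = c("count", "word"),
                         colClasses = c("integer", "character"),
                         fileEncoding = "UTF-8", quote = "")
  assert_freq_table(tibble::as_tibble(x[, c("word", "count")]))
}

#' @rdname read_wordlist
#' @param freq Frequency table to write.
#' @export
write_wordlist <- function(freq, path) {
  assert_freq_table(freq)
  utils::write.table(freq[, c("count", "word")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write gold morph annotations
#'
#' TSV dialect `word<TAB>morph1 morph2 ...<TAB>lemma`, no header.
#'
#' @param path File path.
#' @return `read_gold()` returns a tibble with columns `word`, `morphs`,
#'   `lemma`.
#' @export
read_gold <- function(path) {
  x <- utils::read.delim(path, header = FALSE,
                         col.names = c("word", "morphs", "lemma"),
                         colClasses = "character",
                         fileEncoding = "UTF-8", quote = "")
  tibble::as_tibble(x)
}

#' @rdname read_gold
#' @param gold Gold annotation tibble to write.
#' @export
write_gold <- function(gold, path) {
  utils::write.table(gold[, c("word", "morphs", "lemma")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
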