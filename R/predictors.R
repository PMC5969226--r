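#' Word length as a surprisal predictor
#'
#' Under a letters-as-units model with equiprobable letters, a word's
#' surprisal is proportional to its letter count `N`; the proportionality
#' constant is absorbed by standardization in the analysis stage, so the
#' predictor is simply `N`.
#'
#' @param strings Character vector.
#' @return Integer letter counts.
#' @export
length_surprisal <- function(strings) nchar(strings)

#' Open bigrams of a letter string
#'
#' All ordered letter pairs `(i, j)` with `i < j`, at any distance, order
#' preserved and duplicates retained; a string of `N` letters yields
#' `N (N - 1) / 2` bigrams. `"take"` gives TA, TK, TE, AK, AE, KE.
#'
#' @param string A single string of at least 2 letters.
#' @return Character vector of upper-case letter pairs.
#' @export
#' @examples
#' open_bigrams("take")
open_bigrams <- function(string) {
  n <- nchar(string)
  if (n < 2) stop("open bigrams need at least 2 letters", call. = FALSE)
  chars <- strsplit(toupper(string), "")[[1]]
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  paste0(chars[idx[, "row"]], chars[idx[, "col"]])
}

#' Corpus-wide open-bigram frequency table
#'
#' Counts open bigrams over every word in a frequency table, each word
#' weighted by its token count (set `weighting = "type"` to count each word
#' once).
#'
#' @param freq Frequency table (`word`, `count`).
#' @param weighting `"token"` (default) or `"type"`.
#' @return Tibble with columns `bigram`, `count`.
#' @export
build_bigram_table <- function(freq, weighting = c("token", "type")) {
  assert_freq_table(freq)
  weighting <- match.arg(weighting)
  usable <- freq[nchar(freq$word) >= 2, ]
  if (nrow(usable) == 0) stop("no words of length >= 2", call. = FALSE)
  bgs <- lapply(usable$word, open_bigrams)
  w <- if (weighting == "token") usable$count else rep(1L, nrow(usable))
  counts <- tapply(rep(w, lengths(bgs)), unlist(bgs), sum)
  tibble::tibble(bigram = names(counts), count = as.numeric(counts)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$bigram)
}

#' Mean open-bigram surprisal of strings
#'
#' `-log2` of the mean per-million frequency of a string's open bigrams
#' (converted to a probability), with unseen bigrams floored at `eps` per
#' million so pseudoword bigrams remain finite.
#'
#' @param strings Character vector (each of length >= 2).
#' @param bigram_table Tibble from [build_bigram_table()].
#' @param eps Per-million floor for unseen bigrams.
#' @return Numeric surprisals in bits.
#' @export
bigram_surprisal <- function(strings, bigram_table, eps = 0.01) {
  if (nrow(bigram_table) == 0) stop("empty bigram table", call. = FALSE)
  total <- sum(bigram_table$count)
  vapply(strings, function(s) {
    bg <- open_bigrams(s)
    cnt <- bigram_table$count[match(bg, bigram_table$bigram)]
    pm <- ifelse(is.na(cnt), 0, cnt) / total * 1e6
    pm[pm == 0] <- eps
    -log2(mean(pm) * 1e-6)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Surface-frequency surprisal
#'
#' `-log2` of the word's corpus probability (the per-million surface
#' frequency divided by 1e6). Real stimulus words must be present in the
#' table; there is no smoothing here.
#'
#' @param words Character vector of words present in `freq`.
#' @param freq Frequency table.
#' @return Numeric surprisals in bits.
#' @export
surface_surprisal <- function(words, freq) {
  pm <- per_million(freq, words)
  unname(-log2(pm / 1e6))
}

#' Lemma-frequency surprisal and lemma transition probability
#'
#' The lemma frequency pools every word form sharing a root, so
#' `lemma_surprisal(w) <= surface_surprisal(w)` always. TPL is the surface
#' count divided by the lemma count: the conditional probability of the
#' particular form given its stem, reported on the probability scale (use
#' `log = TRUE` for `-log2` TPL).
#'
#' @param words Character vector.
#' @param gold Gold annotations (`word`, `lemma`) covering `words`.
#' @param lemma_freqs Lemma table from [lemma_table()].
#' @param freq Frequency table (needed by `tpl()` for surface counts).
#' @param log For `tpl()`: return `-log2(tpl)` instead of the probability.
#' @return Numeric vector.
#' @export
lemma_surprisal <- function(words, gold, lemma_freqs) {
  lem <- gold$lemma[match(words, gold$word)]
  if (anyNA(lem)) {
    stop("no lemma annotation for: ",
         paste(utils::head(words[is.na(lem)], 5), collapse = ", "), call. = FALSE)
  }
  cnt <- lemma_freqs$count[match(lem, lemma_freqs$lemma)]
  if (anyNA(cnt)) {
    stop("lemma missing from lemma table: ",
         paste(utils::head(lem[is.na(cnt)], 5), collapse = ", "), call. = FALSE)
  }
  unname(-log2(cnt / sum(lemma_freqs$count)))
}

#' @rdname lemma_surprisal
#' @export
tpl <- function(words, freq, gold, lemma_freqs, log = FALSE) {
  surface <- freq$count[match(words, freq$word)]
  if (anyNA(surface)) {
    stop("word missing from frequency table: ",
         paste(utils::head(words[is.na(surface)], 5), collapse = ", "), call. = FALSE)
  }
  lem <- gold$lemma[match(words, gold$word)]
  cnt <- lemma_freqs$count[match(lem, lemma_freqs$lemma)]
  if (anyNA(lem) || anyNA(cnt)) stop("missing lemma resources", call. = FALSE)
  if (any(cnt < surface)) {
    stop("lemma frequency below surface frequency for: ",
         paste(utils::head(words[cnt < surface], 5), collapse = ", "), call. = FALSE)
  }
  p <- unname(surface / cnt)
  if (log) -log2(p) else p
}

#' Assemble the item-by-predictor matrix
#'
#' One row per stimulus item with the seven predictor columns in canonical
#' order: `image_complexity`, `length`, `bigram_surprisal`, `tpl`,
#' `mdl_surprisal`, `lemma_surprisal`, `surface_surprisal`. Pseudoword rows
#' carry `NA` in the three frequency-based columns (`tpl`,
#' `lemma_surprisal`, `surface_surprisal`), which have no definition for
#' strings absent from the corpus; their MDL surprisal uses the model's
#' character-level fallback and stays finite.
#'
#' @param items Tibble with columns `item`, `string`, `is_word`.
#' @param model A trained [mdl_train()] model.
#' @param freq Corpus frequency table.
#' @param gold Gold annotations covering the word items.
#' @param lemma_freqs Optional lemma table (computed from `gold` and `freq`
#'   when omitted).
#' @param bigram_table Optional open-bigram table (built from `freq` when
#'   omitted).
#' @param config Render configuration for [gif_index()].
#' @return Tibble `item`, `string`, `is_word` plus the seven predictor
#'   columns.
#' @export
build_predictor_matrix <- function(items, model, freq, gold,
                                   lemma_freqs = NULL, bigram_table = NULL,
                                   config = render_config()) {
  stopifnot(all(c("item", "string", "is_word") %in% names(items)))
  lemma_freqs <- lemma_freqs %||% lemma_table(gold, freq)
  bigram_table <- bigram_table %||% build_bigram_table(freq)
  wrap <- function(col, expr) {
    tryCatch(expr, error = function(e) {
      stop("predictor `", col, "` failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- items[, c("item", "string", "is_word")]
  out$image_complexity <- wrap("image_complexity", gif_index(items$string, config))
  out$length <- length_surprisal(items$string)
  out$bigram_surprisal <- wrap("bigram_surprisal",
                               bigram_surprisal(items$string, bigram_table))
  out$tpl <- NA_real_
  out$mdl_surprisal <- wrap("mdl_surprisal",
                            mdl_segment(model, items$string)$surprisal_bits)
  out$lemma_surprisal <- NA_real_
  out$surface_surprisal <- NA_real_
  iw <- which(items$is_word)
  if (length(iw) > 0) {
    ws <- items$string[iw]
    for (col in c("tpl", "lemma_surprisal", "surface_surprisal")) {
      vals <- switch(col,
        tpl = wrap("tpl", tpl(ws, freq, gold, lemma_freqs)),
        lemma_surprisal = wrap("lemma_surprisal", lemma_surprisal(ws, gold, lemma_freqs)),
        surface_surprisal = wrap("surface_surprisal", surface_surprisal(ws, freq))
      )
      out[[col]][iw] <- vals
    }
  }
  tibble::as_tibble(out)
}
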