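test_that("open bigrams enumerate ordered letter pairs at any distance", {
  expect_equal(open_bigrams("take"), c("TA", "TK", "TE", "AK", "AE", "KE"))
  expect_equal(open_bigrams("aa"), "AA")
  expect_equal(open_bigrams("abc"), c("AB", "AC", "BC"))
  expect_length(open_bigrams("abcdef"), choose(6, 2))
  expect_error(open_bigrams("a"), "2 letters")
})

test_that("length predictor is the letter count", {
  expect_equal(length_surprisal(c("take", "a", strrep("x", 16))), c(4, 1, 16))
})

test_that("bigram surprisal follows the mean per-million frequency", {
  # uniform case: every bigram of the string at 1 per million
  tab <- tibble::tibble(bigram = c("AA", "ZZ"), count = c(1, 999999))
  expect_equal(bigram_surprisal("aa", tab), -log2(1e-6), tolerance = 1e-9)
  # mean of 4/million and 1/million = 2.5/million
  tab2 <- tibble::tibble(bigram = c("AB", "BC", "ZZ"),
                         count = c(4, 1, 999995))
  expect_equal(bigram_surprisal("abc", tab2),
               -log2(mean(c(4, 1, 0.01)) * 1e-6), tolerance = 1e-9)
  # doubling every queried bigram count at fixed total lowers surprisal 1 bit
  tab3 <- tibble::tibble(bigram = c("AA", "ZZ"), count = c(2, 999998))
  expect_equal(bigram_surprisal("aa", tab) - bigram_surprisal("aa", tab3), 1,
               tolerance = 1e-9)
  expect_error(bigram_surprisal("aa", tab[0, ]), "empty")
})

test_that("bigram tables are token-weighted with a type-weighted option", {
  freq <- tibble::tibble(word = c("ab", "ba"), count = c(3L, 1L))
  tok <- build_bigram_table(freq)
  expect_equal(tok$count[match(c("AB", "BA"), tok$bigram)], c(3, 1))
  typ <- build_bigram_table(freq, weighting = "type")
  expect_equal(typ$count[match(c("AB", "BA"), typ$bigram)], c(1, 1))
})

test_that("surface surprisal is the negative log corpus probability", {
  freq <- tibble::tibble(word = c("current", "currant", "filler"),
                         count = c(121L, 1L, 999878L))
  s <- surface_surprisal(c("current", "currant"), freq)
  expect_equal(s[1], -log2(1.21e-4), tolerance = 1e-9)
  expect_equal(s[2], -log2(1e-6), tolerance = 1e-9)
  expect_equal(s[2] - s[1], log2(121), tolerance = 1e-9)
  # probability one gives zero bits
  expect_equal(surface_surprisal("x", tibble::tibble(word = "x", count = 5L)), 0)
  expect_error(surface_surprisal("absent", freq), "absent")
})

test_that("lemma surprisal pools forms and TPL is a conditional probability", {
  gold <- tibble::tibble(word = c("talo", "talossa"),
                         morphs = c("talo", "talo ssa"),
                         lemma = c("talo", "talo"))
  freq <- tibble::tibble(word = c("talo", "talossa", "muu"),
                         count = c(6L, 2L, 92L))
  lf <- lemma_table(gold, freq[1:2, ])
  # word that is its lemma's only form has TPL 1
  gold1 <- tibble::tibble(word = "muu", morphs = "muu", lemma = "muu")
  expect_equal(tpl("muu", freq, gold1, lemma_table(gold1, freq)), 1)
  # surface 2, lemma 8: TPL = 0.25
  expect_equal(tpl("talossa", freq, gold, lf), 0.25)
  expect_equal(tpl("talossa", freq, gold, lf, log = TRUE), 2)
  # corrupted lemma table triggers the integrity check
  bad <- tibble::tibble(lemma = "talo", count = 1L)
  expect_error(tpl("talossa", freq, gold, bad), "below surface")
})

test_that("lemma surprisal never exceeds surface surprisal on a synthetic corpus", {
  corp <- demo_corpus()
  lf <- lemma_table(corp$gold, corp$frequencies)
  words <- demo_stimuli()$string
  ls_ <- lemma_surprisal(words, corp$gold, lf)
  ss <- surface_surprisal(words, corp$frequencies)
  expect_true(all(ls_ <= ss + 1e-9))
})

test_that("GIF encoding is structurally sound and deterministic", {
  img <- render_string("take")
  bytes <- gif_encode(img)
  expect_identical(rawToChar(bytes[1:6]), "GIF89a")
  expect_identical(bytes[length(bytes)], as.raw(0x3B))
  expect_identical(bytes, gif_encode(img))
  expect_identical(gif_index("take"), gif_index("take"))
})

test_that("blank renderings compress further than lettered ones", {
  cfg <- render_config(canvas_cells = 8)
  expect_lt(gif_index(strrep(" ", 8), cfg), gif_index("takelate", cfg))
})

test_that("repeated letters never look more complex than distinct ones", {
  # controlling for glyph ink density: a string of 8 distinct letters is
  # compared against repetitions of its own letters, so only the loss of
  # inter-cell repetition differs
  cfg <- render_config(canvas_cells = 8)
  rep_ratio <- vapply(letters, function(ch) gif_index(strrep(ch, 8), cfg),
                      numeric(1))
  set.seed(99)
  for (i in 1:50) {
    ch <- sample(letters, 8, replace = FALSE)
    expect_lte(mean(rep_ratio[ch]),
               gif_index(paste(ch, collapse = ""), cfg))
  }
})

test_that("image complexity increases with word length on a fixed canvas", {
  set.seed(3)
  strs <- replicate(60, paste(sample(letters, sample(4:16, 1), replace = TRUE),
                              collapse = ""))
  rho <- cor(gif_index(strs), nchar(strs), method = "spearman")
  expect_gt(rho, 0)
  expect_error(render_string("abcdefghijklmnopq"), "canvas")
  expect_error(render_string("a1"), "unrenderable")
})

test_that("the predictor matrix masks exactly the frequency columns for pseudowords", {
  corp <- demo_corpus()
  m <- memo("demo_model_small", {
    mdl_train(utils::head(corp$frequencies, 300), seed = 2, max_epochs = 5)
  })
  items <- tibble::tibble(
    item = c("w1", "pw1"),
    string = c(corp$frequencies$word[1], "zzzzq"),
    is_word = c(TRUE, FALSE)
  )
  # decode alphabet must cover the pseudoword letters; pick letters from the corpus
  items$string[2] <- paste(rep(substr(corp$frequencies$word[2], 1, 1), 5),
                           collapse = "")
  pm <- build_predictor_matrix(items, m, corp$frequencies, corp$gold)
  wordrow <- pm[pm$is_word, ]
  pwrow <- pm[!pm$is_word, ]
  pred_cols <- c("image_complexity", "length", "bigram_surprisal", "tpl",
                 "mdl_surprisal", "lemma_surprisal", "surface_surprisal")
  expect_false(anyNA(wordrow[pred_cols]))
  expect_false(anyNA(pwrow[c("image_complexity", "length",
                             "bigram_surprisal", "mdl_surprisal")]))
  expect_true(all(is.na(pwrow[c("tpl", "lemma_surprisal",
                                "surface_surprisal")])))
  # recomputation reproduces the matrix exactly
  expect_identical(pm, build_predictor_matrix(items, m, corp$frequencies,
                                              corp$gold))
  # resource misses are reported with the offending column
  bad <- tibble::tibble(item = "w9", string = "notincorpusxx", is_word = TRUE)
  expect_error(
    build_predictor_matrix(bad, m, corp$frequencies, corp$gold),
    "tpl|lemma_surprisal|surface_surprisal|mdl_surprisal"
  )
})

test_that("surprisal predictors decrease when frequency increases", {
  freq_lo <- tibble::tibble(word = c("aabb", "ccdd"), count = c(1L, 99L))
  freq_hi <- tibble::tibble(word = c("aabb", "ccdd"), count = c(10L, 90L))
  expect_gt(surface_surprisal("aabb", freq_lo),
            surface_surprisal("aabb", freq_hi))
  tab_lo <- build_bigram_table(freq_lo)
  tab_hi <- build_bigram_table(freq_hi)
  expect_gt(bigram_surprisal("aabb", tab_lo), bigram_surprisal("aabb", tab_hi))
})
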