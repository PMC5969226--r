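#' Sample a stimulus word set with target length statistics
#'
#' Draws `n_items` distinct words from a frequency table, stratified over
#' letter length so that the sample's length mean and SD approximate the
#' configured targets (defaults follow a typical lexical-decision design:
#' lengths 4-16, mean 10.3, SD 2.8). Length strata are allocated from a
#' discretized truncated normal over the admissible lengths; shortfalls in a
#' stratum are reallocated to the nearest lengths with spare words.
#'
#' @param freq Frequency table (`word`, `count`).
#' @param n_items Number of items to sample without replacement.
#' @param length_range Inclusive `c(min, max)` letter lengths.
#' @param length_mean,length_sd Target sample mean and SD of length.
#' @param seed Integer seed.
#' @return Tibble with columns `item`, `string`, `is_word` (all `TRUE`),
#'   `length`, `count`, `per_million`.
#' @export
sample_stimulus_set <- function(freq, n_items = 360, length_range = c(4, 16),
                                length_mean = 10.3, length_sd = 2.8, seed = 1) {
  assert_freq_table(freq)
  set.seed(derive_seed(seed, "stimulus_set"))
  total <- sum(freq$count)
  pool <- freq |>
    dplyr::mutate(length = nchar(.data$word)) |>
    dplyr::filter(.data$length >= length_range[1], .data$length <= length_range[2])
  if (nrow(pool) < n_items) {
    stop("only ", nrow(pool), " words available in length range [",
         length_range[1], ", ", length_range[2], "]; need ", n_items, call. = FALSE)
  }
  lens <- length_range[1]:length_range[2]
  avail <- sapply(lens, function(l) sum(pool$length == l))
  # feasibility of the mean target given the pool
  ord <- order(pool$length)
  min_mean <- mean(pool$length[ord][seq_len(n_items)])
  max_mean <- mean(pool$length[rev(ord)][seq_len(n_items)])
  if (length_mean < min_mean || length_mean > max_mean) {
    stop(sprintf("target mean length %.2f infeasible; achievable range [%.2f, %.2f]",
                 length_mean, min_mean, max_mean), call. = FALSE)
  }

  # target allocation: discretized normal over the length grid
  w <- stats::dnorm(lens, length_mean, length_sd)
  w <- w / sum(w)
  alloc <- floor(w * n_items)
  rem <- n_items - sum(alloc)
  if (rem > 0) {
    extra <- order(w * n_items - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  # cap by availability, then push overflow to nearest lengths with room
  short <- pmax(alloc - avail, 0)
  alloc <- pmin(alloc, avail)
  overflow <- sum(short)
  while (overflow > 0) {
    room <- avail - alloc
    if (all(room <= 0)) stop("not enough words to fill the stimulus set", call. = FALSE)
    # prefer lengths closest to the mean target among those with room
    cand <- which(room > 0)
    pick <- cand[which.min(abs(lens[cand] - length_mean))]
    take <- min(room[pick], overflow)
    alloc[pick] <- alloc[pick] + take
    overflow <- overflow - take
  }

  rows <- purrr::map2(lens, alloc, function(l, k) {
    if (k == 0) return(NULL)
    sub <- pool[pool$length == l, ]
    sub[sample.int(nrow(sub), k), ]
  })
  out <- dplyr::bind_rows(rows)
  out <- out[sample.int(nrow(out)), ] # shuffle presentation order
  tibble::tibble(
    item = paste0("w", seq_len(nrow(out))),
    string = out$word,
    is_word = TRUE,
    length = out$length,
    count = out$count,
    per_million = out$count / total * 1e6
  )
}
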