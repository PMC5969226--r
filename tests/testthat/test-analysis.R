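test_that("window averaging uses a start-inclusive, end-exclusive mean", {
  tc <- tibble::tibble(item = "i1", component = "c1",
                       time_ms = -200:799, amplitude = 4.2)
  expect_equal(window_average(tc, c(300, 700))$amplitude, 4.2)
  # linear ramp 0 -> 1 across the window averages to ~0.5
  ramp <- tibble::tibble(item = "i1", component = "c1", time_ms = -200:799,
                         amplitude = 0)
  idx <- ramp$time_ms >= 300 & ramp$time_ms < 700
  ramp$amplitude[idx] <- seq(0, 1, length.out = sum(idx))
  expect_equal(window_average(ramp, c(300, 700))$amplitude, 0.5,
               tolerance = 1 / sum(idx))
  expect_error(window_average(tc, c(700, 900)), "outside epoch")
})

test_that("within-participant z-scores remove affine participant effects", {
  amp <- tibble::tibble(item = c("a", "b", "c"), participant = "p1",
                        component = "c1", amplitude = c(1, 2, 3))
  z <- zscore_within_participant(amp)
  expect_equal(z$amplitude, c(-1, 0, 1))
  expect_equal(mean(z$amplitude), 0, tolerance = 1e-9)
  expect_equal(sd(z$amplitude), 1, tolerance = 1e-9)
  # affine per-participant corruption leaves the z-scores identical
  amp2 <- dplyr::bind_rows(
    amp,
    dplyr::mutate(amp, participant = "p2", amplitude = 3.7 * amplitude - 11)
  )
  z2 <- zscore_within_participant(amp2)
  expect_equal(z2$amplitude[z2$participant == "p2"],
               z2$amplitude[z2$participant == "p1"], tolerance = 1e-9)
  expect_error(
    zscore_within_participant(
      tibble::tibble(item = c("a", "b"), participant = "p9",
                     component = "c1", amplitude = c(5, 5))),
    "p9"
  )
})

test_that("gain/offset corruption is removed before item averaging", {
  set.seed(31)
  X <- tibble::tibble(item = paste0("i", 1:60), x = rnorm(60))
  clean_sp <- component_spec("c1", 100, c(80, 120), baseline = 10,
                             beta = c(x = 1), noise_trial_sd = 0,
                             participant_gain_sdlog = 0,
                             participant_offset_sd = 0)
  noisy_sp <- component_spec("c1", 100, c(80, 120), baseline = 10,
                             beta = c(x = 1), noise_trial_sd = 0,
                             participant_gain_sdlog = 0.4,
                             participant_offset_sd = 5)
  clean <- simulate_amplitudes(X, clean_sp, 8, seed = 1)
  noisy <- simulate_amplitudes(X, noisy_sp, 8, seed = 1)
  zc <- average_across_items(zscore_within_participant(clean))
  zn <- average_across_items(zscore_within_participant(noisy))
  expect_gt(cor(zc$amplitude[match(X$item, zc$item)],
                zn$amplitude[match(X$item, zn$item)]), 0.99)
})

test_that("item averaging skips missing trials and shrinks noise", {
  amp <- tibble::tibble(
    item = c("a", "a", "b"), participant = c("p1", "p2", "p1"),
    component = "c1", amplitude = c(1, 3, 5)
  )
  out <- average_across_items(amp)
  expect_equal(out$amplitude[out$item == "a"], 2)
  expect_equal(out$amplitude[out$item == "b"], 5)  # p2 missing, not zero-filled
  expect_equal(out$n_participants[out$item == "a"], 2)
  expect_error(average_across_items(amp, items = c("a", "b", "zz")), "zz")
  # single participant: identity
  one <- average_across_items(amp[amp$participant == "p1", ])
  expect_equal(one$amplitude, c(1, 5))
  # item-mean variance shrinks roughly like 1/n on pure noise
  set.seed(11)
  big <- tidyr::expand_grid(item = paste0("i", 1:200),
                            participant = paste0("p", 1:16),
                            component = "c1")
  big$amplitude <- rnorm(nrow(big))
  v <- var(average_across_items(big)$amplitude)
  expect_equal(v, 1 / 16, tolerance = 0.5)
})

test_that("simple correlations agree with the covariance formula and F law", {
  set.seed(5)
  X <- tibble::tibble(a = rnorm(360), b = rnorm(360))
  y <- X$a
  res <- simple_correlations(X, y)
  expect_equal(res$r[res$predictor == "a"], 1)
  expect_equal(res$df1, c(1, 1))
  expect_equal(res$df2, c(358, 358))
  # independent covariance-formula oracle
  r_oracle <- sum((X$b - mean(X$b)) * (y - mean(y))) /
    sqrt(sum((X$b - mean(X$b))^2) * sum((y - mean(y))^2))
  expect_equal(res$r[res$predictor == "b"], r_oracle, tolerance = 1e-12)
  # F and p agree with the t-test equivalence of cor.test
  ct <- cor.test(X$b, y)
  expect_equal(res$statistic[res$predictor == "b"],
               unname(ct$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p_value[res$predictor == "b"], ct$p.value,
               tolerance = 1e-9)
  expect_error(simple_correlations(tibble::tibble(a = rep(1, 10)), rnorm(10)),
               "zero variance")
})

test_that("stepwise selection handles exact, duplicated and masked predictors", {
  set.seed(6)
  X <- tibble::tibble(x1 = rnorm(100))
  X$x2 <- X$x1                      # duplicate: only one may enter
  X$x3 <- rnorm(100)                # pure noise
  X$x4 <- NA_real_                  # masked column is skipped
  y <- X$x1
  fit <- forward_stepwise(X, y)
  expect_equal(fit$selected, "x1")  # tie broken by column order
  expect_equal(unname(fit$beta), 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(nrow(fit$steps), 1)
})

test_that("stepwise results match a reference least-squares fit", {
  set.seed(7)
  n <- 200
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 0.6 * X$a - 0.4 * X$b + rnorm(n, sd = 0.5)
  fit <- forward_stepwise(X, y)
  expect_setequal(fit$selected, c("a", "b"))
  ref <- lm(scale(y) ~ scale(X$a) + scale(X$b))
  expect_equal(unname(fit$beta[c("a", "b")]),
               unname(coef(ref)[2:3]), tolerance = 1e-9)
  expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-9)
  expect_equal(fit$statistic, unname(summary(ref)$fstatistic["value"]),
               tolerance = 1e-6)
  g <- glance(fit)
  expect_equal(g$df, 2)
  expect_equal(g$df_residual, n - 3)
  td <- tidy(fit)
  expect_equal(sort(td$term), c("a", "b"))
})

test_that("partial-F entry tests agree with anova on nested models", {
  set.seed(8)
  n <- 150
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  y <- 0.5 * X$a + 0.3 * X$b + rnorm(n)
  fit <- forward_stepwise(X, y)
  # reproduce the second entry's partial F with stats::anova
  first <- fit$steps$predictor[1]
  second <- fit$steps$predictor[2]
  Xs <- as.data.frame(scale(as.matrix(X)))
  ys <- drop(scale(y))
  m1 <- lm(ys ~ Xs[[first]])
  m2 <- lm(ys ~ Xs[[first]] + Xs[[second]])
  a <- anova(m1, m2)
  expect_equal(unname(fit$steps$partial_f[2]), a$F[2], tolerance = 1e-9)
  expect_equal(unname(fit$steps$p_value[2]), a$`Pr(>F)`[2], tolerance = 1e-9)
})

test_that("tertile bins are disjoint, exhaustive of their size, and ordered", {
  set.seed(9)
  preds <- tibble::tibble(item = paste0("i", 1:360), x = rnorm(360))
  sp <- component_spec("c1", 400, c(300, 700), baseline = 5,
                       beta = c(x = 2), noise_trial_sd = 0.1)
  amp <- simulate_amplitudes(preds, sp, 4, seed = 10)
  tc <- simulate_timecourses(amp, sp)
  bins <- bin_by_predictor(preds, "x", tc, bin_size = 60)
  expect_equal(sort(unique(as.character(bins$bin))), c("high", "low", "mid"))
  expect_true(all(bins$n_items == 60))
  # planted positive effect: high bin exceeds low bin in the window
  wm <- window_average(dplyr::rename(bins, item = bin), c(300, 700))
  expect_gt(wm$amplitude[wm$item == "high"], wm$amplitude[wm$item == "low"])
  expect_error(bin_by_predictor(preds[1:100, ], "x", tc), "three disjoint")
})

test_that("the full analysis pipeline is deterministic and class-aware", {
  skip_if_not_installed("tidyr")
  corr <- predictor_correlations()
  X <- simulate_predictors_from_correlations(corr, 120, seed = 20)
  X$item <- paste0("w", seq_len(nrow(X)))
  X$is_word <- rep(c(TRUE, FALSE), each = 60)
  comps <- default_components(n_participants = 6)
  amp <- simulate_amplitudes(X, comps, 6, seed = 21)
  eff <- default_effects("reaction_time")
  tr <- simulate_behavior(X, rt_betas = eff$beta * 0, rt_baseline = 800,
                          noise_sd = 80, n_participants = 6, seed = 22)
  # frequency-based predictors are undefined for pseudoword items
  X$tpl[!X$is_word] <- NA
  X$lemma_surprisal[!X$is_word] <- NA
  X$surface_surprisal[!X$is_word] <- NA
  res1 <- analyze(X, amp, tr, min_valid = 30)
  res2 <- analyze(X, amp, tr, min_valid = 30)
  expect_identical(res1$simple, res2$simple)
  expect_identical(res1$stepwise, res2$stepwise)
  # pseudoword analyses use exactly the four available predictors
  pw <- unique(res1$simple$predictor[res1$simple$class == "pseudowords"])
  expect_setequal(pw, c("image_complexity", "length", "bigram_surprisal",
                        "mdl_surprisal"))
  ww <- unique(res1$simple$predictor[res1$simple$class == "words"])
  expect_length(ww, 7)
})
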