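# Default study conditions for internal-consistency simulations.
#
# The correlation structure among the seven predictors and the standardized
# effect sizes per response target mirror the published item-level MEG
# lexical-decision study of morphologically rich word reading that this
# package emulates; they are the package's reference conditions, not tuning
# knobs.

#' Reference correlation structure of the seven predictors (word items)
#'
#' Pairwise Pearson correlations between the predictor variables as observed
#' on a 360-word stimulus set in the reference study design. Used by
#' [simulate_predictors_from_correlations()] for internal-consistency
#' simulations.
#'
#' @return A 7x7 symmetric correlation matrix with unit diagonal, rows and
#'   columns named as in [build_predictor_matrix()].
#' @export
predictor_correlations <- function() {
  v <- predictor_names()
  R <- diag(7)
  dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("image_complexity", "length", 0.81)
  set_r("image_complexity", "bigram_surprisal", -0.07)
  set_r("image_complexity", "tpl", -0.06)
  set_r("image_complexity", "mdl_surprisal", 0.42)
  set_r("image_complexity", "lemma_surprisal", 0.05)
  set_r("image_complexity", "surface_surprisal", 0.27)
  set_r("length", "bigram_surprisal", 0.09)
  set_r("length", "tpl", -0.05)
  set_r("length", "mdl_surprisal", 0.54)
  set_r("length", "lemma_surprisal", 0.06)
  set_r("length", "surface_surprisal", 0.34)
  set_r("bigram_surprisal", "tpl", 0.06)
  set_r("bigram_surprisal", "mdl_surprisal", 0.06)
  set_r("bigram_surprisal", "lemma_surprisal", -0.08)
  set_r("bigram_surprisal", "surface_surprisal", 0.09)
  set_r("tpl", "mdl_surprisal", 0.01)
  set_r("tpl", "lemma_surprisal", 0.61)
  set_r("tpl", "surface_surprisal", -0.10)
  set_r("mdl_surprisal", "lemma_surprisal", 0.38)
  set_r("mdl_surprisal", "surface_surprisal", 0.74)
  set_r("lemma_surprisal", "surface_surprisal", 0.40)
  R
}

#' Reference standardized effect sizes per response target
#'
#' Standardized regression coefficients of the predictors on each evoked
#' component's window amplitude and on reaction time, together with the
#' total variance each model explains, for word and pseudoword items in the
#' reference study design. These are the default planted effects for the
#' response simulator.
#'
#' @param target One of `"occipital"`, `"occipito_temporal"`,
#'   `"left_temporal"`, `"right_temporal"`, `"reaction_time"`.
#' @param class `"words"` or `"pseudowords"`.
#' @return A list with `beta` (named standardized coefficients) and
#'   `r_squared` (total explained variance of the full model).
#' @export
#' @examples
#' default_effects("reaction_time")
default_effects <- function(target = c("occipital", "occipito_temporal",
                                       "left_temporal", "right_temporal",
                                       "reaction_time"),
                            class = c("words", "pseudowords")) {
  target <- match.arg(target)
  class <- match.arg(class)
  words <- list(
    occipital = list(beta = c(length = 0.30), r_squared = 0.09),
    occipito_temporal = list(beta = c(length = -0.15, bigram_surprisal = -0.14),
                             r_squared = 0.04),
    left_temporal = list(beta = c(image_complexity = -0.15, mdl_surprisal = 0.22,
                                  surface_surprisal = 0.22),
                         r_squared = 0.15),
    right_temporal = list(beta = c(image_complexity = -0.24, length = 0.33,
                                   mdl_surprisal = 0.21),
                          r_squared = 0.12),
    reaction_time = list(beta = c(length = 0.36, bigram_surprisal = -0.11,
                                  mdl_surprisal = 0.20, lemma_surprisal = 0.14,
                                  surface_surprisal = 0.21),
                         r_squared = 0.52)
  )
  pseudowords <- list(
    occipital = list(beta = c(length = 0.39), r_squared = 0.16),
    occipito_temporal = list(beta = c(length = -0.16), r_squared = 0.03),
    left_temporal = list(beta = c(mdl_surprisal = 0.17), r_squared = 0.03),
    right_temporal = list(beta = c(length = 0.34), r_squared = 0.11),
    reaction_time = list(beta = c(length = 0.89, mdl_surprisal = -0.34),
                         r_squared = 0.46)
  )
  if (class == "words") words[[target]] else pseudowords[[target]]
}

#' Default evoked-component specifications
#'
#' Four components of the word-evoked response with their conventional
#' analysis windows: an occipital response around 100 ms (80-120 ms window),
#' a letter-string-sensitive occipito-temporal response around 150 ms
#' (140-200 ms), and sustained left and right temporal responses around
#' 400 ms (300-700 ms). Planted standardized effects and noise calibrated
#' to the reference explained variance come from [default_effects()].
#'
#' @param class `"words"` or `"pseudowords"` effect sizes.
#' @param corr Predictor correlation matrix used to calibrate trial noise.
#' @param n_participants Cohort size the item-level analysis will average
#'   over; per-trial noise is calibrated so the item-level explained
#'   variance matches the reference totals after averaging.
#' @return A list of [component_spec()] objects.
#' @export
default_components <- function(class = "words", corr = predictor_correlations(),
                               n_participants = 20) {
  specs <- list(
    occipital = list(peak = 100, window = c(80, 120), baseline = 20, bump_sd = 15),
    occipito_temporal = list(peak = 150, window = c(140, 200), baseline = 25, bump_sd = 20),
    left_temporal = list(peak = 400, window = c(300, 700), baseline = 30, bump_sd = 100),
    right_temporal = list(peak = 400, window = c(300, 700), baseline = 25, bump_sd = 100)
  )
  lapply(stats::setNames(names(specs), names(specs)), function(nm) {
    eff <- default_effects(nm, class)
    component_spec(
      name = nm,
      peak_ms = specs[[nm]]$peak,
      window_ms = specs[[nm]]$window,
      baseline = specs[[nm]]$baseline,
      beta = eff$beta,
      noise_trial_sd = calibrate_noise_sd(eff$beta, corr, eff$r_squared,
                                          n_participants = n_participants),
      bump_sd_ms = specs[[nm]]$bump_sd
    )
  })
}
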