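#' Simulated psychometric observer for 4AFC acuity
#'
#' A logistic psychometric observer for a four-alternative forced-choice
#' Landolt-C task: probability correct rises from the 25% guess floor to
#' `1 - lapse` as the stimulus level (logMAR; larger = coarser = easier)
#' increases past the threshold.
#'
#' @param threshold_logmar Threshold location, logMAR.
#' @param slope Psychometric spread (logistic scale parameter), logMAR.
#' @param guess_rate Chance rate; 1/4 for 4AFC.
#' @param lapse_rate Lapse probability in [0, 0.1].
#' @return An object of class `psychometric_observer`.
#' @export
psychometric_observer <- function(threshold_logmar, slope = 0.08,
                                  guess_rate = 0.25, lapse_rate = 0.01) {
  stopifnot(slope > 0, lapse_rate >= 0, lapse_rate <= 0.1,
            guess_rate > 0, guess_rate < 1)
  structure(list(threshold_logmar = threshold_logmar, slope = slope,
                 guess_rate = guess_rate, lapse_rate = lapse_rate),
            class = "psychometric_observer")
}

#' Probability of a correct response
#'
#' `guess + (1 - guess - lapse) * F((level - threshold)/slope)` with logistic
#' `F`; monotone non-decreasing in level.
#'
#' @param observer A [psychometric_observer()].
#' @param level_logmar Stimulus level(s), logMAR.
#' @return Probability correct.
#' @export
p_correct <- function(observer, level_logmar) {
  observer$guess_rate +
    (1 - observer$guess_rate - observer$lapse_rate) *
      stats::plogis((level_logmar - observer$threshold_logmar) / observer$slope)
}

#' Best-PEST staircase state
#'
#' The staircase keeps an unnormalized log posterior over a uniform grid of
#' candidate thresholds and assumes a fixed psychometric template (logistic,
#' known slope, guess and lapse). The default grid spans -0.3 to 1.3 logMAR in
#' 0.02 steps.
#'
#' @param grid Candidate threshold grid (ascending logMAR).
#' @param template Named list with `slope`, `guess_rate`, `lapse_rate` of the
#'   assumed psychometric template.
#' @return An object of class `pest_state`.
#' @export
pest_state <- function(grid = seq(-0.3, 1.3, by = 0.02),
                       template = pest_template()) {
  stopifnot(all(diff(grid) > 0))
  structure(list(grid = grid,
                 log_posterior = numeric(length(grid)),
                 template = template,
                 history = data.frame(trial = integer(), level = numeric(),
                                      correct = logical())),
            class = "pest_state")
}

#' @rdname pest_state
#' @param slope,guess_rate,lapse_rate Template constants.
#' @export
pest_template <- function(slope = 0.08, guess_rate = 0.25, lapse_rate = 0.01) {
  list(slope = slope, guess_rate = guess_rate, lapse_rate = lapse_rate)
}

#' Update the staircase posterior with one response
#'
#' Adds the log likelihood of the observed response, under the psychometric
#' template evaluated at every candidate threshold, to the running log
#' posterior. Updates are log-additive, so the order of trials does not
#' matter.
#'
#' @param state A [pest_state()].
#' @param level Presented level, logMAR (within the grid span).
#' @param correct Logical response.
#' @param record Append the trial to the state's history (disable in bulk
#'   simulation where the caller keeps its own log).
#' @return The updated state.
#' @export
pest_update <- function(state, level, correct, record = TRUE) {
  tpl <- state$template
  p <- tpl$guess_rate + (1 - tpl$guess_rate - tpl$lapse_rate) *
    stats::plogis((level - state$grid) / tpl$slope)
  state$log_posterior <- state$log_posterior +
    if (correct) log(p) else log1p(-p)
  if (record) {
    state$history <- rbind(state$history,
                           data.frame(trial = nrow(state$history) + 1L,
                                      level = level, correct = correct))
  }
  state
}

# middle of the tied posterior maxima, rounding toward the harder
# (lower-logMAR) side: a flat posterior yields the grid midpoint, a two-way
# tie the harder of the two.
pest_mode_index <- function(state) {
  lp <- state$log_posterior
  ties <- which(lp >= max(lp) - 1e-12)
  ties[ceiling(length(ties) / 2)]
}

#' Next level to test
#'
#' Best-PEST convention: test at the current maximum-likelihood threshold
#' estimate (the posterior mode). Ties are broken toward the middle of the
#' tied set, rounding to the harder (lower) level, so a flat prior starts at
#' the grid midpoint.
#'
#' @param state A [pest_state()].
#' @return A level in logMAR.
#' @export
pest_next_level <- function(state) {
  state$grid[pest_mode_index(state)]
}

#' Run a complete adaptive staircase against a simulated observer
#'
#' Iterates place-at-mode / simulate-response / update for `n_trials` trials
#' and returns the posterior-mode threshold. Responses are drawn with the
#' session RNG, so runs are reproducible under `set.seed()`.
#'
#' @param observer A [psychometric_observer()] (or any function mapping level
#'   to probability correct).
#' @param n_trials Number of trials (24 in a standard session).
#' @param grid,template As in [pest_state()].
#' @return A list with `threshold_logmar`, `history`, `n_trials` and the
#'   final `state`.
#' @export
run_staircase <- function(observer, n_trials = 24,
                          grid = seq(-0.3, 1.3, by = 0.02),
                          template = pest_template()) {
  pfun <- if (is.function(observer)) observer else
    function(level) p_correct(observer, level)
  state <- pest_state(grid, template)
  levels <- numeric(n_trials)
  corrects <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    lv <- pest_next_level(state)
    correct <- stats::runif(1) < pfun(lv)
    state <- pest_update(state, lv, correct, record = FALSE)
    levels[i] <- lv
    corrects[i] <- correct
  }
  list(threshold_logmar = state$grid[pest_mode_index(state)],
       history = data.frame(trial = seq_len(n_trials), level = levels,
                            correct = corrects),
       n_trials = n_trials,
       state = state)
}
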