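# Weighted up-down adaptive staircase engine, shared by the contrast and
# orientation sessions of the simulated observer.

#' Weighted up-down staircase configuration
#'
#' An asymmetric-step staircase: after a tracked response the level moves
#' down by `down`, otherwise up by `up`. At equilibrium the tracked-response
#' probability is `up / (up + down)` (e.g. 2/7 for steps up 2, down 5).
#'
#' @param up,down Step sizes (level units: degrees for orientation,
#'   log10-contrast for detection), both > 0.
#' @param start Starting level.
#' @param n_trials Number of trials (> 0).
#' @param min_level,max_level Clamping bounds for the level.
#' @param boost_trials Number of initial trials whose down step is enlarged.
#' @param boost_factor Multiplier applied to the down step on boosted trials.
#' @return Object of class `staircase_config`.
#' @export
staircase_config <- function(up, down, start, n_trials,
                             min_level = -Inf, max_level = Inf,
                             boost_trials = 0, boost_factor = 3) {
  stopifnot(up > 0, down > 0, n_trials > 0, boost_trials >= 0,
            boost_factor > 0, min_level < max_level)
  structure(list(up = up, down = down, start = start, n_trials = n_trials,
                 min_level = min_level, max_level = max_level,
                 boost_trials = boost_trials, boost_factor = boost_factor),
            class = "staircase_config")
}

#' Run a weighted up-down staircase
#'
#' Presents `n_trials` levels, querying `respond` for each and stepping the
#' level down after tracked responses and up otherwise. Randomness (if any)
#' lives inside `respond`; the engine itself is deterministic given the
#' sequence of responses.
#'
#' @param config A [staircase_config()].
#' @param respond Function of `(level, trial)` returning a list with at
#'   least `tracked` (logical); any further scalar elements are carried into
#'   the output.
#' @return Data frame with columns `trial`, `level`, `tracked` plus the
#'   extra fields emitted by `respond`.
#' @export
run_staircase <- function(config, respond) {
  n <- config$n_trials
  level <- numeric(n)
  tracked <- logical(n)
  extras <- vector("list", n)
  cur <- clamp(config$start, config$min_level, config$max_level)
  for (i in seq_len(n)) {
    level[i] <- cur
    ans <- respond(cur, i)
    tracked[i] <- isTRUE(ans$tracked)
    extras[[i]] <- ans[setdiff(names(ans), "tracked")]
    down_i <- config$down *
      if (i <= config$boost_trials) config$boost_factor else 1
    cur <- clamp(if (tracked[i]) cur - down_i else cur + config$up,
                 config$min_level, config$max_level)
  }
  out <- data.frame(trial = seq_len(n), level = level, tracked = tracked)
  if (length(extras[[1]]) > 0) {
    for (nm in names(extras[[1]])) {
      out[[nm]] <- unlist(lapply(extras, `[[`, nm), use.names = FALSE)
    }
  }
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
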