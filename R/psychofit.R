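# Ad-hoc psychometric fitting: the 2D contrast-SF detection surface, per-SO
# orientation discrimination functions, and the 3-key preprocessing rules.

#' Guess rate from third-key usage
#'
#' In the unforced three-key detection design the floor of the psychometric
#' function depends on how often the observer declines to choose: with no
#' third-key presses the task is standard 2AFC (guess rate 50%), and heavier
#' usage lowers the effective guess rate, `gamma = max(0, (1 - p3/0.7) / 2)`.
#'
#' @param p3 Proportion of third-key (undecided) presses, in \[0, 1\].
#' @return Guess rate in \[0, 0.5\]; 0.5 at `p3 = 0`, 0 for `p3 >= 0.7`.
#' @export
guess_rate_from_undecided <- function(p3) {
  if (any(p3 < 0) || any(p3 > 1)) stop("p3 must lie in [0, 1]")
  pmax(0, (1 - p3 / 0.7) / 2)
}

#' Three-parameter contrast sensitivity shape
#'
#' `S(f) = M f^a exp(-f / b)`: the standard bell (on log axes) used for the
#' behavioural CSF; its peak sits at `f = a * b` with value
#' `M (a b)^a e^-a`.
#'
#' @param f SF, c/d.
#' @param M Sensitivity scale.
#' @param a Shape exponent.
#' @param b Scale, c/d.
#' @return Sensitivity values.
#' @export
csf_shape <- function(f, M, a, b) M * f^a * exp(-f / b)

#' Ad-hoc 2D detection psychometric surface
#'
#' Probability correct at contrast `c` and SF `f`:
#' `gamma + (1 - gamma - lambda) / (1 + exp(-log(21/4) (log c - log(1/S(f))) / sigma))`.
#' The log(21/4) slope factor makes `2 sigma` the 16-84% spread of the
#' function within its floor-to-ceiling range; the midpoint sits at
#' threshold contrast `1 / S(f)`.
#'
#' @param c Contrast (> 0).
#' @param f SF, c/d (> 0).
#' @param M,a,b Sensitivity-shape parameters, see [csf_shape()].
#' @param sigma Spread in natural-log contrast units (> 0).
#' @param gamma Guess rate.
#' @param lambda Lapse rate.
#' @return Probability correct in \[gamma, 1 - lambda\].
#' @export
eval_csf_psychometric <- function(c, f, M, a, b, sigma, gamma = 0.5,
                                  lambda = 0.01) {
  stopifnot(all(c > 0), all(f > 0), sigma > 0)
  s <- csf_shape(f, M, a, b)
  gamma + (1 - gamma - lambda) *
    spread_logistic(log(c), log(1 / s), sigma)
}

#' Preprocess three-key trials for fitting
#'
#' The chosen treatment of the unforced third key at fitting time: undecided
#' (detection) and not-seen (tilt) trials are removed from the Bernoulli
#' likelihood; their information enters the detection fit through the
#' data-derived guess rate ([guess_rate_from_undecided()]) and the tilt
#' summaries through the suppression proportions. The separate staircase-time
#' rule (undecided stepped as a random correct/incorrect) lives in the
#' simulator, not here.
#'
#' @param trials Trial data frame with a `response` column.
#' @return The trials whose responses entered a two-alternative decision.
#' @export
drop_unforced_trials <- function(trials) {
  trials[!(trials$response %in% c("undecided", "not_seen")), , drop = FALSE]
}

#' Fit the ad-hoc 2D detection surface
#'
#' Maximum-likelihood fit of [eval_csf_psychometric()] to three-key contrast
#' detection trials over `(M, a, b, sigma)`; the guess rate is fixed from the
#' session's third-key proportion and the lapse rate is fixed (1% by
#' default). Fitting is a deterministic multi-start bounded quasi-Newton
#' search on log-parameters (equivalently, MAP with flat box priors).
#'
#' @param trials Data frame with columns `sf`, `contrast`, `response`
#'   (`"correct"`, `"incorrect"`, `"undecided"`), `correct` (logical, `NA`
#'   for undecided) and optionally `weight`.
#' @param lambda Fixed lapse rate.
#' @param bounds List of length-2 ranges for `M`, `a`, `b`, `sigma`.
#' @return Object of class `csf_fit`: the four fitted parameters, `gamma`,
#'   `lambda`, `p3`, `neg_log_ml`, `n_trials` (trials entering the
#'   likelihood), and a `boundary_flag` raised on degenerate data.
#' @export
fit_csf_adhoc <- function(trials, lambda = 0.01,
                          bounds = list(M = c(1, 1e4), a = c(0.1, 5),
                                        b = c(0.2, 32),
                                        sigma = c(0.05, 5))) {
  stopifnot(all(c("sf", "contrast", "response") %in% names(trials)))
  p3 <- mean(trials$response == "undecided")
  gamma <- guess_rate_from_undecided(p3)
  use <- drop_unforced_trials(trials)
  y <- use$correct
  w <- if ("weight" %in% names(use)) use$weight else rep(1, nrow(use))
  boundary_flag <- all(y) || !any(y)
  nll <- function(lp) {
    p <- exp(lp)
    pr <- eval_csf_psychometric(use$contrast, use$sf, p[1], p[2], p[3],
                                p[4], gamma, lambda)
    pr <- clamp(pr, 1e-10, 1 - 1e-10)
    -sum(w * ifelse(y, log(pr), log(1 - pr)))
  }
  starts <- expand.grid(M = c(20, 200), a = c(0.5, 2), b = c(2, 8),
                        sigma = c(0.6, 2.5))
  lower <- log(vapply(bounds, `[`, numeric(1), 1))
  upper <- log(vapply(bounds, `[`, numeric(1), 2))
  best <- multistart_ml(nll, log(as.matrix(starts)), lower, upper)
  par <- exp(best$par)
  structure(list(M = par[1], a_shape = par[2], b_scale = par[3],
                 sigma_spread = par[4], gamma = gamma, lambda = lambda,
                 p3 = p3, neg_log_ml = best$value, n_trials = nrow(use),
                 boundary_flag = boundary_flag,
                 convergence = best$convergence),
            class = "csf_fit")
}

#' @export
print.csf_fit <- function(x, ...) {
  cat(sprintf(
    "Ad-hoc CSF fit: M = %.3g, a = %.3g, b = %.3g c/d (peak %.3g c/d)\n",
    x$M, x$a_shape, x$b_scale, x$a_shape * x$b_scale))
  cat(sprintf("  spread = %.3g log-units, gamma = %.3g (p3 = %.3g)\n",
              x$sigma_spread, x$gamma, x$p3))
  cat(sprintf("  -log(ML) = %.2f over %d trials\n", x$neg_log_ml,
              x$n_trials))
  invisible(x)
}

#' Fit per-surround orientation psychometric functions
#'
#' Maximum-likelihood fit of a logistic (log(21/4) spread convention, fixed
#' lapse) to the clockwise/counterclockwise responses at each surround
#' orientation, after removing not-seen trials. Opposite surrounds share one
#' threshold (the spread), fitted jointly per |SO| pair; biases are free per
#' SO. Also reports the half-difference biases (the repulsion summary) and
#' the pooled not-seen proportions.
#'
#' @param trials Data frame with columns `so`, `target_orientation`,
#'   `response` (`"cw"`, `"ccw"`, `"not_seen"`), optionally `sf`, `weight`.
#' @param lambda Fixed lapse rate (1% by default; set 0 for strict 2AFC).
#' @param min_trials Per-SO usable-trial count below which the SO pair is
#'   flagged and skipped.
#' @param bias_bound,sigma_bounds Fitting box.
#' @return Object of class `tilt_fit` with elements `biases` (per SO),
#'   `thresholds` (per |SO|), `half_diff` (per |SO| pair), `suppression`,
#'   `lambda`, `neg_log_ml`, `n_trials`, `insufficient` (flagged |SO|s).
#' @export
fit_tilt_adhoc <- function(trials, lambda = 0.01, min_trials = 5,
                           bias_bound = 45, sigma_bounds = c(0.2, 45)) {
  stopifnot(all(c("so", "target_orientation", "response") %in%
                  names(trials)))
  supp <- suppression_proportion(trials)
  use <- drop_unforced_trials(trials)
  w_all <- if ("weight" %in% names(use)) use$weight else rep(1, nrow(use))
  abs_sos <- sort(unique(abs(use$so)))
  biases <- NULL
  thresholds <- NULL
  half_diff <- NULL
  insufficient <- numeric(0)
  total_nll <- 0
  n_used <- 0
  for (s in abs_sos) {
    sos <- if (s == 0) 0 else c(-s, s)
    idx <- use$so %in% sos
    counts <- table(factor(use$so[idx], levels = sos))
    if (any(counts < min_trials)) {
      insufficient <- c(insufficient, s)
      next
    }
    th <- use$target_orientation[idx]
    y <- use$response[idx] == "cw"
    grp <- match(use$so[idx], sos)
    w <- w_all[idx]
    nb <- length(sos)
    nll <- function(par) {
      a <- par[seq_len(nb)]
      sg <- exp(par[nb + 1])
      pr <- lambda + (1 - 2 * lambda) * spread_logistic(th, a[grp], sg)
      pr <- clamp(pr, 1e-10, 1 - 1e-10)
      -sum(w * ifelse(y, log(pr), log(1 - pr)))
    }
    a0 <- vapply(seq_len(nb), function(g) mean(th[grp == g]), numeric(1))
    starts <- rbind(c(a0, log(1.5)), c(a0, log(6)))
    best <- multistart_ml(nll, starts,
                          lower = c(rep(-bias_bound, nb),
                                    log(sigma_bounds[1])),
                          upper = c(rep(bias_bound, nb),
                                    log(sigma_bounds[2])))
    a_hat <- best$par[seq_len(nb)]
    sg_hat <- exp(best$par[nb + 1])
    biases <- rbind(biases,
                    data.frame(so = sos, bias = a_hat,
                               n = as.integer(counts)))
    thresholds <- rbind(thresholds, data.frame(abs_so = s, sigma = sg_hat))
    if (s > 0) {
      half_diff <- rbind(half_diff,
                         data.frame(abs_so = s,
                                    bias = (a_hat[2] - a_hat[1]) / 2))
    }
    total_nll <- total_nll + best$value
    n_used <- n_used + sum(idx)
  }
  structure(list(biases = biases, thresholds = thresholds,
                 half_diff = half_diff, suppression = supp,
                 lambda = lambda, neg_log_ml = total_nll,
                 n_trials = n_used, insufficient = insufficient),
            class = "tilt_fit")
}

#' @export
print.tilt_fit <- function(x, ...) {
  cat("Ad-hoc tilt fit (half-difference biases):\n")
  if (!is.null(x$half_diff)) print(x$half_diff, row.names = FALSE)
  cat(sprintf("  -log(ML) = %.2f over %d trials\n", x$neg_log_ml,
              x$n_trials))
  invisible(x)
}

#' Surround-suppression summary
#'
#' Proportion of not-seen (third key) responses pooled over opposite
#' surround orientations, per |SO| (and per SF when present).
#'
#' @param trials Tilt trial data frame (`so`, `response`, optionally `sf`).
#' @return Data frame with `abs_so`, (optionally `sf`,) `n`, `prop`.
#' @export
suppression_proportion <- function(trials) {
  key <- list(abs_so = abs(trials$so))
  if ("sf" %in% names(trials)) key$sf <- trials$sf
  agg <- aggregate(trials$response == "not_seen", by = key,
                   FUN = function(z) c(n = length(z), prop = mean(z)))
  out <- data.frame(agg[setdiff(names(agg), "x")],
                    n = as.integer(agg$x[, "n"]), prop = agg$x[, "prop"])
  out[order(out$abs_so), , drop = FALSE]
}

#' Guarded logit for proportion summaries
#'
#' Logit transform with zero (and one) proportions pulled to a guard value
#' of 1/120 before transforming, for downstream group comparisons of
#' suppression proportions.
#'
#' @param p Proportions in \[0, 1\].
#' @param guard Guard value substituted for 0 (and `1 - guard` for 1).
#' @return Logits.
#' @export
guarded_logit <- function(p, guard = 1 / 120) {
  stopifnot(all(p >= 0), all(p <= 1))
  stats::qlogis(clamp(p, guard, 1 - guard))
}

# deterministic multi-start bounded ML: L-BFGS-B from each start row, with a
# Nelder-Mead fallback; returns the best converged optimum
multistart_ml <- function(nll, starts, lower, upper) {
  starts <- as.matrix(starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- clamp(starts[i, ], lower, upper)
    fit <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper),
      error = function(e) NULL)
    if (is.null(fit)) {
      pen <- function(p) {
        if (any(p < lower) || any(p > upper)) return(1e10)
        nll(p)
      }
      fit <- stats::optim(p0, pen, method = "Nelder-Mead",
                          control = list(maxit = 2000))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}
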