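# Trustee utility terms and the four decision models.
#
# All quantities are expressed per trial. The Trustee holds
# `investment * true_multiplier` tokens and returns an integer number of
# them; the Investor believes the Trustee holds
# `investment * believed_multiplier` tokens, and is assumed to expect half
# of that amount back (the second-order expectation).

new_model_spec <- function(name, parameter_names, lower, upper) {
  structure(
    list(
      name = name,
      parameter_names = parameter_names,
      k = length(parameter_names),
      lower = lower,
      upper = upper
    ),
    class = "model_spec"
  )
}

#' Decision-model specification
#'
#' Returns the specification (free parameters, parameter count, and fitting
#' bounds) of one of the four Trustee decision models:
#'
#' * `"MS"` moral strategy: `U = theta * payoff - (1 - theta) *
#'   min(guilt + phi, inequity - phi)`. `theta` in \[0, 0.5\] weights payoff
#'   against the moral term; `phi` in \[-0.1, 0.1\] biases the min operator
#'   toward the guilt obligation (`phi < 0`) or the inequity obligation
#'   (`phi > 0`).
#' * `"GA"` guilt aversion: `U = payoff - theta * guilt`, `theta` in
#'   \[0, 200\].
#' * `"IA"` inequity aversion: `U = payoff - theta * inequity`, `theta` in
#'   \[0, 200\].
#'
#' The GA/IA loss weight lives on a different scale from the MS `theta`
#' because the guilt and inequity terms are squared normalized fractions:
#' the upper bound of 200 is chosen so that at the bound the quadratic
#' moral penalty of a one-token deviation exceeds the linear payoff gain
#' on every stimulus in the task (the largest payoff gradient over
#' investments 1-10 and multipliers 2-8 requires a weight of about 100),
#' letting the fitted models reach their theoretical limit patterns.
#' * `"GR"` greed: `U = payoff`; no free parameters.
#'
#' @param name Model name, one of `"MS"`, `"GA"`, `"IA"`, `"GR"`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(name = c("MS", "GA", "IA", "GR")) {
  name <- match.arg(name)
  switch(name,
    MS = new_model_spec(
      "MS", c("theta", "phi"),
      lower = c(theta = 0, phi = -0.1), upper = c(theta = 0.5, phi = 0.1)
    ),
    GA = new_model_spec(
      "GA", "theta",
      lower = c(theta = 0), upper = c(theta = 200)
    ),
    IA = new_model_spec(
      "IA", "theta",
      lower = c(theta = 0), upper = c(theta = 200)
    ),
    GR = new_model_spec("GR", character(0), numeric(0), numeric(0))
  )
}

as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) {
    model
  } else {
    model_spec(model)
  }
}

check_params <- function(spec, params) {
  if (length(params) != spec$k) {
    stop("model ", spec$name, " takes ", spec$k, " parameter(s), got ",
      length(params),
      call. = FALSE
    )
  }
  as.numeric(params)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec %s: k = %d%s>\n", x$name, x$k,
    if (x$k > 0) {
      paste0(
        "; ",
        paste(sprintf(
          "%s in [%g, %g]", x$parameter_names, x$lower, x$upper
        ), collapse = ", ")
      )
    } else {
      ""
    }
  ))
  invisible(x)
}

check_trial_inputs <- function(investment, multiplier, believed = NULL,
                               returned = NULL, allow_zero_investment = FALSE) {
  if (any(!is.finite(investment)) || any(investment != round(investment)) ||
    any(investment < 0)) {
    stop("investment must be a nonnegative integer", call. = FALSE)
  }
  if (!allow_zero_investment && any(investment == 0)) {
    stop("undefined for zero investment: the Trustee holds no tokens and ",
      "the payoff and guilt denominators vanish",
      call. = FALSE
    )
  }
  if (any(multiplier < 1) || any(multiplier != round(multiplier))) {
    stop("multiplier must be a positive integer", call. = FALSE)
  }
  if (!is.null(believed) &&
    (any(believed < 1) || any(believed != round(believed)))) {
    stop("believed multiplier must be a positive integer", call. = FALSE)
  }
  if (!is.null(returned)) {
    total <- investment * multiplier
    if (any(returned < 0 | returned > total)) {
      stop("returned amount outside the feasible range [0, investment * ",
        "multiplier]",
        call. = FALSE
      )
    }
  }
  invisible(TRUE)
}

#' Trustee monetary payoff fraction
#'
#' The fraction of the multiplied investment the Trustee keeps:
#' `(investment * multiplier - returned) / (investment * multiplier)`.
#' Strictly decreasing in the returned amount; 1 when the Trustee keeps
#' everything and 0 when everything is returned.
#'
#' @param investment Invested tokens (positive integer; zero investment is
#'   undefined because the denominator vanishes).
#' @param multiplier True multiplier.
#' @param returned Tokens returned, in `[0, investment * multiplier]`.
#' @return Payoff fraction in \[0, 1\]; vectorized with recycling.
#' @export
payoff <- function(investment, multiplier, returned) {
  check_trial_inputs(investment, multiplier, returned = returned)
  total <- investment * multiplier
  (total - returned) / total
}

#' Second-order expectation of the back-transfer
#'
#' The Trustee's belief about the Investor's expected back-transfer, fixed
#' at half of the amount the Investor believes the Trustee holds:
#' `0.5 * believed_multiplier * investment` tokens.
#'
#' @param investment Invested tokens.
#' @param believed_multiplier The multiplier the Investor believes applies.
#' @return Expected back-transfer in tokens; vectorized.
#' @export
second_order_expectation <- function(investment, believed_multiplier) {
  check_trial_inputs(investment, believed_multiplier,
    allow_zero_investment = TRUE
  )
  0.5 * believed_multiplier * investment
}

#' Guilt term
#'
#' Squared shortfall of the returned amount relative to the second-order
#' expectation, normalized by the tokens the Investor believes the Trustee
#' holds:
#' `((0.5 * believed * I - returned) / (believed * I))^2`.
#' Zero exactly when the Trustee returns what the Investor expects.
#'
#' @inheritParams second_order_expectation
#' @param returned Tokens returned.
#' @return Nonnegative guilt term; vectorized.
#' @export
guilt <- function(investment, believed_multiplier, returned) {
  check_trial_inputs(investment, believed_multiplier)
  believed_total <- investment * believed_multiplier
  expectation <- 0.5 * believed_total
  ((expectation - returned) / believed_total)^2
}

#' Inequity term
#'
#' Squared deviation of the Trustee's final share of all tokens in play
#' from one half:
#' `((I * M - returned) / (endowment - I + I * M) - 0.5)^2`.
#' Zero exactly when the final token split between the two players is even.
#'
#' @inheritParams payoff
#' @param endowment Investor endowment in tokens (default 10).
#' @return Nonnegative inequity term; vectorized.
#' @export
inequity <- function(investment, multiplier, returned, endowment = 10) {
  check_trial_inputs(investment, multiplier,
    returned = returned,
    allow_zero_investment = TRUE
  )
  total <- investment * multiplier
  in_play <- endowment - investment + total
  if (any(in_play <= 0)) {
    stop("no tokens in play: endowment - investment + investment * ",
      "multiplier must be positive",
      call. = FALSE
    )
  }
  ((total - returned) / in_play - 0.5)^2
}

# Utility components over the whole discrete strategy space of one trial;
# the cache unit reused by prediction and fitting.
trial_components <- function(investment, multiplier, believed_multiplier,
                             endowment = 10) {
  total <- investment * multiplier
  s2 <- 0:total
  list(
    s2 = s2,
    payoff = (total - s2) / total,
    guilt = ((0.5 * believed_multiplier * investment - s2) /
      (believed_multiplier * investment))^2,
    inequity = ((total - s2) / (endowment - investment + total) - 0.5)^2
  )
}

utility_from_components <- function(spec, params, comp) {
  switch(spec$name,
    GR = comp$payoff,
    GA = comp$payoff - params[1] * comp$guilt,
    IA = comp$payoff - params[1] * comp$inequity,
    MS = params[1] * comp$payoff -
      (1 - params[1]) * pmin(comp$guilt + params[2], comp$inequity - params[2])
  )
}

#' Trustee utility of a candidate back-transfer
#'
#' Evaluates the utility a Trustee with the given decision model derives
#' from returning `returned` tokens on one trial. See [model_spec()] for
#' the model equations.
#'
#' @param model A model name or `model_spec`.
#' @param params Numeric parameter vector of length `k` (e.g.
#'   `c(theta, phi)` for the MS model; empty for GR).
#' @inheritParams payoff
#' @param believed_multiplier The multiplier the Investor believes applies.
#' @param endowment Investor endowment in tokens.
#' @return Utility value(s); vectorized over `returned`.
#' @export
trustee_utility <- function(model, params, investment, multiplier,
                            believed_multiplier, returned, endowment = 10) {
  spec <- as_model_spec(model)
  params <- check_params(spec, params)
  check_trial_inputs(investment, multiplier, believed_multiplier, returned)
  total <- investment * multiplier
  pay <- (total - returned) / total
  switch(spec$name,
    GR = pay,
    GA = pay - params[1] * guilt(investment, believed_multiplier, returned),
    IA = pay - params[1] *
      inequity(investment, multiplier, returned, endowment),
    MS = params[1] * pay - (1 - params[1]) * pmin(
      guilt(investment, believed_multiplier, returned) + params[2],
      inequity(investment, multiplier, returned, endowment) - params[2]
    )
  )
}

#' Predicted back-transfer by exhaustive argmax
#'
#' The model's predicted strategy is the integer back-transfer in
#' `{0, 1, ..., investment * multiplier}` with maximal utility, found by
#' exhaustive enumeration. Among utility ties the smallest back-transfer is
#' returned (the Trustee keeps more among equally good options), which makes
#' the prediction deterministic.
#'
#' @inheritParams trustee_utility
#' @return Integer predicted back-transfer(s); vectorized over trials.
#' @export
predict_return <- function(model, params, investment, multiplier,
                           believed_multiplier, endowment = 10) {
  spec <- as_model_spec(model)
  params <- check_params(spec, params)
  n <- max(length(investment), length(multiplier),
    length(believed_multiplier))
  investment <- rep_len(investment, n)
  multiplier <- rep_len(multiplier, n)
  believed_multiplier <- rep_len(believed_multiplier, n)
  check_trial_inputs(investment, multiplier, believed_multiplier)
  vapply(seq_len(n), function(i) {
    comp <- trial_components(
      investment[i], multiplier[i], believed_multiplier[i], endowment
    )
    u <- utility_from_components(spec, params, comp)
    as.integer(comp$s2[which.max(u)])
  }, integer(1))
}

#' Predicted behavior over a trial set
#'
#' Applies [predict_return()] to every trial of a schedule, preserving
#' trial order. Predictions are computed once per unique
#' (investment, multiplier, believed multiplier) combination.
#'
#' @inheritParams trustee_utility
#' @param trials Data frame with columns `investment`, `true_multiplier`,
#'   `believed_multiplier`.
#' @return Integer vector of predicted back-transfers, one per trial.
#' @export
predict_behavior <- function(model, params, trials, endowment = 10) {
  spec <- as_model_spec(model)
  params <- check_params(spec, params)
  key <- paste(trials$investment, trials$true_multiplier,
    trials$believed_multiplier,
    sep = ":"
  )
  uniq <- !duplicated(key)
  preds <- predict_return(
    spec, params,
    trials$investment[uniq], trials$true_multiplier[uniq],
    trials$believed_multiplier[uniq], endowment
  )
  unname(preds[match(key, key[uniq])])
}
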