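# Per-participant model fitting by multi-restart bounded least squares,
# AIC model comparison, and the near-perfect-fit exclusion rule.

#' Sum of squared prediction errors for one participant record
#'
#' Squared token distance between a model's argmax predictions and the
#' observed back-transfers, summed over all feasible trials. Trials with
#' zero investment are infeasible for utility evaluation (zero
#' denominators) and are excluded.
#'
#' @inheritParams trustee_utility
#' @param trials Data frame with columns `investment`, `true_multiplier`,
#'   `believed_multiplier`, `returned`.
#' @return Sum of squared errors in squared-token units.
#' @export
model_sse <- function(model, params, trials, endowment = 10) {
  feasible <- trials$investment > 0
  if (!any(feasible)) {
    stop("record contains no feasible trials (all investments are zero)",
      call. = FALSE
    )
  }
  trials <- trials[feasible, , drop = FALSE]
  preds <- predict_behavior(model, params, trials, endowment)
  sum((trials$returned - preds)^2)
}

#' Akaike Information Criterion from a least-squares fit
#'
#' `AIC = n * log(SSE / n) + 2 * k`, the form appropriate for a
#' least-squares fit with normally distributed errors. Rewards fit (low
#' SSE) and penalizes complexity (parameter count `k`). Undefined for
#' `SSE <= 0`, which is why near-perfectly fit participants are excluded
#' from model comparisons (see [exclude_near_perfect()]).
#'
#' @param sse Residual sum of squares (must be positive).
#' @param n Number of observations (trials).
#' @param k Number of free model parameters.
#' @return AIC value; vectorized.
#' @export
aic <- function(sse, n, k) {
  if (any(n <= 0)) {
    stop("n must be positive", call. = FALSE)
  }
  if (any(sse <= 0)) {
    stop("AIC is undefined for SSE <= 0 (log of a non-positive number); ",
      "near-perfect fits must be excluded from model comparison",
      call. = FALSE
    )
  }
  n * log(sse / n) + 2 * k
}

# Compass (pattern) search over a box: the SSE objective is piecewise
# constant in the parameters (argmax predictions change at finitely many
# breakpoints), so derivative-based refinement is useless; a shrinking-step
# coordinate search descends staircase landscapes reliably.
pattern_search <- function(fn, par, lower, upper, init_frac = 1 / 8,
                           min_frac = 1 / 4096) {
  range <- upper - lower
  step <- range * init_frac
  f <- fn(par)
  while (any(step > range * min_frac)) {
    best_par <- NULL
    best_f <- f
    for (d in seq_along(par)) {
      for (s in c(-1, 1)) {
        cand <- par
        cand[d] <- min(max(par[d] + s * step[d], lower[d]), upper[d])
        fc <- fn(cand)
        if (fc < best_f) {
          best_f <- fc
          best_par <- cand
        }
      }
    }
    if (is.null(best_par)) {
      step <- step / 2
    } else {
      par <- best_par
      f <- best_f
    }
  }
  list(par = par, value = f)
}

#' Fit one decision model to one participant record
#'
#' Minimizes the sum of squared differences between the model's argmax
#' predictions and the observed back-transfers. Because the objective is
#' piecewise constant in the parameters, the optimizer draws
#' `n_restarts` uniform random starting points within the parameter
#' bounds, evaluates all of them, and refines the best few by a bounded
#' shrinking-step pattern search; the lowest-SSE solution over all
#' restarts is returned. The greed model has no free parameters and
#' requires no optimization.
#'
#' @inheritParams model_sse
#' @param model Model name or [model_spec()].
#' @param n_restarts Number of random restarts (default 1000).
#' @param seed Optional integer seed making the fit reproducible in
#'   isolation.
#' @param n_refine Number of top-ranked starts to refine by pattern search.
#' @return A `fit_result` list: `model`, named `params`, `sse`, `n` (trials
#'   used), `k`, `aic` (`NA` when `sse == 0`), `n_restarts`, `seed`.
#' @export
fit_model <- function(trials, model, n_restarts = 1000, seed = NULL,
                      endowment = 10, n_refine = 5) {
  spec <- as_model_spec(model)
  feasible <- trials$investment > 0
  if (!any(feasible)) {
    stop("record contains no feasible trials", call. = FALSE)
  }
  trials <- trials[feasible, , drop = FALSE]
  if (n_restarts < 1) {
    stop("n_restarts must be >= 1", call. = FALSE)
  }

  # cache utility components per unique trial type
  key <- paste(trials$investment, trials$true_multiplier,
    trials$believed_multiplier,
    sep = ":"
  )
  uniq <- which(!duplicated(key))
  comps <- lapply(uniq, function(i) {
    trial_components(
      trials$investment[i], trials$true_multiplier[i],
      trials$believed_multiplier[i], endowment
    )
  })
  idx <- match(key, key[uniq])
  actual <- trials$returned

  objective <- function(par) {
    preds <- vapply(comps, function(comp) {
      comp$s2[which.max(utility_from_components(spec, par, comp))]
    }, numeric(1))
    sum((actual - preds[idx])^2)
  }

  if (spec$k == 0L) {
    best_par <- numeric(0)
    best_sse <- objective(best_par)
  } else {
    if (!is.null(seed)) {
      set.seed(seed)
    }
    # row-wise filling makes the first m starts of an n-restart run (m < n)
    # identical to an m-restart run with the same seed, so adding restarts
    # can only improve the best solution found
    starts <- matrix(
      runif(n_restarts * spec$k, rep_len(spec$lower, n_restarts * spec$k),
        rep_len(spec$upper, n_restarts * spec$k)
      ),
      nrow = n_restarts, byrow = TRUE
    )
    sses <- apply(starts, 1, objective)
    top <- union(order(sses)[seq_len(min(n_refine, n_restarts))], 1L)
    best_par <- starts[top[1], ]
    best_sse <- sses[top[1]]
    for (i in top) {
      ref <- pattern_search(objective, starts[i, ], spec$lower, spec$upper)
      if (ref$value < best_sse) {
        best_sse <- ref$value
        best_par <- ref$par
      }
    }
    names(best_par) <- spec$parameter_names
  }

  n <- nrow(trials)
  structure(
    list(
      model = spec$name,
      params = best_par,
      sse = best_sse,
      n = n,
      k = spec$k,
      aic = if (best_sse > 0) aic(best_sse, n, spec$k) else NA_real_,
      n_restarts = if (spec$k > 0) as.integer(n_restarts) else 1L,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  pstr <- if (x$k > 0) {
    paste(sprintf("%s = %.4f", names(x$params), x$params), collapse = ", ")
  } else {
    "no free parameters"
  }
  cat(sprintf(
    "<fit_result %s: %s; SSE = %.2f over %d trials; AIC = %s>\n",
    x$model, pstr, x$sse, x$n,
    if (is.na(x$aic)) "NA (perfect fit)" else sprintf("%.2f", x$aic)
  ))
  invisible(x)
}

# Deterministic child seed (31-bit) so any subset of fits is reproducible
# in isolation from the same top-level seed.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 362437) %% 2147483587 + 1)
}

#' Fit all decision models to every participant record
#'
#' Splits a long behavior table by participant and block, fits each
#' requested model to each record with [fit_model()], and flags
#' participants whose behavior any model explains near-perfectly (see
#' [exclude_near_perfect()]). Each fit receives a deterministic child seed
#' derived from `seed`, so any individual fit can be reproduced in
#' isolation.
#'
#' @param behavior Long-format behavior table (one row per trial) with the
#'   standard columns of [read_behavior_table()].
#' @param models Character vector of model names to fit.
#' @param n_restarts Random restarts per fit.
#' @param seed Top-level integer seed.
#' @param endowment Investor endowment in tokens.
#' @param threshold SSE threshold for the near-perfect exclusion flag.
#' @return A tibble with one row per participant x block x model:
#'   `participant_id`, `block_id`, `model`, `theta`, `phi`, `sse`, `n`,
#'   `k`, `aic`, `seed`, `excluded_near_perfect`.
#' @export
fit_models <- function(behavior, models = c("MS", "GA", "IA", "GR"),
                       n_restarts = 1000, seed = 1, endowment = 10,
                       threshold = 10) {
  groups <- split(
    as.data.frame(behavior),
    list(behavior$participant_id, behavior$block_id),
    drop = TRUE
  )
  groups <- groups[order(names(groups))]
  rows <- vector("list", length(groups) * length(models))
  counter <- 0L
  for (g in seq_along(groups)) {
    rec <- groups[[g]]
    for (m in seq_along(models)) {
      counter <- counter + 1L
      cs <- child_seed(seed, counter)
      fit <- fit_model(rec, models[m],
        n_restarts = n_restarts, seed = cs,
        endowment = endowment
      )
      rows[[counter]] <- tibble::tibble(
        participant_id = rec$participant_id[1],
        block_id = rec$block_id[1],
        model = fit$model,
        theta = if ("theta" %in% names(fit$params)) {
          fit$params[["theta"]]
        } else {
          NA_real_
        },
        phi = if ("phi" %in% names(fit$params)) {
          fit$params[["phi"]]
        } else {
          NA_real_
        },
        sse = fit$sse,
        n = fit$n,
        k = fit$k,
        aic = fit$aic,
        seed = fit$seed
      )
    }
  }
  fits <- do.call(rbind, rows)
  exclude_near_perfect(fits, threshold = threshold)
}

#' Flag participants with a near-perfect model fit
#'
#' A participant (within a block) is flagged when *any* model's SSE falls
#' strictly below the threshold; for such participants `AIC` is unstable
#' (the log of a near-zero SSE) and they are omitted from model
#' comparisons. Flagged participants are retained for strategy
#' classification, which uses only the fitted parameters.
#'
#' @param fits Fits tibble as returned by [fit_models()].
#' @param threshold SSE threshold (default 10, strict inequality).
#' @return The fits tibble with a logical `excluded_near_perfect` column.
#' @export
exclude_near_perfect <- function(fits, threshold = 10) {
  group <- paste(fits$participant_id, fits$block_id, sep = "\r")
  flagged <- tapply(fits$sse, group, function(s) any(s < threshold))
  fits$excluded_near_perfect <- as.vector(flagged[group])
  fits
}

#' Paired model comparison on AIC
#'
#' Two-sided paired-samples t-test on per-participant AIC values of two
#' models. Identical vectors give `t = 0`, `p = 1`; constant nonzero
#' differences (zero variance) are an error.
#'
#' @param aic_a,aic_b Equal-length paired AIC vectors (one entry per
#'   participant), `NA`-free.
#' @return List with `statistic` (t), `df` (`n - 1`), `p.value`, and
#'   `mean_diff` (`mean(aic_a - aic_b)`).
#' @export
compare_models_paired <- function(aic_a, aic_b) {
  if (length(aic_a) != length(aic_b)) {
    stop("paired AIC vectors must have equal length", call. = FALSE)
  }
  if (length(aic_a) < 2) {
    stop("need at least two pairs", call. = FALSE)
  }
  if (anyNA(aic_a) || anyNA(aic_b)) {
    stop("AIC vectors must not contain NA (exclude near-perfect fits first)",
      call. = FALSE
    )
  }
  d <- aic_a - aic_b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(
        statistic = 0, df = length(d) - 1, p.value = 1, mean_diff = 0
      ))
    }
    stop("zero variance of paired differences: t statistic is undefined",
      call. = FALSE
    )
  }
  tt <- stats::t.test(aic_a, aic_b, paired = TRUE)
  list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    mean_diff = unname(tt$estimate)
  )
}

#' Posterior-predictive table of actual versus predicted behavior
#'
#' One row per participant x trial x model, pairing each observed
#' back-transfer with the fitted model's prediction; the raw material for
#' posterior-predictive checks.
#'
#' @param fits Fits tibble from [fit_models()].
#' @param behavior The behavior table the fits were computed from.
#' @param endowment Investor endowment in tokens.
#' @return Tibble with columns `participant_id`, `block_id`, `model`,
#'   `trial_index`, `investment`, `true_multiplier`, `believed_multiplier`,
#'   `actual`, `predicted`.
#' @export
prediction_table <- function(fits, behavior, endowment = 10) {
  behavior <- as.data.frame(behavior)
  out <- vector("list", nrow(fits))
  for (i in seq_len(nrow(fits))) {
    rec <- behavior[
      behavior$participant_id == fits$participant_id[i] &
        behavior$block_id == fits$block_id[i] &
        behavior$investment > 0, ,
      drop = FALSE
    ]
    spec <- model_spec(fits$model[i])
    params <- c(fits$theta[i], fits$phi[i])[seq_len(spec$k)]
    out[[i]] <- tibble::tibble(
      participant_id = rec$participant_id,
      block_id = rec$block_id,
      model = fits$model[i],
      trial_index = rec$trial_index,
      investment = rec$investment,
      true_multiplier = rec$true_multiplier,
      believed_multiplier = rec$believed_multiplier,
      actual = rec$returned,
      predicted = predict_behavior(spec, params, rec, endowment)
    )
  }
  do.call(rbind, out)
}
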