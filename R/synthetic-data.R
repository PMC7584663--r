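# Synthetic Trustee populations: agents drawn from the strategy zones of a
# map, investment schedules with exact condition counts, and noisy
# trial-level behavior generated by the moral-strategy model. Makes every
# stage of the pipeline testable end to end, with known ground truth.

largest_remainder_counts <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  remainder <- n - sum(base)
  if (remainder > 0) {
    frac <- raw - base
    top <- order(frac, decreasing = TRUE)[seq_len(remainder)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

# Interior mask of the label grid: a point is interior when every grid
# point within `margin` grid steps (Chebyshev neighborhood) shares its
# label. Out-of-grid neighbors are ignored, so zones keep their edge along
# the domain boundary.
zone_interior <- function(map, margin) {
  nt <- length(map$theta_values)
  np <- length(map$phi_values)
  lab <- matrix(as.integer(map$grid$label), nt, np)
  interior <- matrix(TRUE, nt, np)
  for (di in -margin:margin) {
    for (dj in -margin:margin) {
      if (di == 0 && dj == 0) next
      ri <- max(1, 1 - di):min(nt, nt - di)
      rj <- max(1, 1 - dj):min(np, np - dj)
      interior[ri, rj] <- interior[ri, rj] &
        (lab[ri, rj] == lab[ri + di, rj + dj])
    }
  }
  as.vector(interior)
}

#' Sample a synthetic agent population from a strategy map
#'
#' Draws `n_agents` agents with a fixed strategy mixture (default 40%
#' inequity-averse, 10% guilt-averse, 40% morally opportunistic, 10%
#' greedy, the mixture reported for student populations on this task).
#' Strategy counts are the largest-remainder rounding of
#' `proportions * n_agents`. Each agent's (theta, phi) is drawn uniformly
#' from the grid points of its strategy's zone that lie at least `margin`
#' grid steps from any zone boundary, so the generating label is
#' unambiguous. When the agents are destined for a multi-block study,
#' pass the strategy maps of all blocks: zone boundaries shift with the
#' multiplier set, and an agent only embodies a strategy across contexts
#' if its parameters fall in that strategy's zone of every map, so
#' sampling is restricted to the intersection of the zones.
#'
#' @param n_agents Number of agents.
#' @param map A [build_strategy_map()] result for the target game, or a
#'   list of maps (one per study block) sharing the same grid axes.
#' @param proportions Named strategy proportions over `GR`, `GA`, `IA`,
#'   `MO`; must be nonnegative and sum to 1.
#' @param margin Zone-interior margin in grid steps.
#' @param noise_sd Decision-noise standard deviation in tokens, attached
#'   to every agent.
#' @param seed Optional integer seed.
#' @return Tibble of agents: `agent_id`, `strategy`, `theta`, `phi`,
#'   `noise_sd`.
#' @export
sample_population <- function(n_agents, map,
                              proportions = c(
                                IA = 0.4, GA = 0.1, MO = 0.4, GR = 0.1
                              ),
                              margin = 3, noise_sd = 1, seed = NULL) {
  maps <- if (inherits(map, "strategy_map")) list(map) else map
  stopifnot(all(vapply(maps, inherits, TRUE, "strategy_map")))
  for (m in maps[-1]) {
    if (!identical(m$theta_values, maps[[1]]$theta_values) ||
      !identical(m$phi_values, maps[[1]]$phi_values)) {
      stop("all maps must share the same grid axes", call. = FALSE)
    }
  }
  map <- maps[[1]]
  if (is.null(names(proportions)) ||
    !all(names(proportions) %in% STRATEGY_LABELS)) {
    stop("proportions must be named with strategy labels ",
      paste(STRATEGY_LABELS, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must be nonnegative and sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  counts <- largest_remainder_counts(unname(proportions), n_agents)
  names(counts) <- names(proportions)
  interior <- Reduce(`&`, lapply(maps, zone_interior, margin = margin))
  grid <- map$grid
  rows <- lapply(names(counts), function(s) {
    if (counts[[s]] == 0) {
      return(NULL)
    }
    in_zone <- Reduce(`&`, lapply(maps, function(m) m$grid$label == s))
    pts <- which(in_zone & interior)
    if (length(pts) == 0) {
      stop("strategy zone ", s, " is empty after applying a margin of ",
        margin, " grid steps",
        call. = FALSE
      )
    }
    take <- pts[sample.int(length(pts), counts[[s]], replace = TRUE)]
    tibble::tibble(
      strategy = s,
      theta = grid$theta[take],
      phi = grid$phi[take]
    )
  })
  agents <- do.call(rbind, rows)
  agents <- agents[sample.int(nrow(agents)), ]
  tibble::tibble(
    agent_id = sprintf("agent%03d", seq_len(nrow(agents))),
    strategy = factor(agents$strategy, levels = STRATEGY_LABELS),
    theta = agents$theta,
    phi = agents$phi,
    noise_sd = noise_sd
  )
}

#' Generate an investment schedule for a game block
#'
#' Produces `n_trials` trials realizing the game's condition counts
#' exactly; condition order is a stratified shuffle. Investments are drawn
#' uniformly from `investments` (default 1..10 tokens; zero is excluded as
#' degenerate). Calling this with the same seed and trial count for two
#' different configurations yields identical investment sequences, so the
#' same investment set can be presented in both blocks of a two-block
#' study.
#'
#' @param config Game configuration.
#' @param seed Optional integer seed.
#' @param investments Support of the investment distribution.
#' @return Tibble of trials: `trial_index`, `investment`,
#'   `true_multiplier`, `believed_multiplier`.
#' @export
generate_investment_schedule <- function(config, seed = NULL,
                                         investments = 1:10) {
  stopifnot(inherits(config, "game_config"))
  if (!is.null(seed)) {
    set.seed(seed)
  }
  n <- config$n_trials
  inv <- sample(investments, n, replace = TRUE)
  cond <- rep(seq_len(nrow(config$conditions)), config$conditions$n_trials)
  cond <- cond[sample.int(n)]
  tibble::tibble(
    trial_index = seq_len(n),
    investment = as.integer(inv),
    true_multiplier = config$conditions$true_multiplier[cond],
    believed_multiplier = config$conditions$believed_multiplier[cond]
  )
}

#' Simulate one agent's behavior on a schedule
#'
#' The agent's deterministic back-transfer on each trial is the
#' moral-strategy argmax at its (theta, phi); decision noise is additive
#' Gaussian on the returned amount, rounded to integer tokens and clipped
#' to the feasible range `[0, investment * multiplier]`.
#'
#' @param agent One-row agent (as from [sample_population()]): needs
#'   `agent_id`, `theta`, `phi`, `noise_sd`.
#' @param schedule Trial schedule from [generate_investment_schedule()].
#' @param config Game configuration (supplies the endowment).
#' @param seed Optional integer seed for the noise draws.
#' @param block_id Block label attached to the record.
#' @return Behavior tibble in the standard long format.
#' @export
simulate_agent <- function(agent, schedule, config, seed = NULL,
                           block_id = config$variant) {
  stopifnot(inherits(config, "game_config"))
  if (!is.null(seed)) {
    set.seed(seed)
  }
  pred <- predict_behavior(
    "MS", c(agent$theta, agent$phi), schedule, config$endowment
  )
  total <- schedule$investment * schedule$true_multiplier
  noise <- if (agent$noise_sd > 0) {
    rnorm(nrow(schedule), 0, agent$noise_sd)
  } else {
    numeric(nrow(schedule))
  }
  returned <- pmin(pmax(round(pred + noise), 0), total)
  tibble::tibble(
    participant_id = agent$agent_id,
    block_id = block_id,
    trial_index = schedule$trial_index,
    investment = schedule$investment,
    true_multiplier = schedule$true_multiplier,
    believed_multiplier = schedule$believed_multiplier,
    returned = as.integer(returned)
  )
}

#' Generate a complete synthetic study
#'
#' Simulates every agent through every game block. All blocks present the
#' same investment sequence (generated from the study seed), mirroring a
#' within-participant two-block design; each agent x block receives a
#' deterministic child seed for its noise draws, so any record is
#' reproducible in isolation.
#'
#' @param agents Agent tibble from [sample_population()].
#' @param configs List of game configurations, one per block. Names are
#'   used as block ids (defaults to `block1`, `block2`, ...).
#' @param seed Top-level integer seed.
#' @return List with `behavior` (long tibble over all agents and blocks),
#'   `truth` (the agent tibble: generating strategy and parameters), and
#'   `schedules` (per-block trial schedules).
#' @export
generate_study <- function(agents, configs, seed = 1) {
  if (inherits(configs, "game_config")) {
    configs <- list(configs)
  }
  if (length(configs) == 0) {
    stop("need at least one game configuration", call. = FALSE)
  }
  block_ids <- names(configs)
  if (is.null(block_ids) || any(block_ids == "")) {
    block_ids <- paste0("block", seq_along(configs))
  }
  schedules <- lapply(configs, generate_investment_schedule, seed = seed)
  names(schedules) <- block_ids
  out <- vector("list", length(configs) * nrow(agents))
  counter <- 0L
  for (b in seq_along(configs)) {
    for (a in seq_len(nrow(agents))) {
      counter <- counter + 1L
      out[[counter]] <- simulate_agent(
        agents[a, ], schedules[[b]], configs[[b]],
        seed = child_seed(seed, counter),
        block_id = block_ids[b]
      )
    }
  }
  list(
    behavior = do.call(rbind, out),
    truth = agents,
    schedules = schedules
  )
}
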