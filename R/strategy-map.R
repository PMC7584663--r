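# Model-driven partition of the theta-phi parameter space into strategy
# zones: simulate the moral-strategy model on a dense parameter grid,
# cluster the simulated behavior patterns, label the clusters by their
# nearest theoretical strategy archetype, and classify participants by the
# zone their fitted parameters fall into. The partition is built purely
# from model simulations, never from participant data, so maps for
# different task variants are directly comparable.

#' Simulate the moral-strategy model over a theta-phi grid
#'
#' Computes the argmax back-transfer of the MS model at every point of an
#' equidistant `n_theta` x `n_phi` grid over the full parameter domain
#' (theta in \[0, 0.5\], phi in \[-0.1, 0.1\]), for every combination of
#' investment and multiplier condition in the game. At the default
#' resolution the grid has 10,201 points.
#'
#' @param config A [make_hmtg_config()] / [make_fbmtg_config()] object.
#' @param n_theta,n_phi Grid resolution per axis (default 101 x 101).
#' @param investments Investment levels in the stimulus set; zero is
#'   excluded as degenerate.
#' @return A `grid_simulation`: grid coordinates, stimulus set, and a
#'   behavior matrix with one row per grid point and one column per
#'   stimulus.
#' @export
simulate_grid <- function(config, n_theta = 101, n_phi = 101,
                          investments = 1:10) {
  stopifnot(inherits(config, "game_config"))
  if (any(investments < 1)) {
    stop("investments must be positive (zero investment is degenerate)",
      call. = FALSE
    )
  }
  spec <- model_spec("MS")
  theta_values <- seq(spec$lower[["theta"]], spec$upper[["theta"]],
    length.out = n_theta
  )
  phi_values <- seq(spec$lower[["phi"]], spec$upper[["phi"]],
    length.out = n_phi
  )
  grid <- expand.grid(theta = theta_values, phi = phi_values)

  conds <- config$conditions
  stimuli <- do.call(rbind, lapply(seq_len(nrow(conds)), function(r) {
    data.frame(
      investment = investments,
      true_multiplier = conds$true_multiplier[r],
      believed_multiplier = conds$believed_multiplier[r]
    )
  }))

  behavior <- matrix(0L, nrow(grid), nrow(stimuli))
  phi_idx <- match(grid$phi, phi_values)
  for (s in seq_len(nrow(stimuli))) {
    comp <- trial_components(
      stimuli$investment[s], stimuli$true_multiplier[s],
      stimuli$believed_multiplier[s], config$endowment
    )
    # moral term per (phi, s2), then utility per (grid point, s2)
    moral <- pmin(
      outer(phi_values, comp$guilt, "+"),
      outer(-phi_values, comp$inequity, "+")
    )
    u <- outer(grid$theta, comp$payoff) -
      (1 - grid$theta) * moral[phi_idx, , drop = FALSE]
    behavior[, s] <- comp$s2[max.col(u, ties.method = "first")]
  }

  structure(
    list(
      theta_values = theta_values,
      phi_values = phi_values,
      grid = grid,
      stimuli = stimuli,
      investments = investments,
      behavior = behavior,
      config = config
    ),
    class = "grid_simulation"
  )
}

#' @export
print.grid_simulation <- function(x, ...) {
  cat(sprintf(
    "<grid_simulation: %d x %d = %d points, %d stimuli, %s game>\n",
    length(x$theta_values), length(x$phi_values), nrow(x$grid),
    nrow(x$stimuli), x$config$variant
  ))
  invisible(x)
}

#' Hierarchically cluster simulated grid behavior
#'
#' Agglomerative clustering of the grid points by pairwise Euclidean
#' distance between their simulated behavior vectors, cut to exactly
#' `n_clusters` clusters. Ward linkage is the default as it produces
#' compact, contiguous parameter-space zones.
#'
#' @param sim A [simulate_grid()] result.
#' @param n_clusters Number of clusters to cut the tree at.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return Integer cluster id per grid point.
#' @export
cluster_grid <- function(sim, n_clusters, linkage = "ward.D2") {
  stopifnot(inherits(sim, "grid_simulation"))
  n_distinct <- nrow(unique(sim$behavior))
  if (n_clusters > n_distinct) {
    stop("n_clusters (", n_clusters, ") exceeds the number of distinct ",
      "behavior patterns (", n_distinct, ")",
      call. = FALSE
    )
  }
  tree <- stats::hclust(stats::dist(sim$behavior), method = linkage)
  stats::cutree(tree, k = n_clusters)
}

# Round half away from the expectation toward the smaller back-transfer,
# matching the argmax tie-break (among equally good options the Trustee
# keeps more).
round_half_down <- function(x) {
  ceiling(x - 0.5)
}

#' Archetypal behavior pattern of a reciprocity motive
#'
#' The theoretical prediction of each pure strategy over a stimulus set:
#' greed (GR) returns nothing; guilt aversion (GA) returns the Investor's
#' expectation (half the tokens the Investor believes the Trustee holds)
#' in every condition; inequity aversion (IA) returns whatever makes the
#' final token split even; moral opportunism (MO) follows the cheaper of
#' the two obligations per condition -- the GA pattern when the Trustee
#' holds more than the Investor believes, the IA pattern when less. All
#' patterns are clipped to the feasible range.
#'
#' @param strategy One of `"GR"`, `"GA"`, `"IA"`, `"MO"`.
#' @param config Game configuration (supplies conditions and endowment).
#' @param investments Investment levels, matching the grid stimulus set.
#' @return Numeric behavior vector, one entry per stimulus in the same
#'   order as [simulate_grid()] stimuli.
#' @export
canonical_pattern <- function(strategy, config, investments = 1:10) {
  strategy <- match.arg(strategy, STRATEGY_LABELS)
  stopifnot(inherits(config, "game_config"))
  conds <- config$conditions
  endow <- config$endowment
  out <- numeric(0)
  for (r in seq_len(nrow(conds))) {
    i <- investments
    total <- i * conds$true_multiplier[r]
    ga <- pmax(0, pmin(
      total,
      round_half_down(0.5 * conds$believed_multiplier[r] * i)
    ))
    ia <- pmax(0, pmin(total, round_half_down((total + i - endow) / 2)))
    believed_total <- i * conds$believed_multiplier[r]
    pattern <- switch(strategy,
      GR = rep(0, length(i)),
      GA = ga,
      IA = ia,
      MO = ifelse(total > believed_total, ga,
        ifelse(total < believed_total, ia, pmin(ga, ia))
      )
    )
    out <- c(out, pattern)
  }
  out
}

#' Label grid clusters by nearest strategy archetype
#'
#' Assigns each cluster the strategy label whose archetypal behavior
#' pattern (see [canonical_pattern()]) lies nearest (Euclidean) to the
#' cluster's mean simulated behavior. Clusters sharing a label are merged
#' into a single zone: the moral-opportunism regime always splits into a
#' guilt-obligation and an inequity-obligation half, and in the
#' raised-set game (x4/x6/x8) the greed regime splits along its payoff
#' gradient before the small inequity-aversion zone separates. An error
#' is raised when one of the four motives has no cluster, which signals a
#' cluster count too small for the game.
#'
#' @param sim A [simulate_grid()] result.
#' @param cluster_ids Cluster id per grid point from [cluster_grid()].
#' @param config The game configuration the simulation was built for.
#' @return A `strategy_map`: tibble of grid coordinates with cluster id
#'   and strategy label, plus the grid axes and configuration.
#' @export
label_clusters <- function(sim, cluster_ids, config = sim$config) {
  stopifnot(inherits(sim, "grid_simulation"))
  ids <- sort(unique(cluster_ids))
  means <- t(vapply(
    ids,
    function(k) colMeans(sim$behavior[cluster_ids == k, , drop = FALSE]),
    numeric(ncol(sim$behavior))
  ))
  archetypes <- vapply(
    STRATEGY_LABELS,
    function(s) canonical_pattern(s, config, sim$investments),
    numeric(ncol(sim$behavior))
  )
  d <- vapply(
    seq_len(ncol(archetypes)),
    function(a) sqrt(rowSums((means - matrix(archetypes[, a],
      nrow(means), nrow(archetypes),
      byrow = TRUE
    ))^2)),
    numeric(nrow(means))
  )
  assigned <- STRATEGY_LABELS[apply(d, 1, which.min)]
  if (!all(STRATEGY_LABELS %in% assigned)) {
    stop("strategy zone(s) missing from the clustering solution: ",
      paste(setdiff(STRATEGY_LABELS, assigned), collapse = ", "),
      "; increase n_clusters",
      call. = FALSE
    )
  }
  # merge clusters that share a label into one zone id
  label_per_point <- assigned[match(cluster_ids, ids)]
  zone_id <- vapply(assigned, function(l) min(ids[assigned == l]), 0)
  merged <- zone_id[match(cluster_ids, ids)]
  merged <- match(merged, sort(unique(merged)))

  grid <- tibble::as_tibble(sim$grid)
  grid$cluster <- merged
  grid$label <- factor(label_per_point, levels = STRATEGY_LABELS)
  structure(
    list(
      grid = grid,
      theta_values = sim$theta_values,
      phi_values = sim$phi_values,
      config = config,
      investments = sim$investments,
      n_clusters = length(ids)
    ),
    class = "strategy_map"
  )
}

#' @export
print.strategy_map <- function(x, ...) {
  cat(sprintf(
    "<strategy_map: %d grid points (%d x %d), %s game>\n",
    nrow(x$grid), length(x$theta_values), length(x$phi_values),
    x$config$variant
  ))
  print(table(x$grid$label))
  invisible(x)
}

#' Build a strategy map for a game configuration
#'
#' Convenience wrapper running [simulate_grid()], [cluster_grid()] and
#' [label_clusters()]. The default cut at five clusters followed by a
#' same-label merge yields the four motive zones for all three task
#' variants: in the lowered-set HMTG and the FBMTG the moral-opportunism
#' regime occupies two clusters, while in the raised-set HMTG (x4/x6/x8)
#' the greed regime does.
#'
#' @inheritParams simulate_grid
#' @inheritParams cluster_grid
#' @return A `strategy_map`.
#' @export
build_strategy_map <- function(config, n_clusters = 5, n_theta = 101,
                               n_phi = 101, investments = 1:10,
                               linkage = "ward.D2") {
  sim <- simulate_grid(config, n_theta, n_phi, investments)
  cl <- cluster_grid(sim, n_clusters, linkage)
  label_clusters(sim, cl, config)
}

#' Classify participants by position in the strategy map
#'
#' Each participant is assigned the strategy label of the grid point
#' nearest (Euclidean in theta-phi) to their fitted parameter pair. Exact
#' ties go to the point with lower theta, then lower phi.
#'
#' @param theta,phi Fitted parameter vectors (equal length).
#' @param map A `strategy_map` from [build_strategy_map()].
#' @return Factor of strategy labels, levels `GR`, `GA`, `IA`, `MO`.
#' @export
classify_participant <- function(theta, phi, map) {
  stopifnot(inherits(map, "strategy_map"))
  if (length(theta) != length(phi)) {
    stop("theta and phi must have equal length", call. = FALSE)
  }
  t_rng <- range(map$theta_values)
  p_rng <- range(map$phi_values)
  eps <- 1e-9
  if (any(theta < t_rng[1] - eps | theta > t_rng[2] + eps) ||
    any(phi < p_rng[1] - eps | phi > p_rng[2] + eps)) {
    stop("parameters outside the map domain (theta in [", t_rng[1], ", ",
      t_rng[2], "], phi in [", p_rng[1], ", ", p_rng[2], "])",
      call. = FALSE
    )
  }
  grid <- map$grid
  ord <- order(grid$theta, grid$phi)
  gt <- grid$theta[ord]
  gp <- grid$phi[ord]
  gl <- grid$label[ord]
  labels <- vapply(seq_along(theta), function(i) {
    d2 <- (gt - theta[i])^2 + (gp - phi[i])^2
    as.character(gl[which.min(d2)])
  }, character(1))
  factor(labels, levels = STRATEGY_LABELS)
}

#' Fit the moral-strategy model and classify every participant
#'
#' End-to-end classification stage: fits the MS model to each participant
#' x block record of a behavior table and assigns each a strategy label
#' from the map.
#'
#' @param behavior Long-format behavior table.
#' @param map Strategy map for the game the behavior comes from.
#' @param n_restarts Random restarts per fit.
#' @param seed Top-level seed (child seeds derived per record).
#' @return Tibble: `participant_id`, `block_id`, `theta`, `phi`, `sse`,
#'   `label`.
#' @export
classify_study <- function(behavior, map, n_restarts = 1000, seed = 1) {
  fits <- fit_models(behavior,
    models = "MS", n_restarts = n_restarts,
    seed = seed, endowment = map$config$endowment
  )
  fits$label <- classify_participant(fits$theta, fits$phi, map)
  fits[c("participant_id", "block_id", "theta", "phi", "sse", "label")]
}

#' Export a strategy map as a plain table
#'
#' @param map A `strategy_map`.
#' @param path Optional CSV path; when given the table is also written.
#' @return Tibble of `theta`, `phi`, `cluster`, `label`.
#' @export
strategy_map_table <- function(map, path = NULL) {
  stopifnot(inherits(map, "strategy_map"))
  out <- map$grid
  if (!is.null(path)) {
    write.csv(as.data.frame(out), path, row.names = FALSE)
  }
  out
}
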