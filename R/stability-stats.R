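# Stability statistics: test-retest correlation, parameter-space geometry,
# marginal homogeneity of paired strategy labels, and prevalence
# comparisons between independent samples.

#' Pearson correlation with two-sided test
#'
#' Thin wrapper around [stats::cor.test()] used for test-retest
#' reliability of fitted parameters, inter-participant distances, and
#' trait correlations.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, nonzero
#'   variance).
#' @return List with `r`, `p.value`, `df`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("need at least three observations", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: correlation is undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(
    r = unname(ct$estimate),
    p.value = ct$p.value,
    df = unname(ct$parameter),
    n = length(x)
  )
}

#' Pairwise distances between participants in parameter space
#'
#' Euclidean distances between every unordered pair of participants'
#' (theta, phi) coordinates, in the canonical condensed ordering of
#' [stats::dist()] (pair (1,2), (1,3), ..., (n-1,n)). The geometry of
#' these distances is more stable across task variants than the raw
#' parameters, because zone boundaries shift slightly with the multiplier
#' set.
#'
#' @param theta,phi Equal-length parameter vectors (>= 2 participants).
#' @return Numeric vector of length `n * (n - 1) / 2`.
#' @export
interparticipant_distances <- function(theta, phi) {
  if (length(theta) != length(phi)) {
    stop("theta and phi must have equal length", call. = FALSE)
  }
  if (length(theta) < 2) {
    stop("need at least two participants", call. = FALSE)
  }
  as.vector(stats::dist(cbind(theta, phi)))
}

#' Cross-tabulate paired strategy labels
#'
#' Builds the k x k table of participants labeled strategy i in one block
#' and strategy j in another. The diagonal counts participants with a
#' stable label.
#'
#' @param labels_a,labels_b Paired label vectors (same participants, same
#'   order).
#' @param labels Label order for rows/columns; defaults to the standard
#'   strategy order for factors over strategy labels, otherwise the sorted
#'   union.
#' @return A `transition_table`: counts matrix, `percent_stable`, and
#'   `row_percent` (each cell as a percentage of its row total).
#' @export
transition_table <- function(labels_a, labels_b, labels = NULL) {
  if (length(labels_a) != length(labels_b)) {
    stop("paired label vectors must have equal length", call. = FALSE)
  }
  if (length(labels_a) == 0) {
    stop("empty label vectors", call. = FALSE)
  }
  if (is.null(labels)) {
    obs <- unique(c(as.character(labels_a), as.character(labels_b)))
    labels <- if (all(obs %in% STRATEGY_LABELS)) {
      STRATEGY_LABELS
    } else {
      sort(obs)
    }
  }
  fa <- factor(as.character(labels_a), levels = labels)
  fb <- factor(as.character(labels_b), levels = labels)
  if (anyNA(fa) || anyNA(fb)) {
    stop("labels outside the supplied label set", call. = FALSE)
  }
  counts <- unclass(table(fa, fb))
  dimnames(counts) <- list(from = labels, to = labels)
  rs <- rowSums(counts)
  row_percent <- 100 * counts / ifelse(rs == 0, NA, rs)
  structure(
    list(
      table = counts,
      n = length(fa),
      percent_stable = 100 * sum(diag(counts)) / length(fa),
      row_percent = row_percent
    ),
    class = "transition_table"
  )
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf(
    "<transition_table: n = %d, %.1f%% stable>\n", x$n, x$percent_stable
  ))
  print(x$table)
  invisible(x)
}

as_square_table <- function(x) {
  if (inherits(x, "transition_table")) {
    x <- x$table
  }
  x <- as.matrix(x)
  if (nrow(x) != ncol(x) || nrow(x) < 2) {
    stop("need a square k x k table with k >= 2", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  x
}

#' Stuart-Maxwell test of marginal homogeneity
#'
#' Tests whether the marginal distributions of a paired k-category table
#' agree, generalizing McNemar's test beyond 2 x 2 (for k = 2 the
#' statistic reduces exactly to McNemar's `(b - c)^2 / (b + c)`). The
#' statistic is `d' S^{-1} d` with `d` the first k-1 row-column marginal
#' differences and `S` the covariance matrix with diagonal
#' `row_i + col_i - 2 n_ii` and off-diagonal `-(n_ij + n_ji)`; it is
#' invariant to which category is dropped and to permutation of the
#' category order. When `S` is singular (e.g. an empty category) a
#' Moore-Penrose generalized inverse is used and the degrees of freedom
#' reduce to the rank of `S`, reported via `generalized_inverse = TRUE`.
#'
#' @param table A k x k counts matrix or a [transition_table()].
#' @return List with `statistic` (X-squared), `df`, `p.value`, and
#'   `generalized_inverse` flag.
#' @export
stuart_maxwell <- function(table) {
  tab <- as_square_table(table)
  k <- nrow(tab)
  d <- (rowSums(tab) - colSums(tab))[-k]
  S <- -(tab[-k, -k, drop = FALSE] + t(tab[-k, -k, drop = FALSE]))
  diag(S) <- (rowSums(tab) + colSums(tab) - 2 * diag(tab))[-k]
  fallback <- FALSE
  sol <- tryCatch(solve(S, d), error = function(e) NULL)
  if (is.null(sol) || rcond(S) < 1e-12) {
    fallback <- TRUE
    sol <- MASS::ginv(S) %*% d
    df <- qr(S)$rank
  } else {
    df <- k - 1
  }
  x2 <- max(0, sum(d * sol))
  p <- if (df == 0) 1 else stats::pchisq(x2, df, lower.tail = FALSE)
  list(
    statistic = x2, df = df, p.value = p,
    generalized_inverse = fallback
  )
}

#' Chi-square test of independent prevalence distributions
#'
#' Pearson chi-square test (no continuity correction) comparing strategy
#' prevalence counts between independent samples, e.g. a 2 x 4 table of
#' study by strategy with df = 3.
#'
#' @param table An r x k counts matrix (rows = samples/studies,
#'   columns = strategies).
#' @return List with `statistic`, `df`, `p.value`.
#' @export
chi_square_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal: expected counts are undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p.value = ct$p.value
  )
}

#' Pairwise prevalence comparisons with Bonferroni correction
#'
#' For every unordered pair of strategies, tests the between-sample
#' difference in relative prevalence with a 2 x 2 chi-square test (no
#' continuity correction). Bonferroni correction multiplies each p-value
#' by the number of pairs, capped at 1. Pairs whose 2 x 2 sub-table has a
#' zero marginal are skipped with a flag.
#'
#' @param table A 2 x k prevalence counts matrix (rows = samples).
#' @return Tibble with one row per strategy pair: `strategy_a`,
#'   `strategy_b`, `statistic`, `df`, `p.value`, `p.bonferroni`,
#'   `skipped`.
#' @export
pairwise_prevalence_tests <- function(table) {
  tab <- as.matrix(table)
  k <- ncol(tab)
  if (k < 2) {
    stop("need at least two strategies", call. = FALSE)
  }
  strategies <- colnames(tab)
  if (is.null(strategies)) {
    strategies <- as.character(seq_len(k))
  }
  pairs <- combn(k, 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(j) {
    sub <- tab[, pairs[, j], drop = FALSE]
    if (any(rowSums(sub) == 0) || any(colSums(sub) == 0)) {
      return(tibble::tibble(
        strategy_a = strategies[pairs[1, j]],
        strategy_b = strategies[pairs[2, j]],
        statistic = NA_real_, df = NA_real_,
        p.value = NA_real_, p.bonferroni = NA_real_, skipped = TRUE
      ))
    }
    res <- chi_square_independence(sub)
    tibble::tibble(
      strategy_a = strategies[pairs[1, j]],
      strategy_b = strategies[pairs[2, j]],
      statistic = res$statistic, df = res$df,
      p.value = res$p.value,
      p.bonferroni = min(1, res$p.value * n_pairs),
      skipped = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Residualize one variable with respect to another
#'
#' Ordinary least-squares residuals of `y` regressed on `x` (with
#' intercept): the part of `y` orthogonal to `x` and mean-zero. Used to
#' remove the shared variance of phi with theta before trait
#' correlations.
#'
#' @param y Response vector.
#' @param x Regressor vector (non-constant, same length, >= 3
#'   observations).
#' @return Residual vector.
#' @export
residualize <- function(y, x) {
  if (length(y) != length(x)) {
    stop("y and x must have equal length", call. = FALSE)
  }
  if (length(y) < 3) {
    stop("need at least three observations", call. = FALSE)
  }
  if (sd(x) == 0) {
    stop("constant regressor: residualization is undefined", call. = FALSE)
  }
  unname(stats::residuals(stats::lm(y ~ x)))
}
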