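test_that("Pearson test matches the hand-computed correlation", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(pearson_test(x, x)$r, 1)
  expect_equal(pearson_test(x, -x)$r, -1)
  res <- pearson_test(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(res$r, 6.5 / sqrt(5 * 8.75), tolerance = 1e-10)
  expect_equal(res$r, 0.9827, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_test(1:2, 1:2), "at least three")
  expect_error(pearson_test(1:3, 1:4), "equal length")
})

test_that("inter-participant distances enumerate all unordered pairs", {
  expect_equal(interparticipant_distances(c(0.1, 0.1), c(0, 0)), 0)
  expect_equal(
    interparticipant_distances(c(0, 0.3), c(0, 0.04)),
    sqrt(0.09 + 0.0016)
  )
  expect_length(interparticipant_distances(runif(4), runif(4)), 6)
  expect_error(interparticipant_distances(0.1, numeric(0)), "equal length")
})

test_that("Stuart-Maxwell reduces to McNemar and vanishes under
           symmetry", {
  # symmetric off-diagonals: marginals agree exactly
  sym <- matrix(c(10, 3, 7, 3, 20, 2, 7, 2, 30), 3, 3)
  expect_equal(stuart_maxwell(sym)$statistic, 0)
  # 2x2 with off-diagonals 8 and 2: McNemar (8-2)^2/(8+2)
  tab <- matrix(c(5, 2, 8, 7), 2, 2)
  res <- stuart_maxwell(tab)
  expect_equal(res$statistic, 3.6)
  expect_equal(res$df, 1)
  expect_equal(res$p.value, stats::pchisq(3.6, 1, lower.tail = FALSE))
  # diagonal-only table: degenerate, statistic 0
  diag4 <- diag(c(5, 8, 2, 9))
  res <- stuart_maxwell(diag4)
  expect_equal(res$statistic, 0)
  expect_true(res$generalized_inverse)
  expect_error(stuart_maxwell(matrix(1, 2, 3)), "square")
})

test_that("Stuart-Maxwell is invariant to category order and equals
           McNemar on random 2x2 tables", {
  set.seed(99)
  for (rep in 1:20) {
    tab <- matrix(rpois(16, 8), 4, 4)
    base <- stuart_maxwell(tab)
    perm <- sample(4)
    permuted <- stuart_maxwell(tab[perm, perm])
    expect_equal(permuted$statistic, base$statistic, tolerance = 1e-8)
    expect_equal(permuted$df, base$df)
  }
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 6) + 1, 2, 2)
    b <- tab[1, 2]
    c_ <- tab[2, 1]
    expect_equal(
      stuart_maxwell(tab)$statistic, (b - c_)^2 / (b + c_),
      tolerance = 1e-12
    )
  }
})

test_that("singular marginal covariance falls back to a generalized
           inverse with reduced df", {
  # an entirely empty category
  tab <- matrix(0, 4, 4)
  tab[1:3, 1:3] <- matrix(c(10, 2, 1, 3, 12, 2, 2, 1, 15), 3, 3)
  res <- stuart_maxwell(tab)
  expect_true(res$generalized_inverse)
  expect_lt(res$df, 3)
  # matches the full-rank statistic computed on the nonempty categories
  full <- stuart_maxwell(tab[1:3, 1:3])
  expect_equal(res$statistic, full$statistic, tolerance = 1e-8)
})

test_that("prevalence chi-square matches closed forms", {
  same <- rbind(c(10, 20, 30), c(10, 20, 30))
  expect_equal(chi_square_independence(same)$statistic, 0)
  res <- chi_square_independence(rbind(c(10, 0), c(0, 10)))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  res4 <- chi_square_independence(rbind(c(5, 10, 15, 20), c(8, 9, 14, 19)))
  expect_equal(res4$df, 3)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "marginal")
  # invariance to permutation; zero iff rows proportional
  set.seed(4)
  tab <- matrix(rpois(8, 20) + 1, 2, 4)
  perm <- sample(4)
  expect_equal(
    chi_square_independence(tab[, perm])$statistic,
    chi_square_independence(tab)$statistic,
    tolerance = 1e-10
  )
  prop <- rbind(c(4, 8, 12), 3 * c(4, 8, 12))
  expect_equal(chi_square_independence(prop)$statistic, 0)
})

test_that("pairwise prevalence tests apply the Bonferroni rule per pair", {
  tab <- rbind(
    study1 = c(GR = 10, GA = 5, IA = 40, MO = 39),
    study2 = c(GR = 3, GA = 12, IA = 22, MO = 18)
  )
  res <- pairwise_prevalence_tests(tab)
  expect_equal(nrow(res), choose(4, 2))
  expect_false(any(res$skipped))
  expect_equal(res$p.bonferroni, pmin(1, res$p.value * 6))
  # identical prevalence rows: every pair is null
  same <- rbind(c(10, 10, 10, 10), c(10, 10, 10, 10))
  expect_true(all(pairwise_prevalence_tests(same)$p.value == 1))
  # a strategy absent from both samples is skipped with a flag
  degen <- rbind(c(10, 0, 5), c(8, 0, 7))
  res <- pairwise_prevalence_tests(degen)
  expect_equal(sum(res$skipped), 2)
  expect_true(all(is.na(res$p.value[res$skipped])))
})

test_that("residualization is an exact orthogonal projection", {
  set.seed(12)
  x <- rnorm(50)
  y <- 0.4 * x + rnorm(50)
  r <- residualize(y, x)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_equal(sum(r * x), 0, tolerance = 1e-10)
  expect_equal(residualize(2 * x + 1, x), rep(0, 50), tolerance = 1e-12)
  # orthogonal design: residuals are just the centered response
  x2 <- rep(c(-1, 1), 25)
  y2 <- rnorm(50)
  y2 <- y2 - (sum(y2 * x2) / sum(x2 * x2)) * x2 # remove the x2 component
  expect_equal(residualize(y2, x2), y2 - mean(y2), tolerance = 1e-10)
  expect_error(residualize(y, rep(1, 50)), "constant")
})

test_that("transition tables count paired labels with stable diagonal", {
  a <- factor(c("GR", "GA", "IA", "MO"), levels = c("GR", "GA", "IA", "MO"))
  tt <- transition_table(a, a)
  expect_equal(diag(tt$table), setNames(rep(1L, 4), c("GR", "GA", "IA", "MO")))
  expect_equal(tt$percent_stable, 100)

  # 48 opportunists, one of whom shifts to guilt aversion
  from <- rep("MO", 48)
  to <- c("GA", rep("MO", 47))
  tt <- transition_table(from, to)
  expect_equal(tt$table["MO", "GA"], 1L)
  expect_equal(tt$row_percent["MO", "GA"], 100 / 48, tolerance = 1e-10)
  expect_equal(round(tt$row_percent["MO", "GA"], 1), 2.1)

  expect_error(transition_table(character(0), character(0)), "empty")
  expect_error(transition_table(c("a", "b"), "a"), "equal length")
})

test_that("type-I error of Stuart-Maxwell is nominal under marginal
           homogeneity", {
  # symmetric joint distribution (diagonal-dominant with uniform
  # symmetric exchange) implies equal marginals by construction
  set.seed(2024)
  p <- c(0.4, 0.1, 0.4, 0.1)
  joint <- 0.6 * diag(p) + 0.4 / 16
  joint <- as.vector(joint / sum(joint))
  rejections <- 0L
  n_sim <- 2000
  for (b in seq_len(n_sim)) {
    tab <- matrix(stats::rmultinom(1, 200, joint), 4, 4)
    if (stuart_maxwell(tab)$p.value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  rate <- rejections / n_sim
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
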