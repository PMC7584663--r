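# Trust-game task structure: game configurations, trial schedules, token
# accounting, and behavior-table I/O.

#' @importFrom stats rnorm runif sd
#' @importFrom utils read.csv write.csv combn
NULL

BEHAVIOR_COLUMNS <- c(
  "participant_id", "block_id", "trial_index", "investment",
  "true_multiplier", "believed_multiplier", "returned"
)

STRATEGY_LABELS <- c("GR", "GA", "IA", "MO")

new_game_config <- function(variant, endowment, conditions, n_trials) {
  structure(
    list(
      variant = variant,
      endowment = as.integer(endowment),
      conditions = conditions,
      n_trials = as.integer(n_trials)
    ),
    class = "game_config"
  )
}

# Condition proportions by number of multiplier levels: a three-level game
# uses the 25/50/25 design (half the rounds at the base multiplier); a
# single level is the standard Trust Game; any other count splits evenly.
condition_proportions <- function(m) {
  if (m == 1L) {
    1
  } else if (m == 3L) {
    c(0.25, 0.5, 0.25)
  } else {
    rep(1 / m, m)
  }
}

check_positive_integer <- function(x, what) {
  if (length(x) == 0) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x != round(x)) || any(x < 1)) {
    stop(what, " must contain positive integers", call. = FALSE)
  }
  as.integer(x)
}

condition_counts <- function(multipliers, n_trials, what) {
  props <- condition_proportions(length(multipliers))
  counts <- props * n_trials
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop(
      "n_trials = ", n_trials, " cannot realize the condition proportions (",
      paste(props, collapse = "/"), ") for ", what,
      " as exact integer trial counts",
      call. = FALSE
    )
  }
  list(proportions = props, counts = as.integer(round(counts)))
}

#' Construct a Hidden Multiplier Trust Game configuration
#'
#' In the hidden multiplier trust game (HMTG) the true multiplier applied to
#' the Investor's investment varies from round to round, while the Investor
#' is led to believe that a single fixed multiplier (the base multiplier)
#' always applies. With three multiplier levels, the lowered and raised
#' multipliers each occur on 25% of rounds and the base multiplier on 50%.
#'
#' @param multipliers Ordered set of true multipliers (e.g. `c(2, 4, 6)`).
#' @param believed The single multiplier the Investor believes applies. For
#'   a three-level game this must be the middle (base) multiplier.
#' @param n_trials Number of rounds in the block; must be divisible into the
#'   condition proportions as exact integer counts.
#' @param endowment Investor endowment in game tokens.
#' @return A `game_config` object with one row per multiplier condition
#'   (true multiplier, believed multiplier, proportion, trial count).
#' @examples
#' make_hmtg_config(c(2, 4, 6), believed = 4, n_trials = 80)
#' @export
make_hmtg_config <- function(multipliers, believed, n_trials = 80,
                             endowment = 10) {
  multipliers <- sort(check_positive_integer(multipliers, "multiplier set"))
  believed <- check_positive_integer(believed, "believed multiplier")
  if (length(believed) != 1L) {
    stop("believed must be a single multiplier", call. = FALSE)
  }
  n_trials <- check_positive_integer(n_trials, "n_trials")
  if (!believed %in% multipliers) {
    stop("believed multiplier must be a member of the multiplier set",
      call. = FALSE
    )
  }
  if (length(multipliers) == 3L && believed != multipliers[2]) {
    stop("for a three-level HMTG the believed multiplier must be the base ",
      "(middle) multiplier",
      call. = FALSE
    )
  }
  cc <- condition_counts(multipliers, n_trials, "the HMTG")
  conditions <- data.frame(
    true_multiplier = multipliers,
    believed_multiplier = rep(believed, length(multipliers)),
    proportion = cc$proportions,
    n_trials = cc$counts
  )
  new_game_config(
    variant = "HMTG", endowment = endowment,
    conditions = conditions, n_trials = n_trials
  )
}

#' Construct a False-Belief Multiplier Trust Game configuration
#'
#' The FBMTG inverts the HMTG: the true multiplier is fixed on every round,
#' while the multiplier the Investor believes applies varies from round to
#' round (25/50/25 for a three-level believed set, with 50% of Investors
#' believing in the middle value).
#'
#' @param believed_set Ordered set of Investor-believed multipliers.
#' @param true_multiplier The single true multiplier applied on every round.
#' @param n_trials Number of rounds in the block.
#' @param endowment Investor endowment in game tokens.
#' @return A `game_config` object.
#' @examples
#' make_fbmtg_config(c(2, 4, 6), true_multiplier = 4, n_trials = 80)
#' @export
make_fbmtg_config <- function(believed_set, true_multiplier, n_trials = 80,
                              endowment = 10) {
  believed_set <- sort(check_positive_integer(believed_set, "believed set"))
  true_multiplier <- check_positive_integer(
    true_multiplier, "true multiplier"
  )
  if (length(true_multiplier) != 1L) {
    stop("true_multiplier must be a single multiplier", call. = FALSE)
  }
  n_trials <- check_positive_integer(n_trials, "n_trials")
  cc <- condition_counts(believed_set, n_trials, "the FBMTG")
  conditions <- data.frame(
    true_multiplier = rep(true_multiplier, length(believed_set)),
    believed_multiplier = believed_set,
    proportion = cc$proportions,
    n_trials = cc$counts
  )
  new_game_config(
    variant = "FBMTG", endowment = endowment,
    conditions = conditions, n_trials = n_trials
  )
}

#' @export
print.game_config <- function(x, ...) {
  cat(sprintf(
    "<game_config: %s, %d trials, endowment %d tokens>\n",
    x$variant, x$n_trials, x$endowment
  ))
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

#' Tokens available to the Trustee on a trial
#'
#' The Trustee receives the investment multiplied by the true multiplier and
#' chooses how many of those tokens to return.
#'
#' @param investment Invested tokens (nonnegative integer).
#' @param multiplier True multiplier (positive integer).
#' @return Integer token count `investment * multiplier`; vectorized.
#' @examples
#' trustee_tokens(10, 4)
#' @export
trustee_tokens <- function(investment, multiplier) {
  if (any(!is.finite(investment)) || any(investment != round(investment)) ||
    any(investment < 0)) {
    stop("investment must be a nonnegative integer", call. = FALSE)
  }
  multiplier <- check_positive_integer(multiplier, "multiplier")
  as.integer(investment) * multiplier
}

#' Read a trial-level behavior table
#'
#' Reads a long-format CSV with one row per trial and columns
#' `participant_id`, `block_id`, `trial_index`, `investment`,
#' `true_multiplier`, `believed_multiplier`, `returned`. Every row is
#' validated: token columns must be integers, multipliers positive, and the
#' returned amount must satisfy `0 <= returned <= investment * multiplier`.
#' Violations are reported with their row number.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A tibble of validated trials.
#' @seealso [write_behavior_table()]
#' @export
read_behavior_table <- function(path) {
  tbl <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(BEHAVIOR_COLUMNS, names(tbl))
  if (length(missing) > 0) {
    stop("behavior table is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tbl <- tbl[BEHAVIOR_COLUMNS]
  validate_behavior_table(tbl)
  tibble::as_tibble(tbl)
}

validate_behavior_table <- function(tbl) {
  num_cols <- c(
    "trial_index", "investment", "true_multiplier",
    "believed_multiplier", "returned"
  )
  for (col in num_cols) {
    x <- tbl[[col]]
    bad <- which(!is.finite(x) | x != round(x))
    if (length(bad) > 0) {
      stop("row ", bad[1], ": column '", col, "' is not an integer token ",
        "count (value: ", x[bad[1]], ")",
        call. = FALSE
      )
    }
  }
  bad <- which(tbl$investment < 0)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": negative investment", call. = FALSE)
  }
  bad <- which(tbl$true_multiplier < 1 | tbl$believed_multiplier < 1)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": multipliers must be >= 1", call. = FALSE)
  }
  total <- tbl$investment * tbl$true_multiplier
  bad <- which(tbl$returned < 0 | tbl$returned > total)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": returned amount ", tbl$returned[bad[1]],
      " outside [0, ", total[bad[1]], "]",
      call. = FALSE
    )
  }
  invisible(tbl)
}

#' Write a trial-level behavior table
#'
#' @param records Data frame of trials with the standard behavior columns.
#' @param path Output CSV path.
#' @return Invisibly, the written data frame. `read_behavior_table()` on the
#'   written file reproduces the records exactly.
#' @export
write_behavior_table <- function(records, path) {
  records <- as.data.frame(records)[BEHAVIOR_COLUMNS]
  validate_behavior_table(records)
  write.csv(records, path, row.names = FALSE)
  invisible(records)
}

#' Write a game configuration to JSON
#'
#' @param config A `game_config` object.
#' @param path Output JSON path.
#' @export
write_game_config <- function(config, path) {
  stopifnot(inherits(config, "game_config"))
  jsonlite::write_json(
    list(
      variant = config$variant,
      endowment = config$endowment,
      n_trials = config$n_trials,
      conditions = config$conditions
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(config)
}

#' Read a game configuration from JSON
#'
#' @param path Path to a JSON file written by [write_game_config()].
#' @return A `game_config` object, re-validated through the appropriate
#'   constructor.
#' @export
read_game_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  conds <- as.data.frame(raw$conditions)
  if (raw$variant == "HMTG") {
    make_hmtg_config(
      multipliers = conds$true_multiplier,
      believed = unique(conds$believed_multiplier),
      n_trials = raw$n_trials,
      endowment = raw$endowment
    )
  } else if (raw$variant == "FBMTG") {
    make_fbmtg_config(
      believed_set = conds$believed_multiplier,
      true_multiplier = unique(conds$true_multiplier),
      n_trials = raw$n_trials,
      endowment = raw$endowment
    )
  } else {
    stop("unknown game variant: ", raw$variant, call. = FALSE)
  }
}
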