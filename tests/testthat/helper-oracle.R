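# Independent brute-force oracle for model predictions: scalar utility
# arithmetic and an explicit enumeration loop, sharing no code with the
# package's vectorized component cache.

oracle_utility <- function(model, params, investment, multiplier,
                           believed, s2, endowment = 10) {
  total <- investment * multiplier
  pay <- (total - s2) / total
  g <- ((0.5 * believed * investment - s2) / (believed * investment))^2
  q <- ((total - s2) / (endowment - investment + total) - 0.5)^2
  if (model == "GR") {
    pay
  } else if (model == "GA") {
    pay - params[1] * g
  } else if (model == "IA") {
    pay - params[1] * q
  } else if (model == "MS") {
    params[1] * pay - (1 - params[1]) * min(g + params[2], q - params[2])
  } else {
    stop("unknown model")
  }
}

oracle_predict <- function(model, params, investment, multiplier,
                           believed, endowment = 10) {
  best_s <- 0L
  best_u <- -Inf
  for (s2 in 0:(investment * multiplier)) {
    u <- oracle_utility(model, params, investment, multiplier, believed,
      s2, endowment)
    if (u > best_u) {
      best_u <- u
      best_s <- s2
    }
  }
  best_s
}

# multiplier pairs (true, believed) appearing across the task variants
task_multiplier_pairs <- function() {
  rbind(
    data.frame(true = c(2, 4, 6), believed = 4),
    data.frame(true = c(4, 6, 8), believed = 6),
    data.frame(true = 4, believed = c(2, 6))
  )
}

# quick long-format record for one synthetic participant
make_record <- function(trials, returned, id = "p1", block = "b1") {
  tibble::tibble(
    participant_id = id,
    block_id = block,
    trial_index = seq_len(nrow(trials)),
    investment = trials$investment,
    true_multiplier = trials$true_multiplier,
    believed_multiplier = trials$believed_multiplier,
    returned = as.integer(returned)
  )
}
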