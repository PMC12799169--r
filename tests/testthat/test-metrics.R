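toy <- make_toy_transcript()

test_that("dominant proportion handles modes, ties and consensus", {
  tr3 <- tibble::tibble(run_id = "x", trial = 1, agent = 0:2, partner = c(1, 0, 2),
                        response = c("A", "A", "B"),
                        partner_response = c("A", "A", "B"),
                        matched = TRUE, points = 1)
  expect_equal(dominant_proportion(tr3, 1), 2 / 3)

  tr_tie <- tibble::tibble(run_id = "x", trial = 1, agent = 0:3, partner = c(1, 0, 3, 2),
                           response = c("A", "A", "B", "B"),
                           partner_response = c("A", "A", "B", "B"),
                           matched = TRUE, points = 1)
  expect_equal(dominant_proportion(tr_tie, 1), 0.5)  # tied modes share the count

  expect_equal(dominant_proportion(toy, 6), 1)
  expect_error(dominant_proportion(toy, 99), "not present")
})

test_that("response entropy matches the closed form and normalization", {
  expect_equal(response_entropy(toy, 6), 0)                      # consensus
  expect_equal(response_entropy(toy, 1), 1.5)                    # {a,b,c,c}
  expect_equal(response_entropy(toy, 1, normalized = TRUE), 0.75)

  tr_even <- tibble::tibble(run_id = "x", trial = 1, agent = 0:3, partner = c(1, 0, 3, 2),
                            response = c("A", "A", "B", "B"),
                            partner_response = c("A", "A", "B", "B"),
                            matched = TRUE, points = 1)
  expect_equal(response_entropy(tr_even, 1), 1)                  # two even classes
  tr_distinct <- tibble::tibble(run_id = "x", trial = 1, agent = 0:3, partner = c(1, 0, 3, 2),
                                response = c("A", "B", "C", "D"),
                                partner_response = c("B", "A", "D", "C"),
                                matched = FALSE, points = 0)
  expect_equal(response_entropy(tr_distinct, 1, normalized = TRUE), 1)
})

test_that("the toy transcript is classified exactly as hand-labelled", {
  labelled <- classify_decisions(toy)
  answer <- toy_strategy_labels()
  expect_equal(labelled$strategy, answer$strategy)
  # all four strategies are exercised, including the repeat-self tie rule
  expect_setequal(unique(answer$strategy),
                  c("new", "repeat_self", "repeat_partner", "earlier_context"))
  # row-wise classifier agrees everywhere
  for (r in seq_len(nrow(toy))) {
    expect_equal(classify_decision(toy, toy$agent[r], toy$trial[r]),
                 answer$strategy[r])
  }
  expect_error(classify_decision(toy[toy$trial > 2, ], 0, 4), "missing history")
})

test_that("the repeat-self tie rule beats repeat-partner when both apply", {
  # agents 0 and 1 agree at trial 1, then both stay: coded repeat_self
  tr <- tibble::tibble(run_id = "x", trial = rep(1:2, each = 2),
                       agent = rep(0:1, 2), partner = rep(1:0, 2),
                       response = "same", partner_response = "same",
                       matched = TRUE, points = c(1, 1, 2, 2))
  expect_equal(classify_decision(tr, 0, 2), "repeat_self")
})

test_that("strategy proportions partition each trial", {
  series <- strategy_time_series(toy)
  expect_equal(series$new[1], 1)  # trial 1 is all-new by definition
  sums <- series$new + series$repeat_self + series$repeat_partner +
    series$earlier_context
  expect_equal(sums, rep(1, nrow(series)))
})

test_that("all metrics agree exactly with naive row-scan oracles", {
  for (tr in c(list(toy = toy), small_transcripts())) {
    expect_lte(nrow(tr), 200L)
    for (t in unique(tr$trial)) {
      expect_equal(dominant_proportion(tr, t), naive_dominant(tr, t))
      expect_equal(response_entropy(tr, t), naive_entropy(tr, t))
      expect_equal(response_entropy(tr, t, normalized = TRUE),
                   naive_entropy(tr, t, normalized = TRUE))
    }
    labelled <- classify_decisions(tr)
    for (r in seq_len(nrow(tr))) {
      expect_equal(labelled$strategy[r],
                   naive_classify(tr, tr$agent[r], tr$trial[r]))
    }
    rates <- coordination_rate_by_response(tr)
    oracle <- naive_coord_rates(tr)
    rates <- as.data.frame(rates[order(rates$response), ])
    expect_equal(rates$response, oracle$response)
    expect_equal(rates$rate, oracle$rate)
    expect_equal(rates$count, oracle$count)
  }
})

test_that("coordination rates reflect matched fractions per token", {
  rates <- coordination_rate_by_response(toy)
  # token "c": produced at t1 by agents 2,3 (matched) and t2/t4 by agents 2/0
  c_row <- rates[rates$response == "c", ]
  expect_equal(c_row$count, 4L)
  expect_equal(c_row$rate, 0.5)
  # token "d" never coordinated
  expect_equal(rates$rate[rates$response == "d"], 0)
})

test_that("partner-context entropy is a trial-order-invariant multiset measure", {
  expect_equal(partner_context_entropy(toy, 1),
               shannon_entropy_ref(c("a", "d", "d", "c", "a", "a")))
  # all-identical context has zero entropy
  tr <- tibble::tibble(run_id = "x", trial = 1:4, agent = 0, partner = 1,
                       response = c("p", "q", "r", "s"), partner_response = "z",
                       matched = FALSE, points = 0)
  expect_equal(partner_context_entropy(tr, 0), 0)
  # equal two-way split gives exactly one bit
  tr$partner_response <- c("a", "b", "a", "b")
  expect_equal(partner_context_entropy(tr, 0), 1)
  shuffled <- tr[c(3, 1, 4, 2), ]
  expect_equal(partner_context_entropy(shuffled, 0), 1)
})

test_that("the tidy metrics table is long-format and complete", {
  tabs <- metrics_table(toy)
  expect_setequal(names(tabs), c("run_id", "trial", "measure", "value"))
  expect_setequal(unique(tabs$measure),
                  c("dominant_proportion", "entropy", "normalized_entropy",
                    "strategy_new", "strategy_repeat_self",
                    "strategy_repeat_partner", "strategy_earlier_context"))
  expect_equal(nrow(tabs), 6 * 7)
})
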