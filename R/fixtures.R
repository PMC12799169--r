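#' Hand-authored toy transcript with known strategy labels
#'
#' A 4-agent, 6-trial transcript constructed by hand as ground truth for the
#' decision-strategy classifier. It exercises all four labels (including the
#' repeat-self coding of trials where repeating self and repeating partner
#' coincide) and ends in full consensus on `"a"`. The intended label for
#' every agent-trial is returned by [toy_strategy_labels()].
#'
#' @return A transcript tibble with 24 rows (`run_id = "toy"`).
#' @examples
#' tr <- make_toy_transcript()
#' identical(classify_decisions(tr)$strategy, toy_strategy_labels()$strategy)
#' @export
make_toy_transcript <- function() {
  # pairings per trial: list of (a, b) 0-based pairs
  pairs <- list(
    rbind(c(0L, 1L), c(2L, 3L)),
    rbind(c(0L, 2L), c(1L, 3L)),
    rbind(c(0L, 3L), c(1L, 2L)),
    rbind(c(0L, 1L), c(2L, 3L)),
    rbind(c(0L, 2L), c(1L, 3L)),
    rbind(c(0L, 3L), c(1L, 2L))
  )
  # responses[t, i+1] = agent i's response at trial t
  responses <- rbind(
    c("a", "b", "c", "c"),  # t1: all new; agents 2,3 coordinate
    c("a", "a", "c", "d"),  # t2: 0 self, 1 copies 0, 2 self (tie rule), 3 new
    c("b", "a", "d", "a"),  # t3: 0 earlier (b from t1), 1 self, 2 new, 3 copies 1
    c("c", "a", "a", "a"),  # t4: 0 earlier (c received t2), 1 self, 2 copies, 3 self
    c("a", "a", "a", "a"),  # t5: 0 copies partner (t4 partner 1 said a), rest self
    c("a", "a", "a", "a")   # t6: all repeat self (ties also code repeat self)
  )
  n <- 4L
  points <- integer(n)
  rows <- vector("list", 6L)
  for (t in 1:6) {
    partner <- integer(n)
    for (r in 1:2) {
      a <- pairs[[t]][r, 1L]; b <- pairs[[t]][r, 2L]
      partner[a + 1L] <- b; partner[b + 1L] <- a
    }
    resp <- responses[t, ]
    matched <- resp == resp[partner + 1L]
    points <- points + as.integer(matched)
    rows[[t]] <- tibble::tibble(run_id = "toy", trial = t, agent = 0:(n - 1L),
                                partner = partner, response = resp,
                                partner_response = resp[partner + 1L],
                                matched = matched, points = points)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("transcript", class(out))
  out
}

#' @rdname make_toy_transcript
#' @return For `toy_strategy_labels()`: tibble with `trial`, `agent` and the
#'   hand-assigned `strategy` for every row of the toy transcript, in the
#'   same row order.
#' @export
toy_strategy_labels <- function() {
  labels <- rbind(
    c("new", "new", "new", "new"),
    c("repeat_self", "repeat_partner", "repeat_self", "new"),
    c("earlier_context", "repeat_self", "new", "repeat_partner"),
    c("earlier_context", "repeat_self", "repeat_partner", "repeat_self"),
    c("repeat_partner", "repeat_self", "repeat_self", "repeat_self"),
    c("repeat_self", "repeat_self", "repeat_self", "repeat_self")
  )
  tibble::tibble(
    trial = rep(1:6, each = 4L),
    agent = rep(0:3, times = 6L),
    strategy = as.character(t(labels))
  )
}
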