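trial_slice <- function(transcript, trial) {
  rows <- transcript[transcript$trial == trial, , drop = FALSE]
  if (nrow(rows) == 0L) stop("trial ", trial, " not present in transcript", call. = FALSE)
  rows
}

shannon_entropy <- function(tokens) {
  p <- as.numeric(table(tokens)) / length(tokens)
  -sum(p * log2(p))
}

#' Dominant-response proportion at a trial
#'
#' The proportion of the group producing the modal (most common)
#' canonicalized response at the given trial; the group-level convergence
#' measure. Ties over the mode do not affect the value, since tied modes
#' share the same count.
#'
#' @param transcript A transcript tibble (one row per agent per trial).
#' @param trial Trial index.
#' @return A real in `(0, 1]`, at least `1/N`.
#' @examples
#' tr <- make_toy_transcript()
#' dominant_proportion(tr, 6)  # 1
#' @export
dominant_proportion <- function(transcript, trial) {
  rows <- trial_slice(transcript, trial)
  tok <- canonicalize_response(rows$response)
  max(table(tok)) / length(tok)
}

#' Response-distribution entropy at a trial
#'
#' Shannon entropy (base 2) of the trial's canonicalized response frequency
#' distribution; the normalized variant divides by `log2(N)` so that 0 means
#' total consensus and 1 means all `N` responses distinct.
#'
#' @inheritParams dominant_proportion
#' @param normalized Divide by `log2(N)`?
#' @return Entropy in bits, or in `[0, 1]` when normalized.
#' @export
response_entropy <- function(transcript, trial, normalized = FALSE) {
  rows <- trial_slice(transcript, trial)
  h <- shannon_entropy(canonicalize_response(rows$response))
  if (normalized) h / log2(nrow(rows)) else h
}

#' Per-trial convergence series for a run
#'
#' @param transcript A transcript for a single run.
#' @return Tibble with `trial`, `dominant_proportion`, `entropy` and
#'   `normalized_entropy`.
#' @export
convergence_series <- function(transcript) {
  trials <- sort(unique(transcript$trial))
  tibble::tibble(
    trial = trials,
    dominant_proportion = vapply(trials, function(t)
      dominant_proportion(transcript, t), numeric(1)),
    entropy = vapply(trials, function(t)
      response_entropy(transcript, t), numeric(1)),
    normalized_entropy = vapply(trials, function(t)
      response_entropy(transcript, t, normalized = TRUE), numeric(1))
  )
}

strategy_labels <- c("new", "repeat_self", "repeat_partner", "earlier_context")

#' Classify one agent-trial decision
#'
#' Labels the agent's response at a trial with one of four decision
#' strategies:
#'
#' * `repeat_self` — the response repeats the agent's own previous-trial
#'   response. When the agent and its previous partner agreed (so repeating
#'   self and repeating partner coincide), the case is coded `repeat_self`,
#'   because self-consistency was rewarded on that trial.
#' * `repeat_partner` — the response repeats the partner response the agent
#'   received on the previous trial.
#' * `earlier_context` — the response appears among the agent's own
#'   productions or received partner responses on trials up to `t - 2`.
#' * `new` — neither the agent nor any partner had produced the response on
#'   a previous trial; trial 1 is always `new`.
#'
#' All comparisons use canonicalized tokens.
#'
#' @param transcript A transcript tibble.
#' @param agent 0-based agent id.
#' @param trial Trial index (>= 1).
#' @return One of `"new"`, `"repeat_self"`, `"repeat_partner"`,
#'   `"earlier_context"`.
#' @export
classify_decision <- function(transcript, agent, trial) {
  hist <- transcript[transcript$agent == agent & transcript$trial <= trial, ,
                     drop = FALSE]
  hist <- hist[order(hist$trial), , drop = FALSE]
  if (!setequal(as.integer(hist$trial), seq_len(as.integer(trial)))) {
    stop("transcript is missing history rows for agent ", agent,
         " up to trial ", trial, call. = FALSE)
  }
  own <- canonicalize_response(hist$response)
  received <- canonicalize_response(hist$partner_response)
  r <- own[trial]
  if (trial == 1L) return("new")
  if (r == own[trial - 1L]) return("repeat_self")
  if (r == received[trial - 1L]) return("repeat_partner")
  if (trial > 2L) {
    earlier <- c(own[seq_len(trial - 2L)], received[seq_len(trial - 2L)])
    if (r %in% earlier) return("earlier_context")
  }
  "new"
}

#' Classify every agent-trial decision in a transcript
#'
#' Vectorized equivalent of [classify_decision()] over all rows.
#'
#' @param transcript A transcript tibble.
#' @return The transcript with an added `strategy` column.
#' @export
classify_decisions <- function(transcript) {
  out <- transcript
  out$strategy <- NA_character_
  for (a in unique(transcript$agent)) {
    idx <- which(transcript$agent == a)
    idx <- idx[order(transcript$trial[idx])]
    own <- canonicalize_response(transcript$response[idx])
    received <- canonicalize_response(transcript$partner_response[idx])
    nt <- length(idx)
    lab <- character(nt)
    lab[1L] <- "new"
    seen <- character(0)
    for (t in seq_len(nt)[-1L]) {
      r <- own[t]
      lab[t] <- if (r == own[t - 1L]) "repeat_self"
        else if (r == received[t - 1L]) "repeat_partner"
        else if (r %in% seen) "earlier_context"
        else "new"
      seen <- c(seen, own[t - 1L], received[t - 1L])
    }
    out$strategy[idx] <- lab
  }
  out
}

#' Per-trial decision-strategy proportions
#'
#' For each trial, the proportion of agents whose decision is labelled with
#' each of the four strategies; the four proportions sum to 1.
#'
#' @param transcript A transcript tibble (may span several runs; proportions
#'   pool all agents present at each trial).
#' @return Tibble with columns `trial`, `new`, `repeat_self`,
#'   `repeat_partner`, `earlier_context`.
#' @export
strategy_time_series <- function(transcript) {
  labelled <- classify_decisions(transcript)
  trials <- sort(unique(labelled$trial))
  rows <- lapply(trials, function(t) {
    lab <- labelled$strategy[labelled$trial == t]
    props <- vapply(strategy_labels, function(s) mean(lab == s), numeric(1))
    tibble::tibble(trial = t, !!!as.list(props))
  })
  dplyr::bind_rows(rows)
}

#' Coordination rate per response token
#'
#' For each canonicalized token, the fraction of the records producing it
#' that were matched (coordinated) records.
#'
#' @param transcript A transcript tibble.
#' @return Tibble with `response` (canonical token), `rate` and `count`
#'   (times produced), sorted by decreasing rate.
#' @export
coordination_rate_by_response <- function(transcript) {
  tok <- canonicalize_response(transcript$response)
  df <- tibble::tibble(response = tok, matched = transcript$matched)
  out <- dplyr::summarise(dplyr::group_by(df, response),
                          rate = mean(matched), count = dplyr::n(),
                          .groups = "drop")
  dplyr::arrange(out, dplyr::desc(rate), response)
}

#' Entropy of the social context an agent experienced
#'
#' Shannon entropy (base 2) of the multiset of partner responses the agent
#' received across all trials; higher values mean the agent was exposed to a
#' more varied social context. Invariant to trial order.
#'
#' @param transcript A transcript tibble.
#' @param agent 0-based agent id.
#' @return Entropy in bits.
#' @export
partner_context_entropy <- function(transcript, agent) {
  rows <- transcript[transcript$agent == agent, , drop = FALSE]
  if (nrow(rows) == 0L) stop("agent ", agent, " not in transcript", call. = FALSE)
  shannon_entropy(canonicalize_response(rows$partner_response))
}

#' Export tidy per-trial metrics for downstream model fitting
#'
#' Long-format table (`run_id`, `trial`, `measure`, `value`) combining the
#' convergence series and strategy proportions for each run in a transcript,
#' suitable for regression fitting in any statistics environment.
#'
#' @param transcript A transcript tibble (possibly multiple runs).
#' @return Tidy tibble with one row per run, trial and measure.
#' @export
metrics_table <- function(transcript) {
  runs <- unique(transcript$run_id)
  out <- lapply(runs, function(rid) {
    tr <- transcript[transcript$run_id == rid, , drop = FALSE]
    conv <- convergence_series(tr)
    strat <- strategy_time_series(tr)
    long <- rbind(
      data.frame(trial = conv$trial, measure = "dominant_proportion",
                 value = conv$dominant_proportion),
      data.frame(trial = conv$trial, measure = "entropy", value = conv$entropy),
      data.frame(trial = conv$trial, measure = "normalized_entropy",
                 value = conv$normalized_entropy),
      do.call(rbind, lapply(strategy_labels, function(s) {
        data.frame(trial = strat$trial, measure = paste0("strategy_", s),
                   value = strat[[s]])
      }))
    )
    tibble::tibble(run_id = rid, tibble::as_tibble(long))
  })
  dplyr::bind_rows(out)
}
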