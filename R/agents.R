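#' Minimal Name Game agent state
#'
#' A Name Game agent carries only a vocabulary: the ordered set of responses
#' it currently entertains. Vocabularies start empty; the first response is
#' drawn from the prior library.
#'
#' @param agent_id 0-based agent id.
#' @param vocabulary Character vector without duplicates.
#' @return An object of class `name_game_state`.
#' @export
name_game_state <- function(agent_id, vocabulary = character(0)) {
  vocabulary <- canonicalize_response(vocabulary)
  if (anyDuplicated(vocabulary)) stop("vocabulary must not contain duplicates", call. = FALSE)
  structure(list(agent_id = as.integer(agent_id), vocabulary = vocabulary),
            class = "name_game_state")
}

#' Produce a Name Game response
#'
#' A uniform selection from the agent's current vocabulary; on trial 1 (empty
#' vocabulary) the response is drawn from the prior library instead.
#'
#' @param state A [name_game_state()].
#' @param prior A `prior_library` used only when the vocabulary is empty.
#' @return A single token.
#' @export
name_game_respond <- function(state, prior) {
  v <- state$vocabulary
  if (length(v) == 0L) {
    if (is.null(prior) || length(prior$tokens) == 0L) {
      stop("empty vocabulary and empty prior: no response possible", call. = FALSE)
    }
    return(sample_prior(prior))
  }
  if (length(v) == 1L) v else sample(v, 1L)
}

#' Apply the Name Game vocabulary update
#'
#' One player per pair is the speaker. If the spoken token is already in the
#' hearer's vocabulary the interaction succeeds and *both* vocabularies
#' collapse to contain only that token; otherwise the token is added to the
#' hearer's vocabulary and the speaker is unchanged.
#'
#' @param speaker,hearer [name_game_state()] objects.
#' @param spoken The speaker's response this trial (canonicalized for the
#'   membership test).
#' @return List with updated `speaker` and `hearer` states.
#' @examples
#' s <- name_game_state(0, c("a", "c")); h <- name_game_state(1, c("a", "b"))
#' name_game_update(s, h, "a")  # both collapse to "a"
#' @export
name_game_update <- function(speaker, hearer, spoken) {
  spoken <- canonicalize_response(spoken)
  if (spoken %in% hearer$vocabulary) {
    speaker$vocabulary <- spoken
    hearer$vocabulary <- spoken
  } else {
    hearer$vocabulary <- c(hearer$vocabulary, spoken)
  }
  list(speaker = speaker, hearer = hearer)
}

#' Context-Aware Agent parameters
#'
#' The Context-Aware Agent (CAA) mixes two response sources: with
#' probability \eqn{p_t} it samples from its prior library (background
#' knowledge about viable responses) and otherwise from a memory trace of its
#' interaction history (social context). The prior-sampling probability
#' starts at \eqn{\alpha} and decays over trials, capturing that background
#' knowledge becomes progressively less important as interaction unfolds.
#'
#' The memory trace is a decay-weighted multiset of tokens: each trial all
#' existing weights are multiplied by `recency_decay`, then the agent's own
#' response and its partner's response are each added with weight 1,
#' multiplied by `match_bonus` when the pair coordinated. This reference rule
#' is a documented stand-in for the under-specified social-context update;
#' all three knobs are exposed so the mechanism can be varied. The defaults
#' (`match_bonus = 5`, `recency_decay = 0.7`) were fixed by a sensitivity
#' sweep to the regime where purely social agents (`alpha = 0`) reproduce
#' the canonical structure effect — fully connected groups reach lower
#' final response entropy than ring lattices — which weaker reinforcement
#' or no forgetting wash out; see the methods vignette.
#'
#' @param alpha Baseline prior-sampling weight in `[0, 1]`. May be a single
#'   value shared by all agents, or per-agent values drawn via `alpha_beta`.
#' @param schedule Decay schedule of the prior-sampling probability over
#'   trials: `"linear"` (`alpha * (1 - (t - 1) / T)`, the reference),
#'   `"exponential"` (`alpha * schedule_rate^(t - 1)`) or `"constant"`.
#' @param schedule_rate Rate for the exponential schedule, in `(0, 1]`.
#' @param match_bonus Multiplier (>= 1) on memory weight added after a
#'   coordinated trial.
#' @param recency_decay Per-trial multiplicative decay of existing memory
#'   weights, in `(0, 1]`; 1 disables forgetting.
#' @param alpha_beta Optional `c(shape1, shape2)`: when supplied, each agent
#'   draws its own alpha from this Beta distribution at run start.
#' @return An object of class `caa_params`.
#' @export
caa_params <- function(alpha = 0.5,
                       schedule = c("linear", "exponential", "constant"),
                       schedule_rate = 0.9,
                       match_bonus = 5,
                       recency_decay = 0.7,
                       alpha_beta = NULL) {
  schedule <- match.arg(schedule)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (schedule_rate <= 0 || schedule_rate > 1) {
    stop("`schedule_rate` must lie in (0, 1]", call. = FALSE)
  }
  if (match_bonus < 1) stop("`match_bonus` must be >= 1", call. = FALSE)
  if (recency_decay <= 0 || recency_decay > 1) {
    stop("`recency_decay` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(alpha_beta) && (length(alpha_beta) != 2L || any(alpha_beta <= 0))) {
    stop("`alpha_beta` must be two positive Beta shape parameters", call. = FALSE)
  }
  structure(list(alpha = alpha, schedule = schedule,
                 schedule_rate = schedule_rate, match_bonus = match_bonus,
                 recency_decay = recency_decay, alpha_beta = alpha_beta),
            class = "caa_params")
}

#' Context-Aware Agent state
#'
#' @param agent_id 0-based agent id.
#' @param alpha This agent's prior-sampling weight in `[0, 1]`.
#' @param memory Named numeric vector of strictly positive token weights
#'   (empty before trial 1).
#' @return An object of class `caa_state`.
#' @export
caa_state <- function(agent_id, alpha, memory = numeric(0)) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (length(memory) && (is.null(names(memory)) || any(memory <= 0))) {
    stop("memory weights must be named and strictly positive", call. = FALSE)
  }
  structure(list(agent_id = as.integer(agent_id), alpha = alpha,
                 memory = memory, last_response = NULL),
            class = "caa_state")
}

#' Prior-sampling probability at a given trial
#'
#' Returns \eqn{p_t}, the probability that a CAA samples its response from
#' the prior library (rather than from social context) at trial `t` of `T`:
#' `alpha * (1 - (t - 1) / T)` for the linear schedule,
#' `alpha * schedule_rate^(t - 1)` for the exponential schedule, and `alpha`
#' for the constant schedule. All schedules are nonincreasing in `t` and stay
#' in `[0, 1]`.
#'
#' @param alpha Prior-sampling weight in `[0, 1]`.
#' @param trial Trial index `t` in `1..T`.
#' @param trials Total number of trials `T`.
#' @param params A [caa_params()] supplying the schedule.
#' @return The probability \eqn{p_t}.
#' @examples
#' caa_sample_probability(1, 40, 40, caa_params(schedule = "linear"))  # 1/40
#' @export
caa_sample_probability <- function(alpha, trial, trials, params = caa_params()) {
  if (trial < 1 || trial > trials) {
    stop("`trial` must lie in 1..trials", call. = FALSE)
  }
  p <- switch(params$schedule,
    linear = alpha * (1 - (trial - 1) / trials),
    exponential = alpha * params$schedule_rate^(trial - 1),
    constant = alpha
  )
  min(max(p, 0), 1)
}

#' Produce a Context-Aware Agent response
#'
#' With probability \eqn{p_t} (see [caa_sample_probability()]) the token is
#' drawn from the prior library; otherwise from the memory trace with
#' probability proportional to the stored weights. An empty memory trace
#' (trial 1) always falls back to the prior.
#'
#' @param state A [caa_state()].
#' @param prior A `prior_library`.
#' @param trial,trials Current trial and total trials.
#' @param params A [caa_params()].
#' @return A single token.
#' @export
caa_respond <- function(state, prior, trial, trials, params = caa_params()) {
  if (is.null(prior) || length(prior$tokens) == 0L) {
    stop("CAA requires a nonempty prior library", call. = FALSE)
  }
  p <- caa_sample_probability(state$alpha, trial, trials, params)
  mem <- state$memory
  if (length(mem) == 0L || stats::runif(1) < p) {
    sample_prior(prior)
  } else if (length(mem) == 1L) {
    names(mem)
  } else {
    sample(names(mem), 1L, prob = mem)
  }
}

#' Update a Context-Aware Agent's memory trace
#'
#' Existing weights decay by `recency_decay`; the agent's own token and the
#' partner's token are each reinforced with weight 1, scaled by `match_bonus`
#' when the trial coordinated.
#'
#' @param state A [caa_state()].
#' @param own The agent's own response this trial.
#' @param partner The partner's response this trial.
#' @param matched Logical: did the canonicalized responses coincide?
#' @param params A [caa_params()].
#' @return The updated `caa_state`.
#' @examples
#' st <- caa_state(0, 0.5, c(a = 1))
#' p <- caa_params(recency_decay = 1, match_bonus = 2)
#' caa_update(st, "a", "a", TRUE, p)$memory  # a: 1 + 2 + 2 = 5
#' @export
caa_update <- function(state, own, partner, matched, params = caa_params()) {
  own <- canonicalize_response(own)
  partner <- canonicalize_response(partner)
  if (matched != (own == partner)) {
    stop("`matched` must equal own == partner after canonicalization", call. = FALSE)
  }
  mem <- state$memory * params$recency_decay
  w <- if (matched) params$match_bonus else 1
  for (tok in c(own, partner)) {
    mem[tok] <- if (tok %in% names(mem)) mem[tok] + w else w
  }
  state$memory <- mem
  state$last_response <- own
  state
}
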