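#' Configure a simulation run
#'
#' A run is a single networked experiment: `N` agents on a fixed network
#' interact for `T` trials. Each trial, agents are paired by a random perfect
#' matching within neighbourhoods, every agent produces one response, matched
#' pairs (identical canonicalized responses) each earn one point, and agent
#' states are updated per the chosen model before the next trial.
#'
#' @param network A [network_spec()].
#' @param trials Number of trials `T` (default 40).
#' @param content `"hashtag"` or `"name"`; selects the synthetic prior
#'   library condition.
#' @param model `"name_game"` (minimal Name Game) or `"caa"` (Context-Aware
#'   Agents).
#' @param caa A [caa_params()]; required when `model = "caa"`.
#' @param prior Optional explicit `prior_library`; by default one is built
#'   with [make_prior_library()] for the content condition.
#' @param prior_spec Optional named list of extra arguments passed to
#'   [make_prior_library()] (ignored when `prior` is given).
#' @param seed Integer seed; the transcript is a pure function of the full
#'   configuration including this seed.
#' @param run_id Identifier stamped on every transcript row.
#' @return An object of class `run_config`.
#' @export
run_config <- function(network, trials = 40L,
                       content = c("hashtag", "name"),
                       model = c("name_game", "caa"),
                       caa = NULL, prior = NULL, prior_spec = NULL,
                       seed = 1L, run_id = NULL) {
  content <- match.arg(content)
  model <- match.arg(model)
  if (!inherits(network, "network_spec")) stop("`network` must be a network_spec", call. = FALSE)
  trials <- as.integer(trials)
  if (trials < 1L) stop("`trials` must be >= 1", call. = FALSE)
  if (model == "caa") {
    if (is.null(caa)) caa <- caa_params()
    if (!inherits(caa, "caa_params")) stop("`caa` must be caa_params", call. = FALSE)
  }
  if (is.null(run_id)) {
    run_id <- sprintf("%s_%s_N%d_s%d", model, network$structure, network$size,
                      as.integer(seed))
  }
  structure(list(network = network, trials = trials, content = content,
                 model = model, caa = caa, prior = prior,
                 prior_spec = prior_spec, seed = as.integer(seed),
                 run_id = run_id),
            class = "run_config")
}

resolve_prior <- function(config) {
  if (!is.null(config$prior)) return(config$prior)
  args <- c(list(content = config$content), config$prior_spec)
  do.call(make_prior_library, args)
}

#' Run one simulated experiment
#'
#' Executes the trial loop for a [run_config()] and returns a tidy
#' transcript: one row per agent per trial. Within a trial all responses are
#' computed from pre-trial states (simultaneous semantics, as in the
#' concurrent online platform being emulated) and all state updates are
#' applied afterwards. For the Name Game, one member of each pair is
#' assigned speaker by a fair coin and the speaker's response drives the
#' vocabulary update; for CAA, every agent updates its memory trace with
#' both responses of its pair.
#'
#' @param config A [run_config()].
#' @param keep_state_trace If `TRUE`, attach per-trial per-agent state sizes
#'   (Name Game vocabulary size / CAA memory size) as attribute
#'   `"state_trace"` for diagnostics.
#' @return A tibble of class `c("transcript", ...)` with columns `run_id`,
#'   `trial`, `agent`, `partner`, `response`, `partner_response`, `matched`,
#'   `points` (cumulative per agent). Exactly `N * T` rows; for every row
#'   `(i, j, t)` a mirror row `(j, i, t)` exists with responses swapped.
#' @examples
#' tr <- run_simulation(run_config(network_spec(10, "homogeneous"),
#'                                 trials = 5, content = "name", seed = 1))
#' nrow(tr)  # 50
#' @export
run_simulation <- function(config, keep_state_trace = FALSE) {
  stopifnot(inherits(config, "run_config"))
  n <- config$network$size
  trials <- config$trials
  net <- build_network(config$network)
  prior <- resolve_prior(config)
  set.seed(config$seed)

  model <- config$model
  if (model == "name_game") {
    vocab <- replicate(n, character(0), simplify = FALSE)
  } else {
    params <- config$caa
    alphas <- if (!is.null(params$alpha_beta)) {
      stats::rbeta(n, params$alpha_beta[1], params$alpha_beta[2])
    } else rep(params$alpha, n)
    memory <- replicate(n, numeric(0), simplify = FALSE)
  }

  points <- integer(n)
  rows_trial <- vector("list", trials)
  state_trace <- if (keep_state_trace) matrix(NA_integer_, trials, n) else NULL

  for (t in seq_len(trials)) {
    pairing <- sample_pairing(net, t)
    partner <- integer(n)
    for (r in seq_len(nrow(pairing$pairs))) {
      a <- pairing$pairs[r, 1L]; b <- pairing$pairs[r, 2L]
      partner[a + 1L] <- b
      partner[b + 1L] <- a
    }

    responses <- character(n)
    if (model == "name_game") {
      for (i in seq_len(n)) {
        v <- vocab[[i]]
        responses[i] <- if (length(v) == 0L) sample_prior(prior)
                        else if (length(v) == 1L) v else sample(v, 1L)
      }
    } else {
      for (i in seq_len(n)) {
        p <- caa_sample_probability(alphas[i], t, trials, params)
        mem <- memory[[i]]
        responses[i] <- if (length(mem) == 0L || stats::runif(1) < p) {
          sample_prior(prior)
        } else if (length(mem) == 1L) names(mem)
          else sample(names(mem), 1L, prob = mem)
      }
    }

    matched <- responses == responses[partner + 1L]
    points <- points + as.integer(matched)

    # state updates from this trial's simultaneous outcomes
    if (model == "name_game") {
      # an agent with an empty (trial-1) vocabulary retains its own response
      for (i in seq_len(n)) {
        if (length(vocab[[i]]) == 0L) vocab[[i]] <- responses[i]
      }
      for (r in seq_len(nrow(pairing$pairs))) {
        a <- pairing$pairs[r, 1L]; b <- pairing$pairs[r, 2L]
        if (stats::runif(1) < 0.5) { sp <- a; he <- b } else { sp <- b; he <- a }
        spoken <- responses[sp + 1L]
        upd <- name_game_update(name_game_state(sp, vocab[[sp + 1L]]),
                                name_game_state(he, vocab[[he + 1L]]),
                                spoken)
        vocab[[sp + 1L]] <- upd$speaker$vocabulary
        vocab[[he + 1L]] <- upd$hearer$vocabulary
      }
    } else {
      decay <- params$recency_decay
      for (i in seq_len(n)) {
        mem <- memory[[i]] * decay
        w <- if (matched[i]) params$match_bonus else 1
        for (tok in c(responses[i], responses[partner[i] + 1L])) {
          mem[tok] <- if (tok %in% names(mem)) mem[tok] + w else w
        }
        memory[[i]] <- mem
      }
    }

    if (keep_state_trace) {
      state_trace[t, ] <- if (model == "name_game") {
        lengths(vocab)
      } else lengths(memory)
    }

    rows_trial[[t]] <- tibble::tibble(
      run_id = config$run_id,
      trial = t,
      agent = 0:(n - 1L),
      partner = partner,
      response = responses,
      partner_response = responses[partner + 1L],
      matched = matched,
      points = points
    )
  }

  out <- dplyr::bind_rows(rows_trial)
  attr(out, "config") <- config
  if (keep_state_trace) attr(out, "state_trace") <- state_trace
  class(out) <- c("transcript", class(out))
  out
}

#' Run a batch of configured simulations
#'
#' @param configs List of [run_config()] objects with distinct `run_id`s.
#' @return A single tidy tibble concatenating all transcripts (empty tibble
#'   with the transcript columns for an empty list).
#' @export
run_batch <- function(configs) {
  if (length(configs) == 0L) {
    return(tibble::tibble(run_id = character(0), trial = integer(0),
                          agent = integer(0), partner = integer(0),
                          response = character(0),
                          partner_response = character(0),
                          matched = logical(0), points = integer(0)))
  }
  ids <- vapply(configs, function(cf) cf$run_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate run_id in batch: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  dplyr::bind_rows(lapply(configs, run_simulation))
}

#' The packaged 26-run experimental design grid
#'
#' Reproduces the human-subject design: for the face-naming content, three
#' runs per network structure at sizes 20 and 50 (12 runs); for the hashtag
#' content the same twelve plus one run per structure at size 100 (14 runs).
#' Totals: 26 runs, 1,040 agents, and with 40 trials each, 41,600
#' interaction records.
#'
#' @param seed Root seed; run `r` of the grid uses `seed + r - 1` so the
#'   batch is reproducible while runs stay independent.
#' @param models Named character vector mapping content condition to agent
#'   model; by default face naming is simulated with the minimal Name Game
#'   and hashtag matching with Context-Aware Agents.
#' @param caa A [caa_params()] used for CAA runs.
#' @return List of 26 [run_config()] objects.
#' @export
human_design_grid <- function(seed = 1L,
                              models = c(name = "name_game", hashtag = "caa"),
                              caa = caa_params(alpha = 0.8)) {
  cells <- rbind(
    expand.grid(content = c("name", "hashtag"),
                structure = c("homogeneous", "spatial"),
                size = c(20L, 50L), rep = 1:3,
                stringsAsFactors = FALSE),
    expand.grid(content = "hashtag",
                structure = c("homogeneous", "spatial"),
                size = 100L, rep = 1L,
                stringsAsFactors = FALSE)
  )
  configs <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    cell <- cells[r, ]
    model <- unname(models[[cell$content]])
    configs[[r]] <- run_config(
      network = network_spec(cell$size, cell$structure),
      trials = 40L,
      content = cell$content,
      model = model,
      caa = if (model == "caa") caa else NULL,
      seed = seed + r - 1L,
      run_id = sprintf("%s_%s_N%d_rep%d", cell$content, cell$structure,
                       cell$size, cell$rep)
    )
  }
  configs
}

#' Sweep conditions and summarise convergence per trial
#'
#' Runs a full grid of alpha values, network structures, content conditions,
#' sizes and replicate seeds with the CAA model (alpha = 0 reduces to a
#' purely social agent) and returns per-run per-trial convergence summaries
#' in long format.
#'
#' @param alphas Numeric vector of alpha values.
#' @param structures Character vector of network structures.
#' @param contents Character vector of content conditions.
#' @param sizes Integer vector of network sizes.
#' @param n_seeds Number of replicate seeds per cell.
#' @param trials Trials per run.
#' @param seed Root seed.
#' @return Tibble with columns `alpha`, `structure`, `content`, `size`,
#'   `seed`, `trial`, `normalized_entropy`, `dominant_proportion`.
#' @export
run_sweep <- function(alphas = c(0, 0.5), structures = c("homogeneous", "spatial"),
                      contents = "hashtag", sizes = 20L, n_seeds = 3L,
                      trials = 40L, seed = 1L) {
  grid <- expand.grid(alpha = alphas, structure = structures,
                      content = contents, size = sizes,
                      rep = seq_len(n_seeds), stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) stop("empty sweep grid", call. = FALSE)
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    run_seed <- seed + r - 1L
    cfg <- run_config(network_spec(g$size, g$structure), trials = trials,
                      content = g$content, model = "caa",
                      caa = caa_params(alpha = g$alpha),
                      seed = run_seed,
                      run_id = sprintf("a%.2f_%s_%s_N%d_rep%d", g$alpha,
                                       g$structure, g$content, g$size, g$rep))
    tr <- run_simulation(cfg)
    series <- convergence_series(tr)
    out[[r]] <- tibble::tibble(alpha = g$alpha, structure = g$structure,
                               content = g$content, size = g$size,
                               seed = run_seed, trial = series$trial,
                               normalized_entropy = series$normalized_entropy,
                               dominant_proportion = series$dominant_proportion)
  }
  dplyr::bind_rows(out)
}

#' Write / read a transcript as CSV or JSON lines
#'
#' CSV uses a header row `run_id,trial,agent,partner,response,
#' partner_response,matched,points` with RFC 4180 quoting; JSONL writes one
#' record object per line.
#'
#' @param transcript A transcript tibble.
#' @param path Output path.
#' @export
write_transcript <- function(transcript, path) {
  utils::write.csv(as.data.frame(transcript)[, transcript_cols()],
                   path, row.names = FALSE)
  invisible(path)
}

transcript_cols <- function() {
  c("run_id", "trial", "agent", "partner", "response", "partner_response",
    "matched", "points")
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(run_id = "character",
                                       response = "character",
                                       partner_response = "character"))
  df$matched <- as.logical(df$matched)
  out <- tibble::as_tibble(df[, transcript_cols()])
  class(out) <- c("transcript", class(out))
  out
}

#' @rdname write_transcript
#' @export
write_transcript_jsonl <- function(transcript, path) {
  con <- file(path, "w")
  on.exit(close(con))
  df <- as.data.frame(transcript)[, transcript_cols()]
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
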