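# Independent brute-force oracles used to cross-check the implementations.

# shortest-path diameter by plain BFS over the neighbour list
bfs_diameter <- function(net) {
  n <- net$n
  ecc <- integer(n)
  for (s in 0:(n - 1L)) {
    dist <- rep(NA_integer_, n)
    dist[s + 1L] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in net$neighbors[[v + 1L]]) {
          if (is.na(dist[u + 1L])) {
            dist[u + 1L] <- dist[v + 1L] + 1L
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    if (anyNA(dist)) stop("disconnected")
    ecc[s + 1L] <- max(dist)
  }
  max(ecc)
}

# enumerate all perfect matchings of a small graph; returns canonical strings
enumerate_matchings <- function(net) {
  n <- net$n
  res <- character(0)
  recurse <- function(unmatched, acc) {
    if (length(unmatched) == 0L) {
      key <- paste(sort(acc), collapse = ";")
      res <<- c(res, key)
      return(invisible())
    }
    v <- unmatched[1L]
    for (u in intersect(net$neighbors[[v + 1L]], unmatched[-1L])) {
      recurse(setdiff(unmatched, c(v, u)),
              c(acc, paste(min(v, u), max(v, u), sep = "-")))
    }
  }
  recurse(0:(n - 1L), character(0))
  unique(res)
}

matching_key <- function(pairs) {
  paste(sort(paste(pairs[, 1], pairs[, 2], sep = "-")), collapse = ";")
}

# literal row-scan recomputations of the transcript metrics
naive_dominant <- function(transcript, trial) {
  toks <- tolower(sub("^#", "", trimws(
    transcript$response[transcript$trial == trial])))
  counts <- sapply(unique(toks), function(tk) sum(toks == tk))
  max(counts) / length(toks)
}

naive_entropy <- function(transcript, trial, normalized = FALSE) {
  toks <- tolower(sub("^#", "", trimws(
    transcript$response[transcript$trial == trial])))
  h <- 0
  for (tk in unique(toks)) {
    p <- sum(toks == tk) / length(toks)
    h <- h - p * log(p, base = 2)
  }
  if (normalized) h / log(length(toks), base = 2) else h
}

naive_classify <- function(transcript, agent, trial) {
  canon <- function(x) tolower(sub("^#", "", trimws(x)))
  row_at <- function(t) transcript[transcript$agent == agent &
                                     transcript$trial == t, ]
  if (trial == 1L) return("new")
  r <- canon(row_at(trial)$response)
  if (r == canon(row_at(trial - 1L)$response)) return("repeat_self")
  if (r == canon(row_at(trial - 1L)$partner_response)) return("repeat_partner")
  earlier <- character(0)
  for (t in seq_len(max(trial - 2L, 0L))) {
    earlier <- c(earlier, canon(row_at(t)$response),
                 canon(row_at(t)$partner_response))
  }
  if (r %in% earlier) return("earlier_context")
  "new"
}

naive_coord_rates <- function(transcript) {
  canon <- tolower(sub("^#", "", trimws(transcript$response)))
  toks <- sort(unique(canon))
  data.frame(
    response = toks,
    rate = sapply(toks, function(tk) mean(transcript$matched[canon == tk])),
    count = sapply(toks, function(tk) sum(canon == tk)),
    row.names = NULL
  )
}

shannon_entropy_ref <- function(tokens) {
  h <- 0
  for (tk in unique(tokens)) {
    p <- sum(tokens == tk) / length(tokens)
    h <- h - p * log(p, base = 2)
  }
  h
}

# closed-form Welch statistic for the two-sample comparison
welch_by_hand <- function(x, y) {
  vx <- sum((x - mean(x))^2) / (length(x) - 1)
  vy <- sum((y - mean(y))^2) / (length(y) - 1)
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                 vy^2 / (length(y)^2 * (length(y) - 1)))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# small simulated transcripts (<= 200 rows) for oracle-equivalence checks
small_transcripts <- function() {
  list(
    name_game = run_simulation(run_config(network_spec(10, "homogeneous"),
                                          trials = 20, content = "name",
                                          seed = 11)),
    caa = run_simulation(run_config(network_spec(10, "spatial"), trials = 20,
                                    content = "hashtag", model = "caa",
                                    caa = caa_params(alpha = 0.5), seed = 12))
  )
}
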