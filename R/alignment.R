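#' Split a response into words for embedding
#'
#' Strips a leading `#`, splits camel case, underscores and other
#' non-alphanumeric separators into words, and lowercases, so
#' `#NuclearDisaster` embeds like `"nuclear disaster"`.
#'
#' @param text A single string.
#' @return Character vector of lowercase words.
#' @export
tokenize_text <- function(text) {
  text <- sub("^#", "", trimws(as.character(text)))
  text <- gsub("([a-z])([A-Z])", "\\1 \\2", text)
  words <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  words[nzchar(words)]
}

# deterministic polynomial string hash (31-ary over char codes, kept < 2^31)
.hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

#' Deterministic n-gram hashing embedder
#'
#' A pluggable embedder is any pure function mapping a text to a fixed-length
#' numeric vector (identical text always yields the identical vector, and
#' nonempty text a nonzero vector). This constructor returns the packaged
#' fixture embedder: a hashed bag of character n-grams. Each word is padded
#' with `_` and decomposed into character n-grams; each n-gram (and each
#' whole word) is hashed to one of `dim` signed buckets and counted. The
#' result is crude but fully deterministic and download-free, which is what
#' the test suite and simulations need. Adapters for pretrained sentence
#' encoders can be dropped in wherever an `embedder` argument is accepted —
#' any `function(text) -> numeric(d)` works.
#'
#' @param dim Embedding dimension (>= 2).
#' @param n N-gram length (default 3).
#' @return A function `text -> numeric(dim)`.
#' @examples
#' emb <- ngram_embedder()
#' identical(emb("tsunami"), emb("#Tsunami"))
#' @export
ngram_embedder <- function(dim = 64L, n = 3L) {
  dim <- as.integer(dim); n <- as.integer(n)
  if (dim < 2L) stop("`dim` must be >= 2", call. = FALSE)
  function(text) {
    words <- tokenize_text(text)
    v <- numeric(dim)
    if (length(words) == 0L) stop("cannot embed empty text", call. = FALSE)
    for (w in words) {
      grams <- w
      padded <- paste0("_", w, "_")
      if (nchar(padded) >= n) {
        starts <- seq_len(nchar(padded) - n + 1L)
        grams <- c(grams, substring(padded, starts, starts + n - 1L))
      }
      for (g in grams) {
        h <- .hash_string(g)
        idx <- (h %% dim) + 1L
        sgn <- if ((h %/% dim) %% 2 == 0) 1 else -1
        v[idx] <- v[idx] + sgn
      }
    }
    if (all(v == 0)) v[1] <- 1  # degenerate full cancellation guard
    v
  }
}

#' Cosine similarity between two vectors
#'
#' `dot(u, v) / (||u|| ||v||)`, clipped to `[-1, 1]` against round-off.
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return A real in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 2), c(2, 1))  # 0.8
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector", call. = FALSE)
  min(max(sum(u * v) / (nu * nv), -1), 1)
}

softmax <- function(x, tau) {
  z <- x / tau
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Narrative alignment vector for one hashtag
#'
#' Computes the cosine similarity between the hashtag's embedding and each
#' narrative event's text embedding, then normalizes the similarity vector
#' with a temperature-scaled softmax, `a_i = exp(s_i / tau) / sum_j
#' exp(s_j / tau)` (evaluated with max subtraction for numerical stability).
#' The result is a simplex over events that proxies the responder's narrative
#' credence: low `tau` sharpens toward the best-matching event, high `tau`
#' flattens toward uniform.
#'
#' @param hashtag A single response string (nonempty after canonicalization).
#' @param events An event set tibble (see [fukushima_events()]).
#' @param embedder A `function(text) -> numeric(d)`; default the packaged
#'   [ngram_embedder()].
#' @param tau Softmax temperature, > 0 (default 0.1).
#' @return An object of class `alignment_vector`: list with `similarities`
#'   and `credences` (both named by event), and `tau`.
#' @export
alignment_vector <- function(hashtag, events, embedder = ngram_embedder(),
                             tau = 0.1) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("`tau` must be a single positive number", call. = FALSE)
  }
  events <- validate_event_set(events)
  if (!nzchar(paste(tokenize_text(hashtag), collapse = ""))) {
    stop("hashtag is empty after canonicalization", call. = FALSE)
  }
  h <- embedder(hashtag)
  s <- vapply(events$text, function(txt) cosine_similarity(h, embedder(txt)),
              numeric(1), USE.NAMES = FALSE)
  names(s) <- events$name
  a <- softmax(s, tau)
  names(a) <- events$name
  structure(list(similarities = s, credences = a, tau = tau),
            class = "alignment_vector")
}

#' @export
print.alignment_vector <- function(x, ...) {
  top <- names(x$credences)[which.max(x$credences)]
  cat(sprintf("<alignment_vector> tau = %g, argmax = %s (%.3f)\n",
              x$tau, top, max(x$credences)))
  invisible(x)
}

#' Mean narrative alignment over an agent's hashtags
#'
#' The arithmetic mean of the per-hashtag alignment vectors; being a convex
#' combination of simplices, the result is itself a simplex over events.
#'
#' @param hashtags Nonempty character vector of one agent's responses.
#' @inheritParams alignment_vector
#' @return Named numeric simplex over events.
#' @export
mean_alignment <- function(hashtags, events, embedder = ngram_embedder(),
                           tau = 0.1) {
  if (length(hashtags) == 0L) stop("agent produced no hashtags", call. = FALSE)
  mats <- vapply(hashtags, function(h) {
    alignment_vector(h, events, embedder, tau)$credences
  }, numeric(nrow(tibble::as_tibble(events))))
  rowMeans(mats)
}

#' Aggregate event credences into narrative-role scores
#'
#' Sums a per-event credence simplex within each causal-role label (`topic`,
#' `cause`, `plant_damage`, `first_order_effect`, `second_order_effect`);
#' the result is a simplex over the labels present in the event set.
#'
#' @param credences Named numeric simplex over event names (e.g. from
#'   [mean_alignment()] or an [alignment_vector()]'s `credences`).
#' @param events The event set defining each event's label.
#' @return Named numeric vector of per-label scores.
#' @export
aggregate_by_label <- function(credences, events) {
  events <- validate_event_set(events)
  if (!setequal(names(credences), events$name)) {
    stop("credences must be named by the event set's event names", call. = FALSE)
  }
  lab <- stats::setNames(events$label, events$name)[names(credences)]
  out <- tapply(credences, lab, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Welch two-sample comparison of alignment scores
#'
#' The generic unequal-variance two-sample t test used to compare per-agent
#' narrative-alignment scores between groups (e.g. network structures).
#'
#' @param scores1,scores2 Numeric vectors, each of length >= 2 with nonzero
#'   variance.
#' @return List with `t` (Welch statistic), `df` (Welch-Satterthwaite
#'   degrees of freedom) and `p` (two-sided p value).
#' @export
compare_groups <- function(scores1, scores2) {
  if (length(scores1) < 2L || length(scores2) < 2L) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  if (stats::var(scores1) == 0 && stats::var(scores2) == 0) {
    stop("both groups are constant; the test statistic is undefined", call. = FALSE)
  }
  ht <- stats::t.test(scores1, scores2, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Alignment table for many responses
#'
#' Convenience wrapper computing one alignment vector per row of a response
#' table and returning a tidy long table.
#'
#' @param responses Tibble/data frame with columns `agent` and `response`.
#' @inheritParams alignment_vector
#' @return Tibble with columns `agent`, `response`, `event`, `similarity`,
#'   `credence`.
#' @export
alignment_table <- function(responses, events, embedder = ngram_embedder(),
                            tau = 0.1) {
  events <- validate_event_set(events)
  rows <- lapply(seq_len(nrow(responses)), function(i) {
    av <- alignment_vector(responses$response[i], events, embedder, tau)
    tibble::tibble(agent = responses$agent[i],
                   response = responses$response[i],
                   event = names(av$credences),
                   similarity = unname(av$similarities),
                   credence = unname(av$credences))
  })
  dplyr::bind_rows(rows)
}
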