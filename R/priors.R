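#' Canonicalize a response token
#'
#' Responses are compared for coordination after canonicalization: a leading
#' `#` is stripped, surrounding whitespace trimmed, and the token casefolded,
#' so `#Tsunami` and `tsunami` coordinate.
#'
#' @param x Character vector of raw responses.
#' @return Character vector of canonical tokens.
#' @examples
#' canonicalize_response(c("#Tsunami", "  Emily "))
#' @export
canonicalize_response <- function(x) {
  x <- sub("^#", "", trimws(as.character(x)))
  tolower(x)
}

# common first names used to populate synthetic name-condition priors
.name_pool <- c(
  "emily", "maddie", "taylor", "mary", "sarah", "anna", "kate", "laura",
  "jessica", "rachel", "megan", "claire", "hannah", "grace", "olivia",
  "sophia", "amelia", "chloe", "lily", "ella", "nora", "ruby", "ivy",
  "june", "rose", "faye", "tess", "wren", "cora", "isla"
)

#' Construct a synthetic prior response library
#'
#' Agents sample first responses (and, for Context-Aware Agents, later
#' prior-driven responses) from a skewed prior distribution over candidate
#' tokens, standing in for participants' background knowledge about viable
#' responses. Two content conditions are emulated:
#'
#' * `"hashtag"`: a fraction `core_mass` of probability is concentrated on
#'   `n_core_events` event-tagged tokens (default 8, one per causal event of
#'   the packaged disaster narrative), distributed Zipf-wise among them; the
#'   remainder is Zipf-distributed over a long tail of idiosyncratic
#'   hashtags. This mimics priors anchored to a narrative's causal structure.
#' * `"name"`: a flatter Zipf distribution over interchangeable, untagged
#'   name tokens; no event tags, because face names carry no causal content.
#'
#' @param content `"hashtag"` or `"name"`.
#' @param n_tokens Total number of candidate tokens (default 50 hashtag /
#'   30 name).
#' @param zipf_exponent Zipf exponent `s` (rank-`r` weight `r^-s`); default
#'   1.2 for hashtags, 0.8 for names (names are closer to interchangeable).
#' @param n_core_events Number of event-anchored core tokens (hashtag only).
#' @param core_mass Total probability on the core tokens (hashtag only).
#' @return An object of class `prior_library`: list with `tokens`, `probs`
#'   (a probability simplex) and `event_tags` (named character, hashtag
#'   condition only).
#' @examples
#' lib <- make_prior_library("hashtag")
#' sum(lib$probs)
#' @export
make_prior_library <- function(content = c("hashtag", "name"),
                               n_tokens = NULL,
                               zipf_exponent = NULL,
                               n_core_events = 8L,
                               core_mass = 0.6) {
  content <- match.arg(content)
  if (is.null(n_tokens)) n_tokens <- if (content == "hashtag") 50L else 30L
  if (is.null(zipf_exponent)) zipf_exponent <- if (content == "hashtag") 1.2 else 0.8
  n_tokens <- as.integer(n_tokens)
  if (content == "name") n_core_events <- 0L
  if (n_core_events < 0L || n_tokens < n_core_events) {
    stop("need n_tokens >= n_core_events >= 0", call. = FALSE)
  }
  if (core_mass < 0 || core_mass >= 1) {
    stop("`core_mass` must lie in [0, 1)", call. = FALSE)
  }
  zipf <- function(m, s) {
    if (m == 0L) return(numeric(0))
    w <- seq_len(m)^(-s)
    w / sum(w)
  }
  if (content == "hashtag") {
    events <- fukushima_events()
    core_names <- events$name[seq_len(min(n_core_events, nrow(events)))]
    if (n_core_events > length(core_names)) {
      core_names <- c(core_names,
                      sprintf("event%02d", seq_len(n_core_events - length(core_names))))
    }
    n_tail <- n_tokens - n_core_events
    tail_tokens <- if (n_tail > 0L) sprintf("tag%02d", seq_len(n_tail)) else character(0)
    tokens <- c(core_names, tail_tokens)
    probs <- c(core_mass * zipf(n_core_events, zipf_exponent),
               (1 - core_mass) * zipf(n_tail, zipf_exponent))
    event_tags <- stats::setNames(core_names, core_names)
  } else {
    tokens <- if (n_tokens <= length(.name_pool)) {
      .name_pool[seq_len(n_tokens)]
    } else {
      c(.name_pool, sprintf("name%02d", seq_len(n_tokens - length(.name_pool))))
    }
    probs <- zipf(n_tokens, zipf_exponent)
    event_tags <- NULL
  }
  prior_library(tokens, probs, event_tags)
}

#' Assemble a prior library from tokens and probabilities
#'
#' @param tokens Character vector of response tokens (canonicalized; must be
#'   unique afterwards).
#' @param probs Nonnegative weights summing to 1 within `1e-9`.
#' @param event_tags Optional named character vector mapping tokens to
#'   narrative-event labels.
#' @return A `prior_library`.
#' @export
prior_library <- function(tokens, probs, event_tags = NULL) {
  tokens <- canonicalize_response(tokens)
  if (anyDuplicated(tokens)) {
    stop("tokens must be unique after canonicalization", call. = FALSE)
  }
  if (length(probs) != length(tokens) || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-9) {
    stop("`probs` must be a probability simplex over `tokens`", call. = FALSE)
  }
  structure(list(tokens = tokens, probs = as.numeric(probs),
                 event_tags = event_tags),
            class = "prior_library")
}

#' @export
print.prior_library <- function(x, ...) {
  cat(sprintf("<prior_library> %d tokens%s; top: %s\n",
              length(x$tokens),
              if (is.null(x$event_tags)) "" else
                sprintf(" (%d event-tagged)", length(x$event_tags)),
              paste(utils::head(x$tokens[order(-x$probs)], 3), collapse = ", ")))
  invisible(x)
}

#' Draw tokens from a prior library
#'
#' @param prior A `prior_library`.
#' @param n Number of draws.
#' @return Character vector of sampled tokens.
#' @export
sample_prior <- function(prior, n = 1L) {
  if (length(prior$tokens) == 0L) stop("empty prior library", call. = FALSE)
  sample(prior$tokens, n, replace = TRUE, prob = prior$probs)
}

#' Write / read a prior library as JSON
#'
#' @param prior A `prior_library`.
#' @param path File path.
#' @export
write_prior_json <- function(prior, path) {
  jsonlite::write_json(
    list(tokens = prior$tokens, probs = prior$probs,
         event_tags = as.list(prior$event_tags)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prior_json
#' @export
read_prior_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tags <- obj$event_tags
  if (length(tags) == 0L) tags <- NULL else tags <- unlist(tags)
  prior_library(obj$tokens, obj$probs, tags)
}
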