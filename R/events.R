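#' Packaged narrative event set (synthetic reconstruction)
#'
#' The narrative-alignment measure projects hashtag responses onto the causal
#' events of a focal narrative. This packaged set covers the 2011 Fukushima
#' nuclear disaster as eight events along its causal chain — the narrative
#' topic, two generative causes (earthquake, tsunami), damage to the nuclear
#' plant, two first-order effects (radiation leak, population displacement)
#' and two second-order effects (lasting contamination, the Setsuden
#' energy-saving movement).
#'
#' The event texts are a *synthetic reconstruction* written for this package:
#' short single-sentence summaries with distinctive vocabulary per event, not
#' the original experimental stimulus text. They are adequate for testing the
#' alignment pipeline and for simulation work; analyses of real experimental
#' data should substitute the actual narrative segmentation via
#' [read_event_set()].
#'
#' @return A tibble with columns `label` (one of `topic`, `cause`,
#'   `plant_damage`, `first_order_effect`, `second_order_effect`), `name`
#'   (unique event name) and `text`.
#' @export
fukushima_events <- function() {
  ev <- tibble::tribble(
    ~label, ~name, ~text,
    "topic", "topic",
    "In March 2011 Japan suffered a severe nuclear disaster at the Fukushima Daiichi power station, an accident that reshaped national energy policy.",
    "cause", "earthquake",
    "A magnitude nine earthquake struck off the Tohoku coast, one of the strongest seismic events ever recorded in Japan.",
    "cause", "tsunami",
    "The earthquake triggered a towering tsunami whose waves overwhelmed the seawalls protecting the coastal plant.",
    "plant_damage", "reactor_damage",
    "Flooding disabled the backup generators, and the reactor cores overheated and melted down, destroying containment buildings.",
    "first_order_effect", "radiation_leak",
    "Radioactive material escaped from the damaged units, releasing caesium and iodine into the air and the ocean.",
    "first_order_effect", "displacement",
    "More than one hundred thousand residents were evacuated from the exclusion zone and displaced from their homes for years.",
    "second_order_effect", "contamination",
    "Lingering contamination of farmland, fisheries and drinking water raised long term public health concerns.",
    "second_order_effect", "setsuden",
    "A voluntary energy saving movement called Setsuden spread across the country as households cut electricity consumption."
  )
  validate_event_set(ev)
}

narrative_labels <- c("topic", "cause", "plant_damage",
                      "first_order_effect", "second_order_effect")

validate_event_set <- function(events) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("label", "name", "text") %in% names(events)))
  if (nrow(events) == 0L) stop("event set must be nonempty", call. = FALSE)
  if (anyDuplicated(events$name)) stop("event names must be unique", call. = FALSE)
  if (any(!nzchar(events$text))) stop("every event needs nonempty text", call. = FALSE)
  if (!all(events$label %in% narrative_labels)) {
    stop("labels must be one of: ", paste(narrative_labels, collapse = ", "),
         call. = FALSE)
  }
  events
}

#' Read / write a narrative event set as JSON
#'
#' On-disk form: `[{"label": "...", "name": "...", "text": "..."}, ...]`.
#'
#' @param events A tibble as returned by [fukushima_events()].
#' @param path File path.
#' @export
write_event_set <- function(events, path) {
  events <- validate_event_set(events)
  jsonlite::write_json(events, path, auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname write_event_set
#' @export
read_event_set <- function(path) {
  validate_event_set(jsonlite::read_json(path, simplifyVector = TRUE))
}
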