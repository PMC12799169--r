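events <- fukushima_events()
emb <- ngram_embedder()

test_that("cosine similarity matches hand arithmetic and rejects zero vectors", {
  expect_equal(cosine_similarity(c(1, 2), c(1, 2)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(2, 1)), 0.8)  # 4/5 by hand
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "length")
})

test_that("the fixture embedder is deterministic and canonicalizing", {
  expect_identical(emb("tsunami"), emb("tsunami"))
  expect_identical(emb("#Tsunami"), emb("tsunami"))
  expect_identical(emb("NuclearDisaster"), emb("nuclear disaster"))
  expect_gt(sum(emb("radiation")^2), 0)
  expect_error(emb("   "), "empty")
})

test_that("the worked softmax example evaluates as hand-calculated", {
  # two events with similarities 0.9 and 0.1 at tau = 1 -> (0.690, 0.310)
  two <- tibble::tibble(label = c("cause", "topic"), name = c("e1", "e2"),
                        text = c("x", "y"))
  # unit hashtag embedding whose cosines with the two unit event axes are
  # exactly 0.9 and 0.1 (third coordinate absorbs the rest of the norm)
  h <- c(0.9, 0.1, sqrt(1 - 0.9^2 - 0.1^2))
  av <- alignment_vector("anything", two, embedder = function(t) {
    if (t == "x") c(1, 0, 0) else if (t == "y") c(0, 1, 0) else h
  }, tau = 1)
  expect_equal(unname(av$similarities), c(0.9, 0.1), tolerance = 1e-12)
  expect_equal(unname(av$credences), c(0.690, 0.310), tolerance = 5e-4)
})

test_that("alignment vectors are simplices with argmax preserved", {
  tags <- c("#earthquake", "#RadiationLeak", "#setsuden", "#wave", "#energy")
  for (tau in c(0.05, 0.1, 1)) {
    for (h in tags) {
      av <- alignment_vector(h, events, emb, tau = tau)
      expect_equal(sum(av$credences), 1, tolerance = 1e-9)
      expect_true(all(av$credences >= 0))
      expect_true(all(av$similarities >= -1 & av$similarities <= 1))
      expect_equal(which.max(av$credences), which.max(av$similarities))
    }
  }
  expect_error(alignment_vector("#tsunami", events, emb, tau = 0), "tau")
  expect_error(alignment_vector("#", events, emb), "empty")
})

test_that("temperature limits give one-hot and uniform credences", {
  av_cold <- alignment_vector("#earthquake", events, emb, tau = 1e-6)
  hot_idx <- which.max(av_cold$similarities)
  expect_equal(unname(av_cold$credences[hot_idx]), 1, tolerance = 1e-9)

  av_hot <- alignment_vector("#earthquake", events, emb, tau = 1e3)
  expect_equal(unname(av_hot$credences), rep(1 / nrow(events), nrow(events)),
               tolerance = 1e-3)
})

test_that("raising one similarity raises its credence and lowers the rest", {
  s <- c(0.2, 0.5, -0.1)
  soft <- function(s, tau = 0.1) { z <- exp((s - max(s)) / tau); z / sum(z) }
  a0 <- soft(s)
  s2 <- s; s2[3] <- s2[3] + 0.3
  a1 <- soft(s2)
  expect_gt(a1[3], a0[3])
  expect_true(all(a1[-3] < a0[-3]))
})

test_that("verbatim event tokens align to their source event", {
  probes <- list(
    earthquake = "#MagnitudeNineEarthquake",
    tsunami = "#tsunami waves seawalls",
    reactor_damage = "#ReactorCoresMeltedDown",
    radiation_leak = "#RadioactiveCaesiumIodine",
    displacement = "#EvacuatedResidentsDisplaced",
    setsuden = "#SetsudenEnergySaving"
  )
  for (target in names(probes)) {
    av <- alignment_vector(probes[[target]], events, emb, tau = 0.1)
    expect_equal(names(which.max(av$credences)), target)
  }
})

test_that("mean alignment is a simplex and averages correctly", {
  one <- alignment_vector("#tsunami", events, emb, tau = 0.1)$credences
  expect_equal(mean_alignment("#tsunami", events, emb, tau = 0.1), one)

  m <- mean_alignment(c("#tsunami", "#setsuden", "#earthquake"), events, emb,
                      tau = 0.1)
  expect_equal(sum(m), 1, tolerance = 1e-9)
  direct <- (alignment_vector("#tsunami", events, emb, 0.1)$credences +
             alignment_vector("#setsuden", events, emb, 0.1)$credences +
             alignment_vector("#earthquake", events, emb, 0.1)$credences) / 3
  expect_equal(m, direct)
  expect_error(mean_alignment(character(0), events, emb), "no hashtags")
})

test_that("label aggregation is a brute-force group-by and order-invariant", {
  cred <- mean_alignment(c("#tsunami", "#radiation"), events, emb, tau = 0.1)
  agg <- aggregate_by_label(cred, events)
  expect_equal(sum(agg), 1, tolerance = 1e-9)
  brute <- sapply(unique(events$label), function(L) {
    sum(cred[events$name[events$label == L]])
  })
  expect_equal(agg[names(brute)], brute[names(brute)], tolerance = 1e-12)

  perm <- events[c(3, 1, 8, 5, 2, 7, 4, 6), ]
  expect_equal(aggregate_by_label(cred, perm)[names(agg)], agg)

  single <- tibble::tibble(label = "cause", name = "only", text = "z")
  expect_equal(unname(aggregate_by_label(c(only = 1), single)), 1)
})

test_that("the group comparison is the Welch test, verified by closed form", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- compare_groups(a, b)
  oracle <- welch_by_hand(a, b)
  expect_equal(got$t, oracle$t, tolerance = 1e-12)
  expect_equal(got$df, oracle$df, tolerance = 1e-12)
  expect_equal(got$p, oracle$p, tolerance = 1e-12)
  expect_equal(got$t, -3.674235, tolerance = 1e-6)
  expect_equal(got$df, 4)

  flipped <- compare_groups(b, a)
  expect_equal(flipped$t, -got$t)
  expect_equal(flipped$p, got$p)

  expect_error(compare_groups(c(1, 1), c(1, 1)), "constant")
  expect_error(compare_groups(1, c(1, 2)), "two observations")
})

test_that("event sets validate and round-trip through JSON", {
  expect_equal(nrow(events), 8L)
  expect_false(anyDuplicated(events$name) > 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_event_set(events, path)
  expect_equal(read_event_set(path), events)
  bad <- events; bad$label[1] <- "mystery"
  expect_error(write_event_set(bad, path), "labels")
})
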