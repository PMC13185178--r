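test_that("prompt templates enforce their contract", {
  t <- prompt_template()
  expect_s3_class(t, "prompt_template")
  expect_identical(t$temperature, 0)
  expect_error(prompt_template(task_specification = "  "),
               class = "pdsentinel_config_error")
  expect_error(prompt_template(temperature = 0.7),
               class = "pdsentinel_config_error")
})

test_that("the mock extractor labels by keyphrase and routes misses to review", {
  narr <- tibble::tibble(
    study_id = "A", site_id = "A-1", country = "US",
    narrative_id = c("n1", "n2", "n3"),
    narrative = c("Participant's consent form signed late by the coordinator.",
                  "The dose given outside the dosing window on day 3.",
                  "Completely unrelated gibberish text."))
  ex <- extract_topics(narr)
  expect_setequal(ex$assignments$topic,
                  c("informed consent timing", "dosing schedule deviation"))
  expect_equal(ex$manual_review$narrative_id, "n3")
  expect_true(nzchar(ex$manual_review$raw_response))
  # provenance: every labelled narrative appears in exactly one topic record
  expect_setequal(unlist(ex$topics$source_narrative_ids), c("n1", "n2"))
  expect_error(extract_topics(narr[0, ]), "no narratives")
})

test_that("the mock embedder is deterministic with uniform dimension", {
  emb <- embed_texts(c("sample stored cold", "sample stored cold",
                       "unrelated words entirely"))
  expect_equal(emb[1, ], emb[2, ])
  expect_equal(ncol(emb), 64L)
  sim_same <- cosine_similarity(emb[1, ], emb[2, ])
  sim_diff <- cosine_similarity(emb[1, ], emb[3, ])
  expect_equal(sim_same, 1)
  expect_lt(sim_diff, 1)
  expect_error(embed_texts(c("ok", "")), "index 2|empty text")
  bad_backend <- function(texts) matrix(1, nrow = length(texts) + 1, ncol = 2)
  expect_error(embed_texts("x", bad_backend), "one fixed-length vector")
})

test_that("cosine similarity matches closed forms", {
  expect_equal(cosine_similarity(c(2, 3, 4), c(2, 3, 4)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), sqrt(2) / 2)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(cosine_similarity(1:2, 1:3), "equal dimension")
})

make_topics <- function(labels, n_narr = 5L) {
  tibble::tibble(
    topic_id = sprintf("T%02d", seq_along(labels)), label = labels,
    study_id = "A", n_narratives = rep_len(n_narr, length(labels)),
    source_narrative_ids = lapply(seq_along(labels), function(i)
      sprintf("N%02d-%d", i, seq_len(rep_len(n_narr, length(labels))[i]))))
}

test_that("merging separates distinct groups and fuses identical ones", {
  # two groups of mutually identical embeddings -> 2 merged topics
  emb <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0))
  tx <- merge_topics(make_topics(c("aa", "ab", "ba", "bb")), emb)
  expect_equal(nrow(tx$topics), 2L)
  # all-identical embeddings -> a single topic and a single category
  emb1 <- matrix(rep(c(1, 2, 3), 4), nrow = 4, byrow = TRUE)
  tx1 <- merge_topics(make_topics(c("aa", "ab", "ba", "bb")), emb1,
                      t_topic = 0.1, t_category = 0.5)
  expect_equal(nrow(tx1$topics), 1L)
  expect_equal(nrow(tx1$categories), 1L)
  expect_error(merge_topics(make_topics(c("a", "b")), t_topic = 0.9,
                            t_category = 0.3),
               class = "pdsentinel_config_error")
})

test_that("planted clusters are recovered exactly", {
  withr::with_seed(71, {
    centroids <- diag(6)[, ] + 0.0
    emb <- do.call(rbind, lapply(1:6, function(k) {
      t(replicate(5, centroids[k, ] + rnorm(6, sd = 0.02)))
    }))
    labels <- sprintf("topic %s %d", rep(letters[1:6], each = 5), 1:30)
    tx <- merge_topics(make_topics(labels), emb,
                       t_topic = 0.3, t_category = 0.6)
    expect_equal(nrow(tx$topics), 6L)
    planted <- rep(1:6, each = 5)
    recovered <- tx$assignment$merged_topic[order(match(tx$assignment$topic_id,
                                                        make_topics(labels)$topic_id))]
    expect_equal(length(unique(paste(planted, recovered))), 6L)
  })
})

test_that("topic clusters nest inside categories and conserve provenance", {
  withr::with_seed(19, {
    emb <- matrix(rnorm(20 * 8), nrow = 20)
    topics <- make_topics(sprintf("lbl %02d", 1:20), n_narr = 3L)
    tx <- merge_topics(topics, emb, t_topic = 0.5, t_category = 1.0)
    # nesting: each merged topic's members map into exactly one category
    for (j in seq_len(nrow(tx$topics))) {
      members <- tx$topics$member_topic_ids[[j]]
      cats <- unique(tx$assignment$category[tx$assignment$topic_id %in% members])
      expect_length(cats, 1L)
      expect_equal(cats, tx$topics$category[j])
    }
    # provenance conservation: no narrative lost or duplicated
    expect_setequal(unlist(tx$topics$source_narrative_ids),
                    unlist(topics$source_narrative_ids))
    expect_equal(sort(unlist(tx$categories$source_narrative_ids)),
                 sort(unlist(topics$source_narrative_ids)))
  })
})

test_that("merging is invariant to input topic order", {
  withr::with_seed(23, {
    emb <- matrix(rnorm(12 * 6), nrow = 12)
    topics <- make_topics(sprintf("label %02d", 1:12))
    tx1 <- merge_topics(topics, emb, t_topic = 0.6, t_category = 1.1)
    perm <- sample(12)
    tx2 <- merge_topics(topics[perm, ], emb[perm, ], t_topic = 0.6,
                        t_category = 1.1)
    a1 <- tx1$assignment[order(tx1$assignment$topic_id), ]
    a2 <- tx2$assignment[order(tx2$assignment$topic_id), ]
    expect_equal(a1, a2)
    expect_equal(tx1$silhouette, tx2$silhouette)
  })
})

test_that("rare clusters are tagged, never dropped", {
  topics <- make_topics(c("big one", "big two", "tiny"), n_narr = 1L)
  topics$n_narratives <- c(300L, 300L, 2L)
  emb <- rbind(c(1, 0, 0), c(0.99, 0.1, 0), c(0, 0, 1))
  tx <- merge_topics(topics, emb, t_topic = 0.3, t_category = 0.6)
  tiny <- tx$topics[vapply(tx$topics$member_topic_ids,
                           function(m) "T03" %in% m, TRUE), ]
  expect_equal(nrow(tiny), 1L)
  expect_true(tiny$rare)
  expect_false(any(tx$topics$rare[tx$topics$n_narratives >= 300]))
})

test_that("silhouette matches closed forms and the brute-force oracle", {
  # perfectly separated, internally identical clusters score 1
  emb <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(silhouette_score(emb, c(1, 1, 2, 2)), 1)
  # symmetric 4-point configuration: every point scores 1/3
  emb2 <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  expect_equal(silhouette_score(emb2, c(1, 1, 2, 2)), 1 / 3,
               tolerance = 1e-12)
  expect_error(silhouette_score(emb2, rep(1, 4)), "single cluster")
  # random instances up to 50 points against the O(n^2) oracle
  withr::with_seed(99, {
    for (rep in 1:12) {
      n <- sample(5:50, 1)
      k <- sample(2:5, 1)
      emb <- matrix(rnorm(n * 6), nrow = n)
      assign <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
      expect_equal(silhouette_score(emb, assign),
                   naive_silhouette(emb, assign), tolerance = 1e-12)
    }
  })
})

test_that("random cluster assignments score near zero silhouette", {
  withr::with_seed(123, {
    scores <- replicate(8, {
      emb <- matrix(rnorm(200 * 5), nrow = 200)
      silhouette_score(emb, sample.int(3, 200, replace = TRUE))
    })
    expect_lt(abs(mean(scores)), 0.1)
  })
})

test_that("topic distributions are normalized within each group", {
  a <- tibble::tibble(
    study_id = "A", site_id = c("s1", "s1", "s1", "s2", "s2"),
    country = c("US", "US", "US", "DE", "DE"),
    topic = c("A", "A", "B", "C", "C"))
  d <- topic_distribution(a, "site")
  s1 <- d[d$site_id == "s1", ]
  expect_equal(s1$prop[s1$topic == "A"], 2 / 3)
  expect_equal(s1$prop[s1$topic == "B"], 1 / 3)
  # disjoint topics across sites stay disjoint
  expect_false("C" %in% s1$topic)
  sums <- tapply(d$prop, d$site_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})
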