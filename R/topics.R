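#' @section Topic pipeline:
#' Narratives are turned into study-level topics by a pluggable extraction
#' backend, embedded by a pluggable embedding backend, merged by
#' average-linkage agglomerative clustering on cosine distance into a
#' two-level taxonomy (specific topics nested inside broad categories),
#' labelled by cluster medoids, and scored with the silhouette. The
#' default backends are deterministic mocks so the whole pipeline runs
#' offline; live model adapters only need to satisfy the same contracts.
#' @name topic-pipeline
NULL

#' Load the packaged reference deviation taxonomy
#'
#' A small synthetic two-level vocabulary (5 categories, 15 topics, each
#' topic with characteristic keyphrases) used by the narrative generator
#' and the mock extraction backend.
#'
#' @return A tibble with columns `category`, `topic`, `keyphrases`
#'   (list column of character vectors).
#' @export
reference_taxonomy <- function() {
  path <- system.file("extdata", "reference_taxonomy.json",
                      package = "pdsentinel", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- list()
  for (cat in raw$categories) {
    for (tp in cat$topics) {
      rows[[length(rows) + 1L]] <- tibble(
        category = cat$category, topic = tp$topic,
        keyphrases = list(vapply(tp$keyphrases, identity, "")))
    }
  }
  bind_rows(rows)
}

#' Construct a prompt template for topic extraction backends
#'
#' The contract every extraction backend receives: a task specification, a
#' placeholder slot where the narrative batch is presented, and a
#' structured output format requirement. Sampling temperature is pinned to
#' zero; the template refuses any other value so runs stay reproducible.
#'
#' @param task_specification what the backend is asked to do.
#' @param context_slot placeholder marking where narratives are inserted.
#' @param output_format_spec the parseable response format demanded.
#' @param temperature must be 0.
#' @return A list of class `prompt_template`.
#' @export
prompt_template <- function(
    task_specification = paste(
      "You are given protocol deviation narratives from one clinical study.",
      "Assign each narrative a short deviation topic label."),
    context_slot = "{narratives}",
    output_format_spec = "One line per narrative: <index>\t<topic label>.",
    temperature = 0) {
  if (!nzchar(trimws(task_specification)) || !nzchar(trimws(context_slot)) ||
      !nzchar(trimws(output_format_spec))) {
    config_error("all prompt template sections must be non-empty")
  }
  if (!identical(as.numeric(temperature), 0)) {
    config_error("temperature must be 0 for reproducible extraction")
  }
  structure(list(task_specification = task_specification,
                 context_slot = context_slot,
                 output_format_spec = output_format_spec,
                 temperature = 0), class = "prompt_template")
}

normalize_text <- function(x) {
  x <- tolower(x)
  gsub("\\s+", " ", trimws(x))
}

#' Deterministic keyword-rule extraction backend
#'
#' The default, fully offline stand-in for a generative extraction model:
#' it labels a narrative with the topic whose keyphrase occurs in the
#' (casefolded, whitespace-collapsed) text. Keyphrases are tried longest
#' first so more specific phrases win. A narrative matching no keyphrase
#' yields a malformed (non-)response, which the caller routes to the
#' manual-review list.
#'
#' @param taxonomy a keyphrase taxonomy as returned by
#'   [reference_taxonomy()].
#' @return A function `(narratives, template)` returning a tibble
#'   `index`, `topic`, `category`, `ok`, `raw`.
#' @export
mock_extractor <- function(taxonomy = reference_taxonomy()) {
  rules <- tibble(
    keyphrase = unlist(taxonomy$keyphrases),
    topic = rep(taxonomy$topic, lengths(taxonomy$keyphrases)),
    category = rep(taxonomy$category, lengths(taxonomy$keyphrases))
  )
  rules <- rules[order(-nchar(rules$keyphrase), rules$keyphrase), ]
  function(narratives, template = prompt_template()) {
    stopifnot(inherits(template, "prompt_template"))
    txt <- normalize_text(narratives)
    out <- tibble(index = seq_along(narratives), topic = NA_character_,
                  category = NA_character_, ok = FALSE, raw = txt)
    for (i in seq_len(nrow(rules))) {
      hit <- !out$ok & grepl(rules$keyphrase[i], txt, fixed = TRUE)
      if (any(hit)) {
        out$topic[hit] <- rules$topic[i]
        out$category[hit] <- rules$category[i]
        out$ok[hit] <- TRUE
      }
    }
    out
  }
}

#' Extract study-level topics from deviation narratives
#'
#' Runs the extraction backend over the narratives of each study and
#' aggregates its per-narrative labels into topic records with full
#' provenance (every topic keeps the ids of the narratives that produced
#' it). Narratives the backend cannot label are not dropped: they go to a
#' manual-review list with the raw response retained.
#'
#' @param narratives tibble with at least `study_id`, `narrative_id`,
#'   `narrative` (e.g. [portfolio_narratives()]).
#' @param extractor an extraction backend; default [mock_extractor()].
#' @param template a [prompt_template()].
#' @return A list: `topics` (tibble `topic_id`, `label`, `category_hint`,
#'   `study_id`, `n_narratives`, `source_narrative_ids` list column),
#'   `assignments` (tibble `narrative_id`, `study_id`, `site_id`,
#'   `country`, `topic`), and `manual_review` (unlabelled narratives with
#'   raw responses).
#' @export
extract_topics <- function(narratives, extractor = mock_extractor(),
                           template = prompt_template()) {
  narratives <- as_tibble(narratives)
  if (nrow(narratives) == 0L) abort("no narratives to extract topics from")
  res <- extractor(narratives$narrative, template)
  stopifnot(nrow(res) == nrow(narratives))
  ok <- res$ok & !is.na(res$topic) & nzchar(res$topic %||% "")
  manual <- narratives[!ok, , drop = FALSE]
  manual$raw_response <- res$raw[!ok]

  lab <- narratives[ok, , drop = FALSE]
  lab$topic <- res$topic[ok]
  lab$category_hint <- res$category[ok]
  topics <- lab %>%
    group_by(.data$study_id, .data$topic) %>%
    summarise(category_hint = .data$category_hint[1],
              n_narratives = n(),
              source_narrative_ids = list(.data$narrative_id),
              .groups = "drop") %>%
    mutate(topic_id = paste(.data$study_id, .data$topic, sep = "::")) %>%
    rename(label = "topic") %>%
    select("topic_id", "label", "category_hint", "study_id",
           "n_narratives", "source_narrative_ids")

  keep <- intersect(c("narrative_id", "study_id", "site_id", "country"),
                    names(lab))
  assignments <- lab[, c(keep, "topic")]
  list(topics = topics, assignments = assignments, manual_review = manual)
}

token_hash <- function(token, mult) {
  h <- 0
  for (ch in utf8ToInt(token)) h <- (h * mult + ch) %% 1048573
  h
}

#' Deterministic hashed bag-of-tokens embedding backend
#'
#' Offline stand-in for a semantic embedding model: tokens are hashed into
#' a fixed number of signed buckets (the classic feature-hashing trick),
#' so identical texts always embed identically and texts sharing
#' vocabulary land near each other in cosine similarity. No semantics
#' beyond token overlap are captured, which is all the test loop needs.
#'
#' @param dim embedding dimension (default 64).
#' @return A function mapping a character vector to an `n x dim` matrix.
#' @export
mock_embedder <- function(dim = 64L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2L)
  cache <- new.env(parent = emptyenv())
  function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      toks <- strsplit(gsub("[^a-z0-9 ]", " ", normalize_text(texts[i])),
                       " ", fixed = TRUE)[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) == 0L) {
        abort(sprintf("text %d contains no tokens to embed", i))
      }
      for (tok in toks) {
        key <- tok
        hv <- cache[[key]]
        if (is.null(hv)) {
          hv <- c(token_hash(tok, 31) %% dim,
                  if (token_hash(tok, 131) %% 2 == 0) 1 else -1)
          cache[[key]] <- hv
        }
        out[i, hv[1] + 1L] <- out[i, hv[1] + 1L] + hv[2]
      }
    }
    out
  }
}

#' Embed a batch of texts
#'
#' @param texts character vector of non-empty strings.
#' @param embedder embedding backend; default [mock_embedder()].
#' @return A numeric matrix, one row per text, uniform dimension, all
#'   values finite.
#' @export
embed_texts <- function(texts, embedder = mock_embedder()) {
  empty <- which(!nzchar(trimws(texts)))
  if (length(empty)) {
    abort(sprintf("empty text at index %s cannot be embedded",
                  paste(empty, collapse = ", ")))
  }
  emb <- embedder(texts)
  if (!is.matrix(emb) || nrow(emb) != length(texts)) {
    abort("embedding backend must return one fixed-length vector per text")
  }
  if (any(!is.finite(emb))) abort("embeddings must be finite")
  rownames(emb) <- names(texts) %||% NULL
  emb
}

#' Cosine similarity of two vectors
#'
#' @param a,b numeric vectors of equal length and non-zero norm.
#' @return `dot(a, b) / (|a| * |b|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal dimension")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity undefined for zero-norm vectors")
  sum(a * b) / (na * nb)
}

# pairwise cosine distances 1 - sim, clamped into [0, 2]
cosine_dist_matrix <- function(emb) {
  norms <- sqrt(rowSums(emb^2))
  if (any(norms == 0)) abort("zero-norm embedding encountered")
  x <- emb / norms
  d <- 1 - tcrossprod(x)
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

#' Merge topics into a two-level taxonomy
#'
#' Average-linkage (or complete-linkage) agglomerative clustering on
#' cosine distance between topic-label embeddings. One dendrogram is cut
#' at two heights: the lower cut (`t_topic`) yields the specific merged
#' topics, the higher cut (`t_category`) the broad categories, so topics
#' nest inside categories by construction. Alternatively target counts
#' `n_topics` / `n_categories` may be given instead of heights. Each
#' cluster is labelled by its medoid (the member with the highest mean
#' similarity to its cluster peers; ties broken by lexicographically
#' smallest label). Clusters holding less than 1% of source narratives
#' are tagged rare but never dropped.
#'
#' Inputs are sorted lexicographically by label before clustering so the
#' result is invariant to input order.
#'
#' @param topics topic tibble as produced by [extract_topics()] (needs
#'   `topic_id`, `label`, `n_narratives`, `source_narrative_ids`).
#' @param embeddings matrix of label embeddings, rows aligned with
#'   `topics`; if `NULL`, labels are embedded with [mock_embedder()].
#' @param t_topic,t_category dendrogram cut heights on the cosine
#'   distance scale, `0 < t_topic <= t_category < 2`.
#' @param linkage `"average"` or `"complete"`.
#' @param n_topics,n_categories optional target cluster counts overriding
#'   the cut heights (`n_categories <= n_topics`).
#' @return An object of class `pd_taxonomy`: a list with tibbles `topics`
#'   (merged level-2 clusters) and `categories` (level-1 clusters), an
#'   `assignment` tibble mapping every input topic to its clusters, and
#'   the topic-level `silhouette` score (NA when fewer than 2 clusters).
#' @export
merge_topics <- function(topics, embeddings = NULL,
                         t_topic = 0.3, t_category = 0.6,
                         linkage = c("average", "complete"),
                         n_topics = NULL, n_categories = NULL) {
  linkage <- match.arg(linkage)
  topics <- as_tibble(topics)
  if (nrow(topics) < 2L) abort("need at least 2 topics to merge")
  if (is.null(n_topics) != is.null(n_categories) && !is.null(n_categories)) {
    config_error("give both n_topics and n_categories or neither")
  }
  use_counts <- !is.null(n_topics)
  if (use_counts) {
    if (is.null(n_categories)) config_error("give both n_topics and n_categories or neither")
    if (n_categories > n_topics) config_error("thresholds out of order: n_categories must be <= n_topics")
  } else {
    if (!(t_topic > 0 && t_category < 2 && t_topic <= t_category)) {
      config_error("thresholds out of order: need 0 < t_topic <= t_category < 2")
    }
  }

  ord <- order(topics$label, topics$topic_id)
  topics <- topics[ord, , drop = FALSE]
  if (is.null(embeddings)) {
    embeddings <- embed_texts(topics$label)
  } else {
    stopifnot(nrow(embeddings) == length(ord))
    embeddings <- embeddings[ord, , drop = FALSE]
  }
  d <- cosine_dist_matrix(embeddings)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  if (use_counts) {
    k_t <- min(n_topics, nrow(topics))
    k_c <- min(n_categories, nrow(topics))
    cut_t <- stats::cutree(hc, k = k_t)
    cut_c <- stats::cutree(hc, k = k_c)
  } else {
    cut_t <- stats::cutree(hc, h = t_topic)
    cut_c <- stats::cutree(hc, h = t_category)
  }

  sim <- 1 - d
  total_narr <- sum(topics$n_narratives)
  level <- function(cut) {
    ids <- sort(unique(cut))
    labels <- character(length(ids))
    rows <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      members <- which(cut == ids[j])
      if (length(members) == 1L) {
        med <- members
      } else {
        msim <- (rowSums(sim[members, members, drop = FALSE]) - 1) /
          (length(members) - 1)
        best <- members[msim == max(msim)]
        med <- best[order(topics$label[best])][1]
      }
      labels[j] <- topics$label[med]
      nn <- sum(topics$n_narratives[members])
      rows[[j]] <- tibble(
        cluster = ids[j], label = labels[j], n_members = length(members),
        n_narratives = nn,
        rare = nn < 0.01 * total_narr,
        member_topic_ids = list(topics$topic_id[members]),
        source_narrative_ids = list(unlist(topics$source_narrative_ids[members],
                                           use.names = FALSE)))
    }
    out <- bind_rows(rows)
    out$label <- make.unique(out$label, sep = " / ")
    out
  }
  lvl_topics <- level(cut_t)
  lvl_cats <- level(cut_c)

  # nesting: each topic cluster sits inside exactly one category cluster
  topic_to_cat <- vapply(seq_len(nrow(lvl_topics)), function(j) {
    member <- match(lvl_topics$member_topic_ids[[j]][1], topics$topic_id)
    cat_cluster <- cut_c[member]
    lvl_cats$label[match(cat_cluster, lvl_cats$cluster)]
  }, "")
  lvl_topics$category <- topic_to_cat

  sil <- if (length(unique(cut_t)) >= 2L)
    silhouette_score(embeddings, cut_t) else NA_real_

  assignment <- tibble(
    topic_id = topics$topic_id, label = topics$label,
    merged_topic = lvl_topics$label[match(cut_t, lvl_topics$cluster)],
    category = lvl_cats$label[match(cut_c, lvl_cats$cluster)])

  structure(list(topics = lvl_topics, categories = lvl_cats,
                 assignment = assignment, silhouette = sil,
                 linkage = linkage),
            class = "pd_taxonomy")
}

#' @export
print.pd_taxonomy <- function(x, ...) {
  cat(sprintf("<pd_taxonomy> %d categories, %d topics (silhouette %.3f)\n",
              nrow(x$categories), nrow(x$topics),
              if (is.na(x$silhouette)) NA else x$silhouette))
  invisible(x)
}

#' Silhouette score of a clustering under cosine distance
#'
#' Mean over points of `(b - a) / max(a, b)` where `a` is the mean
#' distance to the point's own cluster peers and `b` the smallest mean
#' distance to any other cluster. A point alone in its cluster scores 0
#' by convention.
#'
#' @param embeddings numeric matrix, one row per point.
#' @param assignments cluster labels, one per point; at least 2 distinct
#'   clusters.
#' @return The mean silhouette, in `[-1, 1]`.
#' @export
silhouette_score <- function(embeddings, assignments) {
  n <- nrow(embeddings)
  stopifnot(length(assignments) == n)
  f <- factor(assignments)
  k <- nlevels(f)
  if (k < 2L) abort("silhouette undefined for a single cluster")
  d <- cosine_dist_matrix(embeddings)
  ind <- outer(f, levels(f), `==`) * 1
  cnt <- colSums(ind)
  sums <- d %*% ind                       # n x k total distance to each cluster
  own <- as.integer(f)
  a <- sums[cbind(seq_len(n), own)] / pmax(cnt[own] - 1, 1)
  mean_other <- sweep(sums, 2, cnt, "/")
  mean_other[cbind(seq_len(n), own)] <- Inf
  b <- apply(mean_other, 1, min)
  s <- (b - a) / pmax(a, b)
  s[!is.finite(s)] <- 0                    # identical points in both clusters
  s[cnt[own] == 1] <- 0                    # singleton convention
  mean(s)
}

#' Topic frequency distribution by site, country or study
#'
#' @param assignments tibble with a `topic` column plus the grouping
#'   columns (`study_id`, and `site_id` / `country` as needed).
#' @param group_by `"site"`, `"country"` or `"study"`.
#' @return A tibble of per-group topic counts and proportions; each
#'   group's proportions sum to 1. Groups with no narratives simply do
#'   not appear.
#' @export
topic_distribution <- function(assignments,
                               group_by = c("site", "country", "study")) {
  group_by <- match.arg(group_by)
  keys <- switch(group_by,
                 site = c("study_id", "site_id"),
                 country = c("study_id", "country"),
                 study = "study_id")
  assignments <- as_tibble(assignments)
  stopifnot(all(c(keys, "topic") %in% names(assignments)))
  out <- assignments %>%
    count(dplyr::across(dplyr::all_of(c(keys, "topic"))), name = "n") %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup()
  out
}
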