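#' Classify the scope of each deviation topic within a study
#'
#' The operational question: is a deviation pattern site-specific,
#' country-specific or study-systemic? The decision rule here is the
#' package's own construction (no published rule exists): for every topic
#' a two-level cascade of heterogeneity tests on the topic-versus-other
#' count table, Benjamini-Hochberg adjusted across topics.
#'
#' 1. *Across sites within country*: chi-square test of the topic's
#'    share across sites (Fisher's exact test whenever an expected cell
#'    is below 5), per country with at least two sites, combined over
#'    countries by Fisher's method. Significant after adjustment:
#'    `site_specific` — tested first because a spike at one site also
#'    inflates its country's aggregate and must be attributed to the
#'    site, not the country.
#' 2. *Across countries*: the same test of the topic's share across
#'    countries. Significant after adjustment (sites within countries
#'    homogeneous): `country_specific`.
#' 3. Otherwise, a topic that is homogeneous everywhere but elevated
#'    study-wide — proportion at least `systemic_margin` times the
#'    uniform reference share with at least `min_count` narratives — is
#'    `study_systemic`; anything else is `indeterminate`.
#'
#' Results are signals that warrant investigation, not compliance
#' determinations.
#'
#' @param assignments tibble with `study_id`, `site_id`, `country`,
#'   `topic` (one row per narrative).
#' @param alpha significance level after BH adjustment (default 0.05).
#' @param systemic_margin study-wide elevation factor over the uniform
#'   reference share (default 2).
#' @param min_count minimum narrative count for a systemic call
#'   (default 5).
#' @return A tibble: `study_id`, `topic`, `n`, `p_country`,
#'   `p_country_adj`, `p_site`, `p_site_adj`, `scope`.
#' @export
scope_classification <- function(assignments, alpha = 0.05,
                                 systemic_margin = 2, min_count = 5L) {
  assignments <- as_tibble(assignments)
  stopifnot(all(c("study_id", "site_id", "country", "topic") %in%
                  names(assignments)))
  out <- list()
  for (sid in sort(unique(assignments$study_id))) {
    a <- assignments[assignments$study_id == sid, , drop = FALSE]
    topics <- sort(unique(a$topic))
    n_ref <- max(length(topics), 1L)
    single_site <- length(unique(a$site_id)) < 2L
    p_country <- p_site <- rep(NA_real_, length(topics))
    n_topic <- integer(length(topics))
    for (j in seq_along(topics)) {
      is_t <- a$topic == topics[j]
      n_topic[j] <- sum(is_t)
      if (single_site || n_topic[j] == 0L) next
      p_country[j] <- heterogeneity_p(is_t, a$country)
      p_site[j] <- stratified_site_p(is_t, a$site_id, a$country)
    }
    adj_c <- bh_or_na(p_country)
    adj_s <- bh_or_na(p_site)
    scope <- rep("indeterminate", length(topics))
    for (j in seq_along(topics)) {
      if (single_site || n_topic[j] == 0L) next
      if (!is.na(adj_s[j]) && adj_s[j] <= alpha) {
        scope[j] <- "site_specific"
      } else if (!is.na(adj_c[j]) && adj_c[j] <= alpha) {
        scope[j] <- "country_specific"
      } else if (n_topic[j] >= min_count &&
                 n_topic[j] / nrow(a) >= systemic_margin / n_ref) {
        scope[j] <- "study_systemic"
      }
    }
    out[[sid]] <- tibble(study_id = sid, topic = topics, n = n_topic,
                         p_country = p_country, p_country_adj = adj_c,
                         p_site = p_site, p_site_adj = adj_s, scope = scope)
  }
  bind_rows(out)
}

bh_or_na <- function(p) {
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) adj[ok] <- p.adjust(p[ok], method = "BH")
  adj
}

# 2 x G test of a binary indicator across groups; exact when sparse
heterogeneity_p <- function(indicator, group) {
  tab <- table(factor(indicator, levels = c(TRUE, FALSE)), group)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) return(NA_real_)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- tryCatch(fisher.test(tab, simulate.p.value = FALSE,
                              workspace = 2e6)$p.value,
                  error = function(e)
                    fisher.test(tab, simulate.p.value = TRUE, B = 2000)$p.value)
  } else {
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  min(max(p, .Machine$double.xmin), 1)
}

# combine per-country site-heterogeneity tests with Fisher's method
stratified_site_p <- function(indicator, site, country) {
  ps <- c()
  for (ct in unique(country)) {
    sel <- country == ct
    if (length(unique(site[sel])) < 2L) next
    p <- heterogeneity_p(indicator[sel], site[sel])
    if (!is.na(p)) ps <- c(ps, p)
  }
  if (length(ps) == 0L) return(NA_real_)
  if (length(ps) == 1L) return(ps)
  stat <- -2 * sum(log(ps))
  pchisq(stat, df = 2 * length(ps), lower.tail = FALSE)
}

#' Build per-site risk profiles
#'
#' Joins the statistical flags from [detect_outliers()] with per-site
#' topic distributions and the per-topic scope labels into one profile
#' per site. Dominant topics are those over-represented at the site
#' relative to the study (site proportion at least `dominance_margin`
#' times the study proportion, with at least `min_narratives` site
#' narratives for that topic). Flagged sites sort first, by their
#' smallest adjusted tail probability. Sites appearing on only one side
#' of the join get empty components and are logged in the `mismatches`
#' attribute.
#'
#' @param site_results output of [detect_outliers()].
#' @param assignments narrative-level topic assignments (from
#'   [extract_topics()]), carrying `study_id`, `site_id`, `topic`.
#' @param scopes optional output of [scope_classification()]; computed
#'   from `assignments` when omitted (requires a `country` column).
#' @param dominance_margin multiple of the study share above which a
#'   topic is dominant at a site (default 2).
#' @param min_narratives minimum site narrative count for dominance
#'   (default 5).
#' @return A tibble of class `risk_profiles`, one row per site, with
#'   list columns `topic_table` (site vs study shares per topic, scope
#'   labels attached) and `dominant_topics`.
#' @export
build_profiles <- function(site_results, assignments, scopes = NULL,
                           dominance_margin = 2, min_narratives = 5L) {
  site_results <- as_tibble(site_results)
  assignments <- as_tibble(assignments)
  st_r <- unique(site_results$study_id)
  st_a <- unique(assignments$study_id)
  if (length(intersect(st_r, st_a)) == 0L && nrow(assignments) > 0L) {
    abort("study ids in site results and topic assignments do not overlap")
  }
  if (is.null(scopes)) {
    scopes <- if ("country" %in% names(assignments) && nrow(assignments) > 0L)
      scope_classification(assignments)
    else tibble(study_id = character(), topic = character(),
                scope = character())
  }
  site_dist <- if (nrow(assignments)) topic_distribution(assignments, "site")
  else tibble(study_id = character(), site_id = character(),
              topic = character(), n = integer(), prop = numeric())
  study_dist <- if (nrow(assignments)) topic_distribution(assignments, "study")
  else tibble(study_id = character(), topic = character(),
              n = integer(), prop = numeric())

  rows <- vector("list", nrow(site_results))
  for (i in seq_len(nrow(site_results))) {
    sid <- site_results$study_id[i]
    site <- site_results$site_id[i]
    tab <- site_dist[site_dist$study_id == sid & site_dist$site_id == site,
                     c("topic", "n", "prop"), drop = FALSE]
    names(tab) <- c("topic", "n", "site_prop")
    sd_ <- study_dist[study_dist$study_id == sid, c("topic", "prop")]
    names(sd_) <- c("topic", "study_prop")
    tab <- left_join(tab, sd_, by = "topic")
    sc <- scopes[scopes$study_id == sid, c("topic", "scope")]
    tab <- left_join(tab, sc, by = "topic")
    dominant <- tab$topic[tab$n >= min_narratives &
                            tab$site_prop >= dominance_margin * tab$study_prop]
    rows[[i]] <- tibble(
      study_id = sid, site_id = site,
      flag = site_results$flag[i],
      p_low_adj = site_results$p_low_adj[i],
      p_high_adj = site_results$p_high_adj[i],
      n_narratives = sum(tab$n),
      dominant_topics = list(dominant),
      scope_summary = list(setNames(tab$scope, tab$topic)),
      topic_table = list(tab))
  }
  out <- bind_rows(rows)
  flagged <- out$flag %in% c("under_reporter", "high_rate")
  min_p <- pmin(out$p_low_adj, out$p_high_adj, na.rm = FALSE)
  min_p[is.na(min_p)] <- Inf
  out <- out[order(!flagged, min_p, out$study_id, out$site_id), , drop = FALSE]

  only_topics <- dplyr::anti_join(
    distinct(site_dist, .data$study_id, .data$site_id),
    distinct(site_results, .data$study_id, .data$site_id),
    by = c("study_id", "site_id"))
  attr(out, "mismatches") <- only_topics
  class(out) <- c("risk_profiles", class(out))
  out
}
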