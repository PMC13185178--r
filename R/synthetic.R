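#' Configuration for the synthetic portfolio generator
#'
#' The generator emulates the structure the detector's null assumes:
#' participants exchangeable across sites conditional on visit count,
#' violated only at injected under-/over-reporting sites. Deviation
#' counts are Poisson (optionally negative-binomial, since real PD
#' counts are over-dispersed) with mean
#' `n_visits * base_pd_rate * site_effect * class_multiplier`.
#'
#' @param n_studies number of studies.
#' @param sites_per_study sites per study (default 20).
#' @param participants_per_site length-2 range; per-site participant
#'   counts are drawn uniformly from it (default `c(10, 10)`).
#' @param visits_per_participant length-2 discrete range of visit counts
#'   (default `c(4, 10)`).
#' @param base_pd_rate expected deviations per visit at a null site
#'   (default 0.5).
#' @param site_effect_sd standard deviation (log scale) of benign
#'   lognormal site heterogeneity; 0 gives exact exchangeability
#'   (default 0).
#' @param under_rate_multiplier rate multiplier at injected
#'   under-reporting sites (default 0.25).
#' @param over_rate_multiplier rate multiplier at injected high-rate
#'   sites (default 3).
#' @param prop_under,prop_over fraction of sites injected per class
#'   (defaults 0); counts are rounded down per study.
#' @param dispersion `NULL` for Poisson counts, otherwise the
#'   negative-binomial size parameter.
#' @param countries country codes cycled over sites (default four).
#' @param topic_mixture optional named list, country code to a weight
#'   vector over the reference taxonomy's categories; default uniform.
#' @param generate_narratives set `FALSE` to skip narrative text (faster
#'   when only counts are needed).
#' @param seed root seed; the generator is fully reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_studies = 1L, sites_per_study = 20L,
                             participants_per_site = c(10L, 10L),
                             visits_per_participant = c(4L, 10L),
                             base_pd_rate = 0.5, site_effect_sd = 0,
                             under_rate_multiplier = 0.25,
                             over_rate_multiplier = 3,
                             prop_under = 0, prop_over = 0,
                             dispersion = NULL,
                             countries = c("US", "DE", "JP", "BR"),
                             topic_mixture = NULL,
                             generate_narratives = TRUE,
                             seed = 1L) {
  if (base_pd_rate <= 0) config_error("base_pd_rate must be positive")
  if (under_rate_multiplier <= 0 || over_rate_multiplier <= 0) {
    config_error("rate multipliers must be positive")
  }
  if (!(under_rate_multiplier < 1 && over_rate_multiplier > 1)) {
    config_error("need under_rate_multiplier < 1 < over_rate_multiplier")
  }
  if (prop_under < 0 || prop_over < 0 || prop_under + prop_over >= 1) {
    config_error("need prop_under + prop_over < 1, both non-negative")
  }
  if (length(participants_per_site) != 2L ||
      participants_per_site[1] > participants_per_site[2] ||
      participants_per_site[1] < 1L) {
    config_error("participants_per_site must be a valid range with minimum >= 1")
  }
  if (length(visits_per_participant) != 2L ||
      visits_per_participant[1] > visits_per_participant[2] ||
      visits_per_participant[1] < 1L) {
    config_error("visits_per_participant must be a valid range with minimum >= 1")
  }
  if (site_effect_sd < 0) config_error("site_effect_sd must be >= 0")
  taxonomy <- reference_taxonomy()
  cats <- unique(taxonomy$category)
  if (is.null(topic_mixture)) {
    topic_mixture <- setNames(
      rep(list(setNames(rep(1 / length(cats), length(cats)), cats)),
          length(countries)), countries)
  } else {
    stopifnot(all(countries %in% names(topic_mixture)))
    for (ct in countries) {
      w <- topic_mixture[[ct]]
      if (abs(sum(w) - 1) > 1e-8 || any(w < 0)) {
        config_error(sprintf("topic mixture for %s must be non-negative weights summing to 1", ct))
      }
      stopifnot(all(names(w) %in% cats))
    }
  }
  structure(list(
    n_studies = as.integer(n_studies),
    sites_per_study = as.integer(sites_per_study),
    participants_per_site = as.integer(participants_per_site),
    visits_per_participant = as.integer(visits_per_participant),
    base_pd_rate = base_pd_rate, site_effect_sd = site_effect_sd,
    under_rate_multiplier = under_rate_multiplier,
    over_rate_multiplier = over_rate_multiplier,
    prop_under = prop_under, prop_over = prop_over,
    dispersion = dispersion, countries = countries,
    topic_mixture = topic_mixture,
    generate_narratives = isTRUE(generate_narratives),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Render a deviation narrative from a topic template
#'
#' Produces a short English sentence embedding one of the topic's
#' characteristic keyphrases, so the deterministic mock extractor always
#' recovers the true topic (this closes the end-to-end test loop). Uses
#' the current RNG state to vary the sentence frame.
#'
#' @param category,topic a category/topic pair present in `taxonomy`.
#' @param taxonomy keyphrase taxonomy (default [reference_taxonomy()]).
#' @return A single narrative string.
#' @export
narrative_from_template <- function(category, topic,
                                    taxonomy = reference_taxonomy()) {
  row <- which(taxonomy$category == category & taxonomy$topic == topic)
  if (length(row) != 1L) {
    abort(sprintf("unknown topic '%s' in category '%s'", topic, category))
  }
  phrases <- taxonomy$keyphrases[[row]]
  phrase <- phrases[sample.int(length(phrases), 1L)]
  frames <- c(
    "During monitoring it was noted that the %s.",
    "Site staff reported that the %s for this participant.",
    "Review of the records showed that the %s; a deviation was filed.")
  sprintf(frames[sample.int(length(frames), 1L)], phrase)
}

#' Generate a synthetic multi-study portfolio with ground truth
#'
#' @param config a [synthetic_config()].
#' @return A list: `portfolio` (a `pd_portfolio`) and `truth`, itself a
#'   list of `sites` (tibble `study_id`, `site_id`, `true_class` in
#'   `{null, under, over}`) and `narratives` (tibble `narrative_id`,
#'   `true_category`, `true_topic`).
#' @export
generate_portfolio <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  taxonomy <- reference_taxonomy()
  topics_by_cat <- split(taxonomy$topic, taxonomy$category)
  parts <- list(); narrs <- list(); truth_sites <- list(); truth_narr <- list()
  narr_counter <- 0L

  for (s in seq_len(config$n_studies)) {
    study_id <- sprintf("S%04d", s)
    withr::with_seed(hash_seed(study_id, config$seed), {
      S <- config$sites_per_study
      site_ids <- sprintf("%s-ST%03d", study_id, seq_len(S))
      country <- rep_len(config$countries, S)
      n_under <- floor(config$prop_under * S)
      n_over <- floor(config$prop_over * S)
      cls <- rep("null", S)
      pick <- sample.int(S, n_under + n_over)
      if (n_under > 0) cls[pick[seq_len(n_under)]] <- "under"
      if (n_over > 0) cls[pick[n_under + seq_len(n_over)]] <- "over"
      effect <- if (config$site_effect_sd > 0) {
        rlnorm(S, meanlog = -config$site_effect_sd^2 / 2,
               sdlog = config$site_effect_sd)
      } else rep(1, S)
      mult <- c(null = 1, under = config$under_rate_multiplier,
                over = config$over_rate_multiplier)[cls]

      n_per_site <- if (config$participants_per_site[1] ==
                        config$participants_per_site[2]) {
        rep(config$participants_per_site[1], S)
      } else {
        sample(config$participants_per_site[1]:config$participants_per_site[2],
               S, replace = TRUE)
      }
      site_rep <- rep(seq_len(S), n_per_site)
      n_part <- length(site_rep)
      visits <- sample(config$visits_per_participant[1]:config$visits_per_participant[2],
                       n_part, replace = TRUE)
      mu <- visits * config$base_pd_rate * effect[site_rep] * mult[site_rep]
      pds <- if (is.null(config$dispersion)) rpois(n_part, mu)
             else rnbinom(n_part, size = config$dispersion, mu = mu)
      p <- tibble(
        study_id = study_id, site_id = site_ids[site_rep],
        country = country[site_rep],
        participant_id = sprintf("%s-P%05d", study_id, seq_len(n_part)),
        n_visits = as.integer(visits), n_pds = as.integer(pds))
      parts[[study_id]] <- p
      truth_sites[[study_id]] <- tibble(study_id = study_id,
                                        site_id = site_ids, true_class = cls)

      if (config$generate_narratives && sum(pds) > 0) {
        idx <- rep(seq_len(n_part), pds)
        n_n <- length(idx)
        ctry <- country[site_rep[idx]]
        narr_cat <- character(n_n); narr_top <- character(n_n)
        text <- character(n_n)
        for (k in seq_len(n_n)) {
          w <- config$topic_mixture[[ctry[k]]]
          cat_k <- sample(names(w), 1L, prob = w)
          top_k <- sample(topics_by_cat[[cat_k]], 1L)
          narr_cat[k] <- cat_k; narr_top[k] <- top_k
          text[k] <- narrative_from_template(cat_k, top_k, taxonomy)
        }
        ids <- sprintf("NR%08d", narr_counter + seq_len(n_n))
        narr_counter <- narr_counter + n_n
        narrs[[study_id]] <- tibble(
          study_id = study_id, site_id = p$site_id[idx],
          country = p$country[idx], participant_id = p$participant_id[idx],
          narrative_id = ids, narrative = text,
          topic_label = NA_character_, category_label = NA_character_)
        truth_narr[[study_id]] <- tibble(
          narrative_id = ids, true_category = narr_cat, true_topic = narr_top)
      }
    })
  }

  portfolio <- as_portfolio(bind_rows(parts),
                            if (length(narrs)) bind_rows(narrs) else NULL)
  list(portfolio = portfolio,
       truth = list(sites = bind_rows(truth_sites),
                    narratives = if (length(truth_narr)) bind_rows(truth_narr)
                    else tibble(narrative_id = character(),
                                true_category = character(),
                                true_topic = character())))
}
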