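#' Configuration for the visit-matched bootstrap outlier detector
#'
#' @param n_iterations number of bootstrap iterations `B` (default 1000).
#' @param alpha false discovery rate level for flagging (default 0.05).
#' @param seed root seed; each study derives its own stream via
#'   [hash_seed()], so results for one study never depend on which other
#'   studies are present.
#' @param min_sites_per_study studies with fewer sites are excluded whole
#'   (default 4, i.e. studies with three or fewer sites are set aside for
#'   manual review).
#' @param min_subjects_per_site sites with fewer participants are excluded
#'   from the bootstrap and the multiplicity family but still listed with
#'   flag `insufficient_data` (default 2).
#' @param convergence_start first iteration of the trailing window over
#'   which the convergence coefficient of variation is computed
#'   (default: iteration 800, or `n_iterations` when the run is shorter).
#' @param cv_threshold convergence CV threshold (default 0.01, i.e. 1%).
#' @param pseudo_count logical; when `TRUE` (default) empirical tail
#'   probabilities use the add-one correction `(c + 1) / (B + 1)` so they
#'   are never zero and remain valid p-values for Benjamini-Hochberg.
#' @param bh_scope `"study"` (default): the Benjamini-Hochberg family is
#'   all included sites of one study, separately per tail. `"portfolio"`:
#'   one family per tail across all studies.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_iterations = 1000L, alpha = 0.05, seed = 1L,
                             min_sites_per_study = 4L,
                             min_subjects_per_site = 2L,
                             convergence_start = NULL,
                             cv_threshold = 0.01,
                             pseudo_count = TRUE,
                             bh_scope = c("study", "portfolio")) {
  bh_scope <- match.arg(bh_scope)
  convergence_start <- convergence_start %||% min(800L, as.integer(n_iterations))
  for (nm in c("n_iterations", "alpha", "seed", "min_sites_per_study",
               "min_subjects_per_site", "convergence_start", "cv_threshold")) {
    assert_scalar_number(get(nm), nm)
  }
  if (n_iterations < 1L) config_error("n_iterations must be >= 1")
  if (alpha <= 0 || alpha >= 1) config_error("alpha must be in (0, 1)")
  if (min_sites_per_study < 1L) config_error("min_sites_per_study must be >= 1")
  if (convergence_start < 1L || convergence_start > n_iterations) {
    config_error("convergence_start must lie in [1, n_iterations]")
  }
  structure(list(
    n_iterations = as.integer(n_iterations), alpha = alpha,
    seed = as.integer(seed),
    min_sites_per_study = as.integer(min_sites_per_study),
    min_subjects_per_site = as.integer(min_subjects_per_site),
    convergence_start = as.integer(convergence_start),
    cv_threshold = cv_threshold,
    pseudo_count = isTRUE(pseudo_count),
    bh_scope = bh_scope
  ), class = "bootstrap_config")
}

#' Apply the eligibility filters to a portfolio
#'
#' Studies with fewer than `min_sites_per_study` sites are removed
#' entirely; within retained studies, sites with fewer than
#' `min_subjects_per_site` participants are marked for exclusion from the
#' bootstrap (they still appear in detector output flagged
#' `insufficient_data`). Everything removed or marked is recorded in the
#' exclusion log so nothing disappears silently.
#'
#' @param portfolio a `pd_portfolio`.
#' @param config a [bootstrap_config()].
#' @return A list with `portfolio` (eligible studies), `insufficient`
#'   (tibble of study_id/site_id marked insufficient) and `exclusions`
#'   (tibble `study_id`, `site_id`, `reason`).
#' @export
filter_eligible <- function(portfolio, config = bootstrap_config()) {
  exclusions <- tibble(study_id = character(), site_id = character(),
                       reason = character())
  insufficient <- tibble(study_id = character(), site_id = character())
  keep <- list()
  for (study in portfolio) {
    n_sites <- length(study$site_index)
    if (n_sites < config$min_sites_per_study) {
      exclusions <- bind_rows(exclusions, tibble(
        study_id = study$study_id, site_id = NA_character_,
        reason = sprintf("study has %d site(s); fewer than %d",
                         n_sites, config$min_sites_per_study)))
      next
    }
    site_n <- lengths(study$site_index)
    small <- names(site_n)[site_n < config$min_subjects_per_site]
    if (length(small)) {
      exclusions <- bind_rows(exclusions, tibble(
        study_id = study$study_id, site_id = small,
        reason = sprintf("site has %d participant(s); fewer than %d",
                         site_n[small], config$min_subjects_per_site)))
      insufficient <- bind_rows(insufficient, tibble(
        study_id = study$study_id, site_id = small))
    }
    keep[[study$study_id]] <- study
  }
  list(portfolio = structure(keep, class = "pd_portfolio"),
       insufficient = insufficient, exclusions = exclusions)
}

#' Site test statistic: mean cumulative PD count per participant
#'
#' The statistic is the arithmetic mean, over a site's participants, of
#' each participant's total deviation count. Visit exposure is controlled
#' by the visit-matched resampling null rather than by dividing counts by
#' visits; see the package vignette for the rationale.
#'
#' @param n_pds integer vector of per-participant cumulative PD counts.
#' @return The mean count.
#' @export
site_statistic <- function(n_pds) {
  if (length(n_pds) == 0L) abort("site has no participants")
  mean(n_pds)
}

#' Draw one visit-matched resampling assignment for a study
#'
#' Each participant is replaced by a participant drawn uniformly with
#' replacement from all participants of the same study with exactly the
#' same visit count (the pool includes the participant themselves and
#' their site mates, so it is never empty). Site membership is untouched:
#' only the deviation counts are transplanted.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param participants a study's participant tibble.
#' @return An integer vector `idx` such that participant `i` receives the
#'   PD count of participant `idx[i]`.
#' @export
resample_study <- function(participants) {
  v <- participants$n_visits
  idx <- integer(length(v))
  pools <- split(seq_along(v), v)
  for (pool in pools) {
    idx[pool] <- pool[sample.int(length(pool), length(pool), replace = TRUE)]
  }
  idx
}

#' Bootstrap tail probabilities for every included site of one study
#'
#' Runs the six-step resampling scheme: record the observed site means,
#' repeatedly replace every participant by a random visit-matched
#' participant from the same study, recompute the site means, and estimate
#' for each site the probability of a resampled mean at or below
#' (`p_low`) / at or above (`p_high`) the observed one. All sites share
#' the same resampled assignments within an iteration, so results do not
#' depend on the order in which sites are read out. The full participant
#' pool of the study (including participants at sites later excluded as
#' too small) feeds the resampling; probabilities are only reported for
#' included sites.
#'
#' @param study a `study_frame`.
#' @param config a [bootstrap_config()]; the RNG stream is
#'   `hash_seed(study_id, config$seed)`, so identical config and study
#'   give bitwise-identical output.
#' @param convergence if `TRUE`, also return per-site running probability
#'   estimates and their trailing-window coefficient of variation.
#' @param exclude_sites site ids to omit from the output (insufficient
#'   sites); their participants still populate the resampling pools.
#' @return A list with `results` (tibble: `study_id`, `site_id`,
#'   `n_participants`, `observed_mean`, `p_low`, `p_high`) and
#'   `convergence` (`NULL`, or a tibble with one row per site and tail
#'   carrying the running estimates as a list column, the window CV and
#'   the convergence verdict).
#' @export
bootstrap_probabilities <- function(study, config = bootstrap_config(),
                                    convergence = FALSE,
                                    exclude_sites = character()) {
  B <- config$n_iterations
  part <- study$participants
  pds <- as.numeric(part$n_pds)
  site <- part$site_id
  sites <- setdiff(sort(unique(site)), exclude_sites)
  if (length(sites) == 0L) abort("no included sites")

  site_f <- factor(site, levels = sites)  # NA for excluded sites
  counts <- tabulate(site_f, nbins = length(sites))
  inc <- !is.na(site_f)
  obs <- as.numeric(tapply(pds[inc], site_f[inc], mean))

  # membership indicator; resampled site means are one matrix product
  ind <- outer(site, sites, `==`) * 1

  withr::with_seed(hash_seed(study$study_id, config$seed), {
    n <- length(pds)
    M <- matrix(0, nrow = B, ncol = n)
    pools <- split(seq_len(n), part$n_visits)
    for (pool in pools) {
      k <- length(pool)
      draw <- pool[sample.int(k, k * B, replace = TRUE)]
      M[, pool] <- pds[draw]
    }
  })
  means <- sweep(M %*% ind, 2, counts, "/")  # B x S resampled site means

  le <- sweep(means, 2, obs, "<=")
  ge <- sweep(means, 2, obs, ">=")
  c_low <- colSums(le)
  c_high <- colSums(ge)
  if (config$pseudo_count) {
    p_low <- (c_low + 1) / (B + 1)
    p_high <- (c_high + 1) / (B + 1)
  } else {
    p_low <- c_low / B
    p_high <- c_high / B
  }

  results <- tibble(
    study_id = study$study_id, site_id = sites,
    n_participants = counts, observed_mean = obs,
    p_low = as.numeric(p_low), p_high = as.numeric(p_high)
  )

  conv <- NULL
  if (convergence) {
    ks <- seq_len(B)
    win <- seq.int(config$convergence_start, B)
    rows <- list()
    for (j in seq_along(sites)) {
      for (tail in c("p_low", "p_high")) {
        cnt <- if (tail == "p_low") cumsum(le[, j]) else cumsum(ge[, j])
        running <- cnt / ks
        cv <- convergence_cv(running, win)
        rows[[length(rows) + 1L]] <- tibble(
          study_id = study$study_id, site_id = sites[j], tail = tail,
          cv_window = cv, converged = cv < config$cv_threshold,
          running_estimates = list(running))
      }
    }
    conv <- bind_rows(rows)
  }
  list(results = results, convergence = conv)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up adjustment via [stats::p.adjust()]: for sorted
#' p-values the adjusted value is `min over j >= i of p(j) * m / j`,
#' capped at 1; a hypothesis is rejected when its adjusted value is at or
#' below `alpha`.
#'
#' @param pvalues numeric vector with all values in (0, 1].
#' @param alpha rejection level (default 0.05).
#' @return A list with `adjusted` and logical `rejected`.
#' @export
adjust_bh <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) return(list(adjusted = numeric(), rejected = logical()))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  adjusted <- p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, rejected = adjusted <= alpha)
}

#' Set site flags from adjusted tail probabilities
#'
#' A site is an `under_reporter` when its adjusted lower-tail probability
#' is at or below `alpha`, a `high_rate` reporter when the adjusted
#' upper-tail probability is. If a pathological tie rejects both tails,
#' the flag follows the smaller adjusted value (lower tail on an exact
#' tie) and the `note` column records the tie-break.
#'
#' @param results tibble with `p_low_adj` and `p_high_adj` columns.
#' @param alpha rejection level.
#' @return `results` with `flag` and `note` columns set.
#' @export
flag_sites <- function(results, alpha = 0.05) {
  low <- !is.na(results$p_low_adj) & results$p_low_adj <= alpha
  high <- !is.na(results$p_high_adj) & results$p_high_adj <= alpha
  flag <- rep("none", nrow(results))
  note <- rep(NA_character_, nrow(results))
  flag[low] <- "under_reporter"
  flag[high] <- "high_rate"
  both <- low & high
  if (any(both)) {
    flag[both] <- ifelse(results$p_low_adj[both] <= results$p_high_adj[both],
                         "under_reporter", "high_rate")
    note[both] <- "both tails rejected; flag follows the smaller adjusted probability"
  }
  results$flag <- flag
  results$note <- note
  results
}

#' Coefficient of variation of running probability estimates
#'
#' The convergence diagnostic: the population standard deviation divided
#' by the mean of the running estimates `p_k = count_k / k` over a
#' trailing iteration window. Zero by convention when the window mean is
#' zero (an estimate pinned at zero has stabilised).
#'
#' @param running_estimates numeric vector of running estimates, one per
#'   iteration.
#' @param window integer vector of iteration indices to evaluate.
#' @return The CV (a non-negative number).
#' @export
convergence_cv <- function(running_estimates, window) {
  if (length(window) == 0L) abort("convergence window is empty")
  if (any(window < 1L) || any(window > length(running_estimates))) {
    abort("window indices outside [1, B]")
  }
  x <- running_estimates[window]
  m <- mean(x)
  if (m == 0) return(0)
  sqrt(mean((x - m)^2)) / m
}

#' Median site-level probabilities per study
#'
#' Descriptive study context: the median of the site-level lower- and
#' upper-tail probabilities, reported alongside results so reviewers can
#' judge sites relative to their study. Does not alter flags.
#'
#' @param results site-result tibble with `p_low`, `p_high`.
#' @return A tibble `study_id`, `median_p_low`, `median_p_high`,
#'   `n_sites`.
#' @export
study_reference_summary <- function(results) {
  results %>%
    filter(!is.na(.data$p_low)) %>%
    group_by(.data$study_id) %>%
    summarise(median_p_low = median(.data$p_low),
              median_p_high = median(.data$p_high),
              n_sites = n(), .groups = "drop")
}

#' Run the full outlier detector over a portfolio
#'
#' Eligibility filtering, per-study visit-matched bootstrap, per-tail
#' Benjamini-Hochberg adjustment and flagging, in one call.
#'
#' @param portfolio a `pd_portfolio`.
#' @param config a [bootstrap_config()].
#' @param convergence if `TRUE`, attach per-site convergence reports.
#' @return A tibble with one row per site of every eligible study:
#'   `study_id`, `site_id`, `n_participants`, `observed_mean`, `p_low`,
#'   `p_high`, `p_low_adj`, `p_high_adj`, `flag`, `note`. Sites excluded
#'   by the minimum-subject filter carry flag `insufficient_data` and NA
#'   probabilities. Attributes: `exclusions` (the eligibility log),
#'   `reference` (per-study median probabilities), and `convergence` when
#'   requested.
#' @export
detect_outliers <- function(portfolio, config = bootstrap_config(),
                            convergence = FALSE) {
  fe <- filter_eligible(portfolio, config)
  all_results <- list()
  conv_all <- list()
  for (study in fe$portfolio) {
    small <- fe$insufficient$site_id[fe$insufficient$study_id == study$study_id]
    bp <- bootstrap_probabilities(study, config, convergence = convergence,
                                  exclude_sites = small)
    res <- bp$results
    if (config$bh_scope == "study") {
      res$p_low_adj <- adjust_bh(res$p_low, config$alpha)$adjusted
      res$p_high_adj <- adjust_bh(res$p_high, config$alpha)$adjusted
    } else {
      res$p_low_adj <- NA_real_
      res$p_high_adj <- NA_real_
    }
    if (length(small)) {
      site_n <- lengths(study$site_index)[small]
      obs <- unname(vapply(small, function(s)
        site_statistic(study$participants$n_pds[study$site_index[[s]]]), 0))
      res <- bind_rows(res, tibble(
        study_id = study$study_id, site_id = small,
        n_participants = as.integer(site_n), observed_mean = obs,
        p_low = NA_real_, p_high = NA_real_,
        p_low_adj = NA_real_, p_high_adj = NA_real_))
    }
    all_results[[study$study_id]] <- res
    if (!is.null(bp$convergence)) conv_all[[study$study_id]] <- bp$convergence
  }
  out <- bind_rows(all_results)
  if (nrow(out) == 0L) {
    out <- tibble(study_id = character(), site_id = character(),
                  n_participants = integer(), observed_mean = numeric(),
                  p_low = numeric(), p_high = numeric(),
                  p_low_adj = numeric(), p_high_adj = numeric())
  }
  if (config$bh_scope == "portfolio" && nrow(out) > 0L) {
    inc <- !is.na(out$p_low)
    out$p_low_adj[inc] <- adjust_bh(out$p_low[inc], config$alpha)$adjusted
    out$p_high_adj[inc] <- adjust_bh(out$p_high[inc], config$alpha)$adjusted
  }
  out <- flag_sites(out, config$alpha)
  out$flag[is.na(out$p_low)] <- "insufficient_data"
  out <- arrange(out, .data$study_id, .data$site_id)
  attr(out, "exclusions") <- fe$exclusions
  attr(out, "reference") <- study_reference_summary(out)
  if (convergence) attr(out, "convergence") <- bind_rows(conv_all)
  out
}
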