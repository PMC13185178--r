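error_types <- c("boundary", "ambiguous", "rare", "straightforward")

#' Sample classified narratives for judging
#'
#' Uniform sample without replacement, reproducible from the seed.
#'
#' @param x tibble of classified narratives.
#' @param n sample size, at most `nrow(x)`.
#' @param seed integer seed.
#' @return A tibble of `n` rows.
#' @export
sample_for_judging <- function(x, n, seed) {
  x <- as_tibble(x)
  if (n > nrow(x)) abort("sample size exceeds population size")
  idx <- withr::with_seed(seed, sample.int(nrow(x), n))
  x[idx, , drop = FALSE]
}

#' Deterministic mock judge backend
#'
#' Stands in for an independent judge model. The verdict compares the
#' assigned topic against the generator's ground-truth topic. Incorrect
#' assignments receive an error type by transparent rules, mirroring the
#' four-way tally the harness reports: short narratives are `ambiguous`;
#' truths rare in the judged sample (< 1% of items) are `rare`;
#' assignments landing in the truth's own category are `boundary`;
#' anything else is a `straightforward` error.
#'
#' @param length_cutoff character count below which a misclassified
#'   narrative is deemed ambiguous (default 40).
#' @param taxonomy keyphrase taxonomy used to look up topic categories.
#' @return A backend function `(items)` returning a tibble with
#'   `verdict`, `error_type` and `rationale` per item. `items` must carry
#'   `narrative`, `assigned_topic` and `true_topic`.
#' @export
mock_judge <- function(length_cutoff = 40L, taxonomy = reference_taxonomy()) {
  force(length_cutoff)
  cat_of <- setNames(taxonomy$category, taxonomy$topic)
  function(items) {
    n <- nrow(items)
    truth_freq <- table(items$true_topic) / n
    verdict <- ifelse(items$assigned_topic == items$true_topic,
                      "correct", "incorrect")
    error_type <- rep("none", n)
    rationale <- rep("assigned topic matches the reference topic", n)
    wrong <- which(verdict == "incorrect")
    for (i in wrong) {
      if (nchar(items$narrative[i]) < length_cutoff) {
        error_type[i] <- "ambiguous"
        rationale[i] <- "narrative too short to disambiguate"
      } else if (truth_freq[[items$true_topic[i]]] < 0.01) {
        error_type[i] <- "rare"
        rationale[i] <- "reference topic is rare in the judged sample"
      } else if (!is.na(cat_of[items$assigned_topic[i]]) &&
                 !is.na(cat_of[items$true_topic[i]]) &&
                 cat_of[items$assigned_topic[i]] == cat_of[items$true_topic[i]]) {
        error_type[i] <- "boundary"
        rationale[i] <- "assigned topic lies in the same category as the reference"
      } else {
        error_type[i] <- "straightforward"
        rationale[i] <- "assigned topic unrelated to the reference"
      }
    }
    tibble(verdict = verdict, error_type = error_type, rationale = rationale)
  }
}

#' Judge a set of topic assignments
#'
#' Applies the judge backend to the whole batch; if the backend throws,
#' items are retried one at a time so a failure on one item never aborts
#' the run — the failing item is marked unjudged, excluded from the
#' denominator and kept in the `unjudged` attribute for inspection
#' (backends may equally return an `NA` verdict to skip an item). All
#' rationales are retained for human review.
#'
#' @param items tibble with `narrative_id`, `narrative`,
#'   `assigned_topic`, `true_topic`.
#' @param backend judge backend; default [mock_judge()].
#' @return A tibble of judged items (`verdict`, `error_type`,
#'   `rationale` appended), with attribute `unjudged` listing failures.
#' @export
judge_items <- function(items, backend = mock_judge()) {
  items <- as_tibble(items)
  stopifnot(all(c("narrative_id", "narrative", "assigned_topic",
                  "true_topic") %in% names(items)))
  res <- tryCatch(as_tibble(backend(items)), error = function(e) NULL)
  if (is.null(res) || nrow(res) != nrow(items)) {
    res <- bind_rows(lapply(seq_len(nrow(items)), function(i) {
      tryCatch(as_tibble(backend(items[i, , drop = FALSE])),
               error = function(e) tibble(verdict = NA_character_,
                                          error_type = NA_character_,
                                          rationale = conditionMessage(e)))
    }))
  }
  bad <- is.na(res$verdict) |
    (res$verdict == "incorrect" & !(res$error_type %in% error_types)) |
    (res$verdict == "correct" & res$error_type != "none")
  out <- items[!bad, , drop = FALSE]
  out$verdict <- res$verdict[!bad]
  out$error_type <- res$error_type[!bad]
  out$rationale <- res$rationale[!bad]
  un <- items[bad, , drop = FALSE]
  if (nrow(un)) un$rationale <- res$rationale[bad]
  attr(out, "unjudged") <- un
  out
}

#' Wilson score interval for a binomial proportion
#'
#' Closed-form score interval: centre `(p + z^2/2n) / (1 + z^2/n)`,
#' half-width `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`, with `z` the
#' standard-normal quantile for the confidence level computed at full
#' double precision. Unlike the Wald interval it stays inside `[0, 1]`
#' and keeps positive width at observed proportions of 0 or 1.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param confidence confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
wilson_interval <- function(x, n, confidence = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n, confidence > 0, confidence < 1)
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Clopper-Pearson exact interval for a binomial proportion
#'
#' @inheritParams wilson_interval
#' @return Named numeric vector `c(low, high)`.
#' @export
clopper_pearson_interval <- function(x, n, confidence = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n, confidence > 0, confidence < 1)
  a <- 1 - confidence
  low <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Summarise judged items into a validation report
#'
#' Accuracy with a binomial confidence interval plus the four-way tally
#' of error types among the incorrect items.
#'
#' @param judged tibble from [judge_items()].
#' @param confidence confidence level for the interval (default 0.95).
#' @param interval `"wilson"` (default) or `"clopper-pearson"`.
#' @return An object of class `validation_report`: `n`, `n_correct`,
#'   `accuracy`, `ci_low`, `ci_high`, `confidence`, `interval`,
#'   `error_counts`, `error_proportions` (among errors; empty when there
#'   are no errors).
#' @export
accuracy_report <- function(judged, confidence = 0.95,
                            interval = c("wilson", "clopper-pearson")) {
  interval <- match.arg(interval)
  judged <- as_tibble(judged)
  n <- nrow(judged)
  if (n == 0L) abort("no judged items")
  n_correct <- sum(judged$verdict == "correct")
  ci <- if (interval == "wilson") wilson_interval(n_correct, n, confidence)
        else clopper_pearson_interval(n_correct, n, confidence)
  errs <- judged$error_type[judged$verdict == "incorrect"]
  counts <- setNames(vapply(error_types, function(t) sum(errs == t), 0L),
                     error_types)
  props <- if (length(errs)) counts / length(errs) else
    setNames(numeric(length(error_types)), error_types)
  structure(list(
    n = n, n_correct = n_correct, accuracy = n_correct / n,
    ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
    confidence = confidence, interval = interval,
    error_counts = as.list(counts), error_proportions = as.list(props)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> accuracy %.1f%% (%d/%d), %d%% CI [%.1f%%, %.1f%%] (%s)\n",
              100 * x$accuracy, x$n_correct, x$n, round(100 * x$confidence),
              100 * x$ci_low, 100 * x$ci_high, x$interval))
  errs <- x$n - x$n_correct
  if (errs > 0) {
    for (t in names(x$error_counts)) {
      cat(sprintf("  %-16s %3d (%.0f%% of errors)\n", t,
                  x$error_counts[[t]], 100 * x$error_proportions[[t]]))
    }
  }
  invisible(x)
}
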