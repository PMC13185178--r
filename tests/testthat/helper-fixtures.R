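# Shared fixtures and independent oracles used across the suite.

# Build a one-study frame from parallel vectors.
toy_study <- function(site, n_visits, n_pds, study_id = "S1",
                      country = "US") {
  n <- length(site)
  study_frame(study_id, tibble::tibble(
    study_id = study_id, site_id = site,
    country = rep_len(country, n),
    participant_id = sprintf("P%03d", seq_len(n)),
    n_visits = as.integer(rep_len(n_visits, n)),
    n_pds = as.integer(rep_len(n_pds, n))))
}

# A portfolio wrapping one or more toy studies.
toy_portfolio <- function(...) {
  frames <- list(...)
  names(frames) <- vapply(frames, function(s) s$study_id, "")
  structure(frames, class = "pd_portfolio")
}

# Exact tail probabilities by exhaustive enumeration of every
# visit-matched replacement assignment (uniform over pool^n outcomes).
# Independent of the package's vectorised Monte-Carlo path.
enumerate_tail_probs <- function(study, site_id) {
  part <- study$participants
  pds <- part$n_pds
  pools <- split(seq_len(nrow(part)), part$n_visits)
  choices <- lapply(seq_len(nrow(part)), function(i) {
    pools[[as.character(part$n_visits[i])]]
  })
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  members <- which(part$site_id == site_id)
  obs <- mean(pds[members])
  means <- apply(grid, 1, function(assign) mean(pds[assign[members]]))
  c(p_low = mean(means <= obs), p_high = mean(means >= obs))
}

# O(n^2) silhouette oracle: plain double loop over points and clusters.
naive_silhouette <- function(emb, assign) {
  norms <- sqrt(rowSums(emb^2))
  x <- emb / norms
  d <- 1 - tcrossprod(x)
  d[d < 0] <- 0
  n <- nrow(emb)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assign == assign[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- Inf
    for (cl in setdiff(unique(assign), assign[i])) {
      b <- min(b, mean(d[i, assign == cl]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
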