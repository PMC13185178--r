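test_that("eligibility filtering removes small studies and marks small sites", {
  s3 <- toy_study(rep(c("a", "b", "c"), each = 2), 4, 1, study_id = "tiny")
  s5 <- toy_study(c(rep("a", 2), rep("b", 2), rep("c", 2), rep("d", 2), "e"),
                  4, 1, study_id = "ok")
  s4 <- toy_study(rep(c("a", "b", "c", "d"), each = 2), 4, 1, study_id = "full")
  fe <- filter_eligible(toy_portfolio(s3, s5, s4))
  expect_named(fe$portfolio, c("ok", "full"), ignore.order = TRUE)
  expect_true(any(fe$exclusions$study_id == "tiny" &
                    is.na(fe$exclusions$site_id)))
  expect_equal(fe$insufficient$site_id, "e")
  # the fully eligible study is untouched
  expect_equal(nrow(fe$exclusions[fe$exclusions$study_id == "full", ]), 0L)
})

test_that("the site statistic is the mean cumulative PD count", {
  expect_equal(site_statistic(c(2, 4)), 3)
  expect_equal(site_statistic(7), 7)
  expect_equal(site_statistic(c(0, 0, 3)), 1)
  expect_error(site_statistic(integer()), "no participants")
})

test_that("resampling pools partition by visit count and include self", {
  part <- tibble::tibble(n_visits = c(3L, 3L, 5L, 5L))
  withr::with_seed(11, {
    for (rep in 1:1000) {
      idx <- resample_study(part)
      expect_true(all(idx[1:2] %in% 1:2))
      expect_true(all(idx[3:4] %in% 3:4))
    }
  })
  # a unique visit count can only map to itself
  part1 <- tibble::tibble(n_visits = c(2L, 9L, 9L))
  withr::with_seed(12, {
    idx <- replicate(50, resample_study(part1)[1])
    expect_true(all(idx == 1L))
  })
})

test_that("a degenerate study with identical counts gives p = 1 both tails", {
  s <- toy_study(rep(c("a", "b", "c", "d"), each = 2), c(3, 4), 5,
                 study_id = "flat")
  cfg <- bootstrap_config(n_iterations = 50, seed = 1, pseudo_count = FALSE)
  res <- bootstrap_probabilities(s, cfg)$results
  expect_true(all(res$p_low == 1))
  expect_true(all(res$p_high == 1))
})

test_that("identical seeds give bitwise-identical probabilities", {
  s <- toy_study(rep(c("a", "b", "c", "d"), each = 3), rep(c(3, 5, 7), 4),
                 rpois(12, 2), study_id = "det")
  cfg <- bootstrap_config(n_iterations = 300, seed = 42)
  r1 <- bootstrap_probabilities(s, cfg)$results
  r2 <- bootstrap_probabilities(s, cfg)$results
  expect_identical(r1, r2)
  r3 <- bootstrap_probabilities(s, bootstrap_config(n_iterations = 300,
                                                    seed = 43))$results
  expect_false(identical(r1$p_low, r3$p_low))
})

test_that("Monte-Carlo tail probabilities match exhaustive enumeration", {
  # two sites x two participants, one shared visit count: 4^4 assignments
  s <- toy_study(c("z", "z", "h", "h"), 4, c(0, 0, 5, 5), study_id = "toy")
  exact <- enumerate_tail_probs(s, "z")
  expect_equal(unname(exact["p_low"]), 0.25)  # both draws from the zero pair
  B <- 1000
  cfg <- bootstrap_config(n_iterations = B, seed = 5, pseudo_count = FALSE,
                          min_sites_per_study = 2)
  mc <- bootstrap_probabilities(s, cfg)$results
  se <- sqrt(exact * (1 - exact) / B)
  expect_lt(abs(mc$p_low[mc$site_id == "z"] - exact["p_low"]),
            3 * se["p_low"] + 1e-12)
  expect_lt(abs(mc$p_high[mc$site_id == "z"] - exact["p_high"]),
            3 * se["p_high"] + 1e-12)

  # a second toy with two visit pools and unequal site sizes
  s2 <- toy_study(c("a", "a", "b", "b", "b"), c(3, 5, 3, 5, 5),
                  c(1, 0, 4, 2, 6), study_id = "toy2")
  exact2 <- enumerate_tail_probs(s2, "a")
  cfg2 <- bootstrap_config(n_iterations = 1000, seed = 9,
                           pseudo_count = FALSE, min_sites_per_study = 2)
  mc2 <- bootstrap_probabilities(s2, cfg2)$results
  se2 <- pmax(sqrt(exact2 * (1 - exact2) / 1000), 1e-6)
  expect_lt(abs(mc2$p_low[mc2$site_id == "a"] - exact2["p_low"]),
            3 * se2["p_low"])
  expect_lt(abs(mc2$p_high[mc2$site_id == "a"] - exact2["p_high"]),
            3 * se2["p_high"])
})

test_that("both tails include equality so p_low + p_high >= 1", {
  withr::with_seed(2, {
    s <- toy_study(rep(letters[1:5], each = 4), sample(3:6, 20, TRUE),
                   rpois(20, 3), study_id = "tails")
  })
  res <- bootstrap_probabilities(s, bootstrap_config(n_iterations = 400,
                                                     seed = 8))$results
  expect_true(all(res$p_low + res$p_high >= 1))
  expect_true(all(res$p_low > 0 & res$p_low <= 1))
  expect_true(all(res$p_high > 0 & res$p_high <= 1))
})

test_that("Benjamini-Hochberg step-up matches hand computation", {
  expect_equal(adjust_bh(c(0.005, 0.01, 0.03, 0.04))$adjusted,
               c(0.02, 0.02, 0.04, 0.04))
  one <- adjust_bh(0.03, alpha = 0.05)
  expect_equal(one$adjusted, 0.03)
  expect_true(one$rejected)
  all1 <- adjust_bh(rep(1, 6))
  expect_true(all(all1$adjusted == 1))
  expect_false(any(all1$rejected))
  expect_error(adjust_bh(c(0.5, 0)), "0, 1")
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})

test_that("flags follow the adjusted tail probabilities", {
  res <- tibble::tibble(p_low_adj = c(0.01, 0.9, 1, 0.02),
                        p_high_adj = c(1, 0.02, 1, 0.02))
  out <- flag_sites(res, alpha = 0.05)
  expect_equal(out$flag, c("under_reporter", "high_rate", "none",
                           "under_reporter"))
  expect_false(is.na(out$note[4]))  # tie documented
})

test_that("convergence CV matches its definition", {
  expect_equal(convergence_cv(rep(0.4, 100), 50:100), 0)
  expect_equal(convergence_cv(c(0.5, 0.5, 1, 1), 1:4), 1 / 3)
  expect_equal(convergence_cv(rep(0, 10), 1:10), 0)  # zero-mean convention
  expect_error(convergence_cv(1:10, integer()), "empty")
  expect_error(convergence_cv(1:10, 5:12), "outside")
})

test_that("per-study reference summaries are medians of site probabilities", {
  res <- tibble::tibble(study_id = "A", site_id = letters[1:4],
                        p_low = c(0.1, 0.3, 0.7, 0.9),
                        p_high = c(0.2, 0.5, 0.9, 0.95))
  s <- study_reference_summary(res)
  expect_equal(s$median_p_low, 0.5)
  res1 <- tibble::tibble(study_id = "B", site_id = "x", p_low = 0.4,
                         p_high = 0.8)
  expect_equal(study_reference_summary(res1)$median_p_low, 0.4)
})

test_that("lowering a site's counts never increases its p_low", {
  withr::with_seed(33, {
    s <- toy_study(rep(letters[1:6], each = 5), sample(4:8, 30, TRUE),
                   rpois(30, 4), study_id = "mono")
  })
  cfg <- bootstrap_config(n_iterations = 400, seed = 17)
  base <- bootstrap_probabilities(s, cfg)$results
  for (shift in c(1, 3)) {
    part2 <- s$participants
    sel <- part2$site_id == "c"
    part2$n_pds[sel] <- pmax(part2$n_pds[sel] - shift, 0L)
    s2 <- study_frame("mono", part2)
    res2 <- bootstrap_probabilities(s2, cfg)$results
    expect_lte(res2$p_low[res2$site_id == "c"],
               base$p_low[base$site_id == "c"])
  }
})

test_that("relabeling sites permutes results without changing values", {
  withr::with_seed(4, {
    s <- toy_study(rep(c("a", "b", "c", "d"), each = 4),
                   sample(3:6, 16, TRUE), rpois(16, 2), study_id = "perm")
  })
  cfg <- bootstrap_config(n_iterations = 300, seed = 6)
  r1 <- bootstrap_probabilities(s, cfg)$results
  relabel <- c(a = "d", b = "c", c = "b", d = "a")
  part2 <- s$participants
  part2$site_id <- unname(relabel[part2$site_id])
  r2 <- bootstrap_probabilities(study_frame("perm", part2), cfg)$results
  r2$site_id <- names(relabel)[match(r2$site_id, relabel)]
  r2 <- r2[order(r2$site_id), ]
  expect_equal(r2$p_low, r1$p_low, tolerance = 1e-12)
  expect_equal(r2$observed_mean, r1$observed_mean)
})

test_that("detector output lists insufficient sites without probabilities", {
  s <- toy_study(c(rep("a", 2), rep("b", 2), rep("c", 2), rep("d", 2), "solo"),
                 4, c(1, 2, 0, 1, 3, 2, 1, 1, 9), study_id = "mix")
  res <- detect_outliers(toy_portfolio(s),
                         bootstrap_config(n_iterations = 100, seed = 2))
  solo <- res[res$site_id == "solo", ]
  expect_equal(solo$flag, "insufficient_data")
  expect_true(is.na(solo$p_low))
  expect_equal(solo$observed_mean, 9)
  expect_equal(sum(res$flag != "insufficient_data"), 4L)
})

test_that("detector results are reproducible and study-wise independent", {
  g <- generate_portfolio(synthetic_config(n_studies = 3, sites_per_study = 5,
                                           participants_per_site = c(4, 6),
                                           generate_narratives = FALSE,
                                           seed = 21))
  cfg <- bootstrap_config(n_iterations = 150, seed = 5)
  r_all <- detect_outliers(g$portfolio, cfg)
  # dropping a study must not change the others (per-study RNG streams)
  sub <- structure(g$portfolio[c("S0001", "S0003")], class = "pd_portfolio")
  r_sub <- detect_outliers(sub, cfg)
  for (col in c("p_low", "p_high")) {
    expect_identical(r_sub[[col]],
                     r_all[[col]][r_all$study_id %in% c("S0001", "S0003")])
  }
})
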