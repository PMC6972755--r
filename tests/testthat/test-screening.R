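test_that("defect classification matches the printed rules and
           boundaries", {
  expect_equal(as.character(classify_defect(25, 25, 50)$label),
               "decid_failure")
  expect_equal(as.character(classify_defect(25, 75, 50)$label),
               "excess_senescence")
  expect_equal(as.character(classify_defect(50, 50, 25)$label),
               "unk_deficiency")
  expect_equal(as.character(classify_defect(80, 20, 80)$label), "none")
  # thresholds are inclusive exactly as printed (<= 30th, >= 70th)
  expect_equal(as.character(classify_defect(30, 30, 50)$label),
               "decid_failure")
  expect_equal(as.character(classify_defect(30, 70, 50)$label),
               "excess_senescence")
  # the uNK rule needs both markers strictly inside (30, 70)
  expect_equal(as.character(classify_defect(30.5, 69.5, 30)$label),
               "unk_deficiency")
  # scara5 at the low boundary with mid-range dio2 matches no rule
  expect_equal(as.character(classify_defect(30, 50, 10)$label), "none")
  expect_error(classify_defect(101, 50, 50), "\\[0, 100\\]")
  expect_error(classify_defect(-1, 50, 50), "\\[0, 100\\]")
  expect_error(defect_rules(70, 30), "low_threshold")
})

test_that("every percentile triple receives exactly one label", {
  # coarse grid here; the full integer grid runs in the acceptance suite
  g <- as.matrix(expand.grid(s = seq(0, 100, by = 5),
                             d = seq(0, 100, by = 5),
                             u = seq(0, 100, by = 5)))
  calls <- classify_defect(g[, "s"], g[, "d"], g[, "u"])
  # independent restatement of the three rule regions
  r1 <- g[, "s"] <= 30 & g[, "d"] <= 30
  r2 <- g[, "s"] <= 30 & g[, "d"] >= 70
  r3 <- g[, "u"] <= 30 & g[, "s"] > 30 & g[, "s"] < 70 &
    g[, "d"] > 30 & g[, "d"] < 70
  n_rules <- r1 + r2 + r3
  expect_true(all(n_rules <= 1))
  expect_equal(as.character(calls$label) == "none", n_rules == 0)
  expect_false(anyNA(calls$label))
})

test_that("percentile-sum bins follow the half-open convention", {
  expect_equal(bin_percentile_sum(0, 0), 1L)
  expect_equal(bin_percentile_sum(100, 100), 4L)
  expect_equal(bin_percentile_sum(50, 50), 3L)  # sum 100 -> [100, 150)
  expect_equal(bin_percentile_sum(25, 24.9), 1L)
  expect_equal(bin_percentile_sum(25, 25), 2L)
  custom <- bin_scheme(edges = c(20, 180))
  expect_equal(bin_percentile_sum(c(5, 50, 95), c(5, 50, 95), custom),
               c(1L, 2L, 3L))
  expect_error(bin_scheme(edges = c(100, 50)), "increasing")
})

test_that("Fisher's exact p-values match full hypergeometric
           enumeration", {
  # perfectly homogeneous [[5,5],[5,5]] table
  res0 <- cohort_contingency(rep(c("a", "b"), each = 10),
                             rep(c("x", "y"), 10))
  expect_equal(res0$method, "fisher")
  expect_equal(res0$p_value, 1)

  # perfectly separated table: p = 2 / choose(20, 10)
  cats <- rep(c("a", "b"), each = 10)
  grps <- rep(c("x", "y"), each = 10)
  res <- cohort_contingency(cats, grps)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p_value, exact_fisher_p(res$table), tolerance = 1e-12)

  # random small tables agree with the enumeration oracle
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(8:60, 1)
    cats <- sample(c("a", "b"), n, replace = TRUE)
    grps <- sample(c("x", "y"), n, replace = TRUE)
    tab <- table(cats, grps)
    if (any(dim(tab) < 2)) next
    res <- cohort_contingency(cats, grps)
    expect_equal(res$p_value, exact_fisher_p(res$table),
                 tolerance = 1e-12)
  }

  # the extreme-bin composition table seen in the four-bin analysis
  big <- cohort_contingency(rep(c("low", "high"), c(31, 19)),
                            rep(c("rpl", "control", "rpl", "control"),
                                c(25, 6, 4, 15)))
  expect_lt(big$p_value, 1e-4)
  expect_equal(big$p_value, exact_fisher_p(big$table), tolerance = 1e-12)

  # larger tables fall back to the chi-squared test
  res3 <- cohort_contingency(rep(c("a", "b", "c"), each = 10),
                             rep(c("x", "y"), 15))
  expect_equal(res3$method, "chisq")
  expect_error(cohort_contingency(c("a", "b"), c("x", "x")), "both groups")
})

test_that("cohort screening summaries equal brute-force enumeration", {
  set.seed(15)
  n <- 50
  samples <- data.frame(
    subject_id = sprintf("p%02d", 1:n),
    group = rep(c("control", "rpl"), each = 25),
    scara5_pct = round(runif(n, 0, 100), 1),
    dio2_pct = round(runif(n, 0, 100), 1),
    unk_pct = round(runif(n, 0, 100), 1))
  scr <- screen_cohort(samples)

  # brute-force re-derivation, subject by subject
  lab <- character(n)
  bin <- integer(n)
  for (i in 1:n) {
    s <- samples$scara5_pct[i]; d <- samples$dio2_pct[i]
    u <- samples$unk_pct[i]
    lab[i] <- if (s <= 30 && d <= 30) "decid_failure"
      else if (s <= 30 && d >= 70) "excess_senescence"
      else if (u <= 30 && s > 30 && s < 70 && d > 30 && d < 70)
        "unk_deficiency"
      else "none"
    total <- s + u
    bin[i] <- if (total < 50) 1L else if (total < 100) 2L
      else if (total < 150) 3L else 4L
  }
  expect_equal(as.character(scr$per_subject$label), lab)
  expect_equal(scr$per_subject$bin, bin)
  for (g in c("control", "rpl")) {
    expect_equal(
      unname(scr$summary$aberrant_incidence[g]),
      100 * mean(lab[samples$group == g] != "none"))
  }
  expect_equal(as.vector(scr$summary$bin_table),
               as.vector(table(factor(bin, 1:4), samples$group)))

  # permuting subject order changes no summary number
  perm <- sample(n)
  scr2 <- screen_cohort(samples[perm, ])
  expect_equal(scr2$summary$defect_table, scr$summary$defect_table)
  expect_equal(scr2$summary$aberrant_incidence,
               scr$summary$aberrant_incidence)
  expect_equal(scr2$summary$aberrant_test$p_value,
               scr$summary$aberrant_test$p_value)

  expect_error(screen_cohort(rbind(samples, samples[1, ])), "duplicate")
})

test_that("uniformly healthy cohorts screen as aberrant-free", {
  samples <- data.frame(subject_id = sprintf("h%02d", 1:20),
                        group = rep(c("control", "rpl"), 10),
                        scara5_pct = 90, dio2_pct = 10, unk_pct = 90)
  scr <- screen_cohort(samples)
  expect_true(all(scr$summary$aberrant_incidence == 0))
  expect_true(all(scr$per_subject$label == "none"))

  # zero planted prevalence propagates to exactly zero aberrant calls
  # when scored against the generative truth percentiles
  zero <- c(decid_failure = 0, excess_senescence = 0, unk_deficiency = 0)
  sim <- generate_cohort(cohort_sim_config(
    n_control = 30, n_rpl = 30,
    prevalence_by_group = list(control = zero, rpl = zero), seed = 9))
  pct <- data.frame(subject_id = sim$truth$subject_id,
                    group = sim$cohort$group,
                    scara5_pct = sim$truth$scara5_pct,
                    dio2_pct = sim$truth$dio2_pct,
                    unk_pct = sim$truth$unk_pct)
  expect_equal(unname(screen_cohort(pct)$summary$aberrant_incidence),
               c(0, 0))
})

test_that("screen reports serialize to disk", {
  samples <- data.frame(subject_id = sprintf("x%02d", 1:12),
                        group = rep(c("control", "rpl"), 6),
                        scara5_pct = runif(12, 0, 100),
                        dio2_pct = runif(12, 0, 100),
                        unk_pct = runif(12, 0, 100))
  scr <- screen_cohort(samples)
  dir <- tempfile("screen")
  write_screen_report(scr, dir)
  expect_true(file.exists(file.path(dir, "per_subject.tsv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  back <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(back$group_sizes$control, 6)
})
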