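test_that("shifts are post minus pre, per key, ERP-removed variant", {
  st <- expand.grid(subject = c("s1", "s2"), channel = "Cz",
                    cue_type = "neutral",
                    window = c("pre_cue", "post_cue_1", "post_cue_2",
                               "post_cue_3"),
                    variant = c("total", "erp_removed"),
                    stringsAsFactors = FALSE)
  st$slope <- -1.0
  st$slope[st$window == "post_cue_1" & st$variant == "erp_removed"] <- -1.2
  st$slope[st$window == "post_cue_1" & st$variant == "total"] <- -9  # ignored
  sh <- compute_shifts(st)
  s1 <- sh[sh$shift == "Shift1", ]
  expect_equal(s1$value, c(-0.2, -0.2))
  expect_equal(sh$value[sh$shift == "Shift2"], c(0, 0))
  expect_equal(sort(unique(sh$shift)), c("Shift1", "Shift2", "Shift3"))
  ## missing baseline is a key error naming the key
  expect_error(compute_shifts(st[st$window != "pre_cue", ]), "key error")
})

test_that("shifts are invariant to per-subject slope offsets", {
  set.seed(3)
  st <- expand.grid(subject = sprintf("s%d", 1:5), channel = c("Fz", "Cz"),
                    cue_type = "all",
                    window = c("pre_cue", "post_cue_1", "post_cue_3"),
                    variant = "erp_removed", stringsAsFactors = FALSE)
  st$slope <- stats::rnorm(nrow(st))
  sh0 <- compute_shifts(st)
  st2 <- st
  st2$slope <- st$slope + stats::ave(rep(0, nrow(st)), st$subject,
                                     FUN = function(z) stats::rnorm(1))
  sh1 <- compute_shifts(st2)
  expect_equal(sh1$value, sh0$value, tolerance = 1e-12)
})

test_that("cluster_average means channels and checks membership", {
  tbl <- expand.grid(subject = "s1", channel = c("Fz", "Cz", "Pz"),
                     shift = "Shift1", stringsAsFactors = FALSE)
  tbl$value <- c(-0.1, -0.3, -0.5)
  one <- cluster_average(tbl, list(mid = "Cz"))
  expect_equal(one$value, -0.3)
  two <- cluster_average(tbl, list(fc = c("Fz", "Cz")))
  expect_equal(two$value, -0.2)
  ## equal-size partition: grand mean equals mean of cluster means
  part <- cluster_average(tbl[tbl$channel != "Pz", ],
                          list(a = "Fz", b = "Cz"))
  expect_equal(mean(part$value), mean(c(-0.1, -0.3)))
  expect_error(cluster_average(tbl, list(fc = character(0))), "config error")
  expect_error(cluster_average(tbl, list(fc = c("Fz", "XX"))), "key error")
})

test_that("observed F statistics match the classical split-plot ANOVA", {
  set.seed(11)
  d <- expand.grid(subject = sprintf("s%02d", 1:10),
                   win = c("w1", "w2", "w3"), clu = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$grp <- ifelse(match(d$subject, unique(d$subject)) <= 5, "y", "o")
  d$y <- stats::rnorm(nrow(d)) +
    0.6 * (d$win == "w2") + 0.4 * (d$grp == "y") * (d$clu == "b")
  res <- permutation_mixed_anova(d, "y", "subject", within = c("win", "clu"),
                                 between = "grp", n_perm = 200, seed = 1)
  a <- summary(stats::aov(y ~ grp * win * clu + Error(subject / (win * clu)),
                          data = d))
  f_aov <- c(
    grp = a[["Error: subject"]][[1]]["grp", "F value"],
    win = a[["Error: subject:win"]][[1]]["win", "F value"],
    `grp:win` = a[["Error: subject:win"]][[1]]["grp:win", "F value"],
    clu = a[["Error: subject:clu"]][[1]]["clu", "F value"],
    `grp:clu` = a[["Error: subject:clu"]][[1]]["grp:clu", "F value"],
    `win:clu` = a[["Error: subject:win:clu"]][[1]]["win:clu", "F value"],
    `grp:win:clu` = a[["Error: subject:win:clu"]][[1]]["grp:win:clu",
                                                       "F value"])
  for (eff in names(f_aov))
    expect_equal(res$F[res$effect == eff], unname(f_aov[eff]),
                 tolerance = 1e-10, label = paste("F for", eff))
})

test_that("identical responses give F = 0 and p = 1 for within effects", {
  d <- expand.grid(subject = sprintf("s%d", 1:6), win = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$y <- 5
  res <- permutation_mixed_anova(d, "y", "subject", within = "win",
                                 n_perm = 100, seed = 2)
  expect_true(all(!is.finite(res$F) | res$F == 0))
  expect_equal(res$p[res$effect == "win"], 1)
})

test_that("the smallest attainable permutation p is 1/(n_perm+1)", {
  set.seed(5)
  d <- expand.grid(subject = sprintf("s%02d", 1:20), win = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$y <- stats::rnorm(nrow(d), sd = 0.01) + 10 * (d$win == "w2")
  res <- permutation_mixed_anova(d, "y", "subject", within = "win",
                                 n_perm = 1000, seed = 3)
  p <- res$p[res$effect == "win"]
  expect_equal(p, 1 / 1001)          # overwhelming effect attains the floor
  expect_gte(p, 1 / 1001)           # the formula can never go below it
})

test_that("unbalanced designs and tiny permutation counts are flagged", {
  d <- expand.grid(subject = c("s1", "s2", "s3"), win = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$y <- stats::rnorm(nrow(d))
  expect_warning(permutation_mixed_anova(d, "y", "subject", within = "win",
                                         n_perm = 50, seed = 1),
                 "coarse")
  expect_error(permutation_mixed_anova(d[-1, ], "y", "subject",
                                       within = "win", n_perm = 100,
                                       seed = 1),
               "unbalanced.*s1")
})

test_that("planned comparisons: paired, Welch, effect sizes, degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_error(planned_comparison(x, x, paired = TRUE), "degenerate")
  set.seed(7)
  a <- stats::rnorm(50); b <- stats::rnorm(50, mean = 1)
  w <- planned_comparison(a, b, paired = FALSE)
  expect_lt(w$p, 0.05)
  expect_false(w$df == 98)           # Welch df are fractional
  expect_lt(w$d, 0)
  p <- planned_comparison(a, a + stats::rnorm(50, 0.5, 0.1), paired = TRUE)
  expect_lt(p$p, 1e-10)
  expect_error(planned_comparison(1:2, 1:2), ">= 3")
})

test_that("Welch test detects a 1-SD group difference reliably", {
  set.seed(8)
  hits <- mean(replicate(200, {
    planned_comparison(stats::rnorm(50), stats::rnorm(50, 1),
                       paired = FALSE)$p < 0.05
  }))
  expect_gt(hits, 0.99)
})

test_that("within-subject SEs remove subject offsets (Cousineau-Morey)", {
  set.seed(9)
  d <- expand.grid(subject = sprintf("s%02d", 1:20),
                   win = c("w1", "w2"), stringsAsFactors = FALSE)
  offsets <- stats::rnorm(20, sd = 5)
  d$y <- offsets[match(d$subject, unique(d$subject))]   # pure offsets
  ws <- within_subject_se(d, "y", "subject", "win")
  expect_lt(max(ws$se), 1e-10)
  ## no offsets: equals classical SE times the Morey factor sqrt(m/(m-1))
  d$y <- stats::rnorm(nrow(d))
  ws <- within_subject_se(d, "y", "subject", "win")
  classical <- tapply(d$y, d$win, function(v) stats::sd(v) / sqrt(length(v)))
  centered <- d$y - stats::ave(d$y, d$subject) + mean(d$y)
  per_cell <- tapply(centered, d$win, function(v) stats::sd(v) / sqrt(length(v)))
  expect_equal(ws$se, as.vector(sqrt(2) * per_cell), tolerance = 1e-12)
  expect_error(within_subject_se(d[d$win == "w1", ], "y", "subject", "win"),
               "single cell")
})
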