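test_that("log transform is exact, label-preserving, and guards positivity", {
  tr <- simulate_leaf_traits(sim_config(seed = 1))
  lt <- log_transform_traits(tr)
  expect_identical(lt$species, tr$species)
  expect_identical(lt$pft, tr$pft)
  expect_equal(exp(lt$SLA), tr$SLA, tolerance = 1e-12)
  expect_equal(log_transform_traits(data.frame(species = "s", pft = "GG",
                                               SLA = exp(1)))$SLA, 1)
  bad <- tr; bad$SLA[3] <- -1
  expect_error(log_transform_traits(bad), paste0(bad$species[3], "/SLA"))
})

test_that("one-way ANOVA matches a brute-force sum-of-squares oracle", {
  vals <- c(1, 2, 3, 2, 3, 4, 10, 11, 12)
  grp <- rep(c("A", "B", "C"), each = 3)
  res <- anova_oneway(vals, grp)
  # explicit decomposition
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(vals, grp, function(v) (v - mean(v))^2)))
  F_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, F_oracle, tolerance = 1e-12)
  expect_equal(res$ss_between, ssb, tolerance = 1e-12)
  expect_equal(res$ss_within, ssw, tolerance = 1e-12)
  expect_equal(res$p, pf(F_oracle, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  # SS identity, including unequal group sizes
  set.seed(5)
  v2 <- rnorm(36); g2 <- rep(c("a", "b", "c", "d", "e"), c(3, 6, 5, 7, 15))
  r2 <- anova_oneway(v2, g2)
  expect_equal(r2$ss_between + r2$ss_within, sum((v2 - mean(v2))^2),
               tolerance = 1e-9)
})

test_that("five groups on 36 units give the (4, 31) df structure", {
  set.seed(6)
  vals <- rnorm(36)
  grp <- rep(c("GG", "ES", "ET", "DS", "DT"), c(3, 6, 5, 7, 15))
  res <- anova_oneway(vals, grp)
  expect_equal(res$df_between, 4)
  expect_equal(res$df_within, 31)
})

test_that("equal observations across groups give F = 0, p = 1", {
  res <- anova_oneway(rep(5, 9), rep(c("A", "B", "C"), each = 3))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_error(anova_oneway(1:3, c("A", "A", "B")), "B")
  expect_error(anova_oneway(1:4, rep("A", 4)), "two groups")
})

test_that("two-group Tukey equals the pooled-variance t-test (q = sqrt(2)|t|)", {
  set.seed(7)
  vals <- c(rnorm(6), rnorm(9, mean = 1))
  grp <- rep(c("A", "B"), c(6, 9))
  tk <- tukey_hsd(vals, grp)
  tt <- t.test(vals ~ grp, var.equal = TRUE)
  expect_equal(tk$pairs$q, sqrt(2) * abs(tt$statistic), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(tk$pairs$p_adj, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey-Kramer q and p match TukeyHSD on unequal group sizes", {
  set.seed(8)
  vals <- c(rnorm(4), rnorm(7, 1), rnorm(12, 3))
  grp <- factor(rep(c("A", "B", "C"), c(4, 7, 12)))
  tk <- tukey_hsd(vals, grp)
  ref <- TukeyHSD(aov(vals ~ grp))$grp
  # same pair order: B-A, C-A, C-B
  expect_equal(tk$pairs$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(tk$pairs$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
  # and the q statistic matches the hand formula
  msw <- anova_oneway(vals, grp)$ss_within / anova_oneway(vals, grp)$df_within
  n <- table(grp)
  q_hand <- abs(diff(tapply(vals, grp, mean))[1]) /
    sqrt(msw / 2 * (1 / n["A"] + 1 / n["B"]))
  expect_equal(tk$pairs$q[1], unname(q_hand), tolerance = 1e-10)
})

test_that("identical groups share one letter; separated groups differ", {
  vals <- rep(c(0.1, 0.11, 0.09), 3)
  tk <- tukey_hsd(vals + rnorm(9, sd = 1e-6), rep(c("A", "B", "C"), each = 3))
  expect_false(any(tk$pairs$significant))
  expect_true(length(unique(tk$letters)) == 1)
  set.seed(9)
  vals2 <- c(rnorm(5), rnorm(5, 50), rnorm(5, 100))
  tk2 <- tukey_hsd(vals2, rep(c("A", "B", "C"), each = 5))
  expect_true(all(tk2$pairs$significant))
  expect_equal(length(unique(tk2$letters)), 3)
})

test_that("raising alpha never turns a significant pair non-significant", {
  set.seed(10)
  vals <- c(rnorm(5), rnorm(6, 0.8), rnorm(4, 2))
  grp <- rep(c("A", "B", "C"), c(5, 6, 4))
  sig05 <- tukey_hsd(vals, grp, alpha = 0.05)$pairs$significant
  sig20 <- tukey_hsd(vals, grp, alpha = 0.20)$pairs$significant
  expect_true(all(sig20[sig05]))
})

test_that("elbow selects K = 3 on three well-separated blobs", {
  set.seed(11)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  x <- centers[rep(1:3, each = 4), ] + matrix(rnorm(24, sd = 0.1), 12, 2)
  km <- kmeans_elbow(x, k_range = 2:5, seed = 2)
  expect_equal(km$k_star, 3)
  expect_equal(length(unique(km$assignments[1:4])), 1)
  expect_equal(length(unique(km$assignments)), 3)
  # variance decomposition identity and monotone WSS
  expect_equal(km$per_k$intra_pct + km$per_k$inter_pct, rep(100, 4),
               tolerance = 1e-9)
  expect_true(all(diff(km$per_k$wss) <= 1e-8))
})

test_that("identical points are reported as degenerate", {
  x <- matrix(1, 10, 3)
  km <- kmeans_elbow(x, k_range = 2:5, seed = 1)
  expect_true(km$degenerate)
  expect_true(is.na(km$k_star))
  expect_true(all(km$per_k$wss < 1e-12))
  expect_error(kmeans_elbow(matrix(rnorm(8), 4, 2), k_range = 2:5), "smaller")
})

test_that("trait generator: counts, labels, and syndrome ordering", {
  tr <- simulate_leaf_traits(sim_config(seed = 1))
  expect_equal(nrow(tr), 32)
  expect_equal(unname(table(tr$pft)[c("GG", "ES", "ET", "DS", "DT")]),
               c(3, 6, 5, 3, 15), ignore_attr = TRUE)
  for (s in 1:10) {
    tr <- simulate_leaf_traits(sim_config(seed = s))
    dec <- tr$pft %in% c("DT", "DS"); ev <- tr$pft %in% c("ET", "ES")
    expect_gt(median(tr$SLA[dec]), median(tr$SLA[ev]))
    expect_gt(median(tr$N_mass[dec]), median(tr$N_mass[ev]))
    expect_lt(median(tr$toughness[dec]), median(tr$toughness[ev]))
    expect_lt(median(tr$CN[dec]), median(tr$CN[ev]))
    expect_gt(median(tr$Si[tr$pft == "GG"]), 3 * median(tr$Si[tr$pft != "GG"]))
    expect_lt(median(tr$lignin[tr$pft == "GG"]), median(tr$lignin[tr$pft != "GG"]))
  }
})

test_that("zero trait separation rejects at about the nominal alpha rate", {
  rej <- 0
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = 20000 + s, trait_separation = 0)
    tr <- simulate_leaf_traits(cfg)
    p <- anova_oneway(log(tr$SLA), tr$pft)$p
    rej <- rej + (p < 0.05)
  }
  # binomial(200, 0.05): 10 expected, central 99.9% range roughly [1, 21]
  expect_gte(rej, 1)
  expect_lte(rej, 22)
})

test_that("default synthetic traits cluster into the three trait syndromes", {
  agree <- numeric(50); kstar3 <- 0
  for (s in 1:50) {
    tr <- simulate_leaf_traits(sim_config(seed = 100 + s))
    lt <- log_transform_traits(tr)
    km <- kmeans_elbow(lt[setdiff(names(lt), c("species", "pft"))],
                       seed = s, labels = tr$pft)
    kstar3 <- kstar3 + (!is.na(km$k_star) && km$k_star == 3)
    agree[s] <- cluster_agreement(km$fits$K3$cluster, merged_pft(tr$pft))
  }
  expect_gte(kstar3, 45)
  expect_gte(mean(agree), 0.9)
})

test_that("trait_group_tests runs all six traits and flags PFT differences", {
  tr <- simulate_leaf_traits(sim_config(seed = 4))
  tg <- trait_group_tests(tr)
  expect_equal(nrow(tg$anova), 6)
  expect_equal(tg$anova$df_between, rep(4, 6))
  expect_equal(tg$anova$df_within, rep(27, 6))  # 32 species, 5 groups
  expect_true(all(tg$anova$p < 0.01))
  expect_setequal(names(tg$tukey), c("SLA", "toughness", "N_mass", "CN",
                                     "lignin", "Si"))
})
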