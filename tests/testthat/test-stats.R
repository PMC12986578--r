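test_that("identical groups give F = 0, p = 1", {
  tab <- make_feature_table(list(a = 0, b = 0), n_per_group = 3, sd = 0)
  tab$value <- rep(c(1, 2, 3), 2)
  res <- anova_tukey(tab, "f_median", "stft80", "derecruitment")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$gate_passed)
  expect_equal(nrow(res$pairwise), 1L)
})

test_that("two-group ANOVA reduces to the squared t statistic", {
  set.seed(42)
  tab <- make_feature_table(list(a = 0, b = 0.8), n_per_group = 15)
  res <- anova_tukey(tab, "f_median", "stft80", "derecruitment")
  tt <- t.test(value ~ group, data = tab, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("Tukey-Kramer with equal n matches the classic HSD oracle", {
  set.seed(7)
  tab <- make_feature_table(list(a = 0, b = 1, c = 2), n_per_group = 10)
  res <- anova_tukey(tab, "f_median", "stft80", "derecruitment")
  # classic HSD by hand: q = |diff| / sqrt(MSE / n), df = N - k
  fit <- stats::aov(value ~ group, data = tab)
  mse <- summary(fit)[[1]][["Mean Sq"]][2]
  means <- tapply(tab$value, tab$group, mean)
  for (r in seq_len(nrow(res$pairwise))) {
    g1 <- res$pairwise$group1[r]; g2 <- res$pairwise$group2[r]
    q <- abs(means[g2] - means[g1]) / sqrt(mse / 10)
    p_hsd <- stats::ptukey(q, 3, 27, lower.tail = FALSE)
    expect_equal(res$pairwise$p_value[r], unname(p_hsd), tolerance = 1e-6)
  }
})

test_that("groups with fewer than 2 observations are dropped with warning", {
  tab <- make_feature_table(list(a = 0, b = 1), n_per_group = 5)
  tab <- rbind(tab, data.frame(subject = "c", group = "c", burst_id = 1L,
                               phase = "derecruitment", source = "stft80",
                               metric = "f_median", value = 3))
  expect_warning(res <- anova_tukey(tab, "f_median", "stft80", "derecruitment"),
                 "dropping")
  expect_equal(nrow(res$pairwise), 1L)
  tab1 <- make_feature_table(list(a = 0), n_per_group = 5)
  expect_error(anova_tukey(tab1, "f_median", "stft80", "derecruitment"),
               "2 groups")
})

test_that("MANOVA detects large effects and is exact under label permutation", {
  # identical rows relabeled: Wilks' Lambda = 1, p = 1
  base <- data.frame(subject = "s", burst_id = 1:6,
                     phase = "sustained", source = "imf2",
                     stringsAsFactors = FALSE)
  vals_f <- c(1, 2, 3, 1, 2, 3)
  vals_e <- c(4, 6, 5, 4, 6, 5)
  tab <- rbind(
    cbind(base, group = rep(c("a", "b"), each = 3), metric = "inst_freq_mean",
          value = vals_f),
    cbind(base, group = rep(c("a", "b"), each = 3), metric = "inst_energy_mean",
          value = vals_e)
  )
  tab$burst_id <- rep(1:6, 2)
  res <- manova_pairs(tab, "imf2", "sustained")
  expect_equal(res$statistic, 1, tolerance = 1e-9)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
  # two groups separated by 5 pooled SDs on both variables, n = 50
  set.seed(11)
  mk <- function(g, mu) rbind(
    data.frame(subject = g, group = g, burst_id = 1:50, phase = "sustained",
               source = "imf2", metric = "inst_freq_mean",
               value = rnorm(50, mu, 1)),
    data.frame(subject = g, group = g, burst_id = 1:50, phase = "sustained",
               source = "imf2", metric = "inst_energy_mean",
               value = rnorm(50, mu, 1))
  )
  tab2 <- rbind(mk("a", 0), mk("b", 5))
  res2 <- manova_pairs(tab2, "imf2", "sustained")
  expect_lt(res2$p_value, 1e-3)
})

test_that("a degenerate metric raises a named singular-covariance error", {
  tab <- rbind(
    make_feature_table(list(a = 1, b = 2), n_per_group = 5, sd = 0,
                       metric = "inst_freq_mean", source = "imf2",
                       phase = "sustained"),
    make_feature_table(list(a = 1, b = 2), n_per_group = 5, sd = 1,
                       metric = "inst_energy_mean", source = "imf2",
                       phase = "sustained")
  )
  expect_error(manova_pairs(tab, "imf2", "sustained"), "freq")
})

test_that("Holm adjustment follows the step-down formula", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(holm_adjust(c(0.5, NA)), "0, 1")
})

test_that("Holm dominates raw p-values and is dominated by Bonferroni", {
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(length(p) * p, 1)))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm]), adj[perm])
  }
})

test_that("the battery analyses spectral sources and gates IMF post hocs", {
  set.seed(5)
  groups <- list(control = 300, week3 = 280, week6 = 220)
  tab <- do.call(rbind, lapply(c("stft80", "cwt"), function(src)
    do.call(rbind, lapply(c("recruitment", "sustained", "derecruitment"),
                          function(ph) rbind(
      make_feature_table(groups, 15, 10, "f_median", src, ph, seed = 5),
      make_feature_table(groups, 15, 10, "f_mean", src, ph, seed = 6)
    )))))
  out <- run_stat_battery(tab)
  # no imf sources -> only spectral ANOVAs, no Holm family
  expect_null(out$anova_family)
  expect_true(all(grepl("^(stft80|cwt)", names(out$results))))
  # 3 groups -> 3 pairwise rows per source x metric x phase
  expect_equal(nrow(out$pairwise), 2 * 2 * 3 * 3)
  # a null IMF source: MANOVA gate closed -> no post hoc rows
  null_imf <- rbind(
    make_feature_table(list(a = 0, b = 0), 20, 1, "inst_freq_mean", "imf2",
                       "sustained", seed = 7),
    make_feature_table(list(a = 0, b = 0), 20, 1, "inst_energy_mean", "imf2",
                       "sustained", seed = 8)
  )
  out2 <- run_stat_battery(null_imf)
  expect_false(is.null(out2$anova_family))
  expect_true(all(out2$anova_family$p_adj >= out2$anova_family$p_raw))
  expect_equal(nrow(out2$pairwise), 0L)
})

test_that("five groups produce the ten pairwise contrasts per cell", {
  set.seed(9)
  groups <- list(control = 340, week3 = 320, week4 = 300, week5 = 295,
                 week6 = 250)
  tab <- make_feature_table(groups, 25, 12)
  res <- anova_tukey(tab, "f_median", "stft80", "derecruitment")
  expect_equal(nrow(res$pairwise), 10L)
  expect_equal(nrow(unique(res$pairwise[, c("group1", "group2")])), 10L)
})

test_that("subject-level aggregation collapses bursts before testing", {
  set.seed(13)
  tab <- make_feature_table(list(a = 0, b = 2), n_per_group = 30)
  tab$subject <- paste0(tab$group, rep(1:3, each = 10))
  out <- run_stat_battery(tab, unit = "subject")
  key <- "stft80.f_median.derecruitment"
  expect_equal(unname(out$results[[key]]$df[2]), 4)  # 6 subjects - 2 groups
})
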