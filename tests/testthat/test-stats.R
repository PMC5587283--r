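test_that("holm-sidak reproduces the closed-form step-down adjustment", {
  expect_equal(holm_sidak(c(0.01, 0.02, 0.04)),
               c(0.029701, 0.039600, 0.040000), tolerance = 1e-9)
  expect_equal(holm_sidak(0.04), 0.04)              # m = 1: unadjusted
  expect_equal(holm_sidak(c(0, 0, 0)), c(0, 0, 0))
  # input order is preserved
  expect_equal(holm_sidak(c(0.04, 0.01, 0.02)),
               c(0.040000, 0.029701, 0.039600), tolerance = 1e-9)
  expect_error(holm_sidak(c(0.5, 1.2)), class = "dmq_domain_error")
  expect_error(holm_sidak(c(0.1, 0.2), m = 1), class = "dmq_domain_error")
})

test_that("holm-sidak adjusted p-values obey the procedure's inequalities", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      p <- stats::runif(sample(2:12, 1))
      adj <- holm_sidak(p)
      expect_true(all(adj >= p - 1e-12))
      expect_true(all(adj <= 1))
      # monotone in the sorted order
      expect_true(all(diff(adj[order(p)]) >= -1e-12))
      # smallest p gets the single-step Sidak adjustment
      i <- which.min(p)
      expect_equal(adj[i], min(1, 1 - (1 - p[i])^length(p)), tolerance = 1e-12)
      # never exceeds Holm-Bonferroni
      expect_true(all(adj <= stats::p.adjust(p, "holm") + 1e-12))
      # permutation invariance
      perm <- sample(length(p))
      expect_equal(holm_sidak(p[perm]), adj[perm])
    }
  })
})

test_that("group summaries are exact sample moments", {
  tab <- tibble::tibble(
    genotype = "mdx", age_months = 3L, region = "dorsal", image_id = "i",
    metric = rep(c("a", "b"), c(3, 3)),
    value = c(2, 2, 2, 1, 2, 3))
  s <- group_summary(tab)
  expect_equal(s$mean[s$metric == "a"], 2)
  expect_equal(s$sd[s$metric == "a"], 0)
  expect_equal(s$mean[s$metric == "b"], 2)
  expect_equal(s$sd[s$metric == "b"], 1)
  expect_equal(s$n, c(3L, 3L))
  tab$value[1] <- NA
  expect_warning(group_summary(tab), "non-finite")
})

test_that("compare_all runs the declared family and flags nothing for identical groups", {
  withr::with_seed(8, {
    tab <- null_metric_table(n_per_group = 8)
  })
  cmp <- compare_all(tab)
  # 18 choose 2 pairwise + pooled genotype contrast
  expect_equal(nrow(cmp), 153 + 1)
  expect_true(all(cmp$adjusted_p >= cmp$raw_p - 1e-12, na.rm = TRUE))

  # duplicated group values: t = 0, p = 1, not significant
  v <- c(1.2, 1.9, 2.5, 3.1)
  tab2 <- tibble::tibble(
    genotype = rep(c("control", "mdx"), each = 4),
    age_months = 3L, region = "dorsal", image_id = letters[1:8],
    metric = "m", value = c(v, v))
  cmp2 <- compare_all(tab2)
  expect_equal(cmp2$raw_p, rep(1, nrow(cmp2)))
  expect_false(any(cmp2$significant))

  # n < 2 groups are skipped with a message, the rest of the family survives
  tab3 <- rbind(tab2, tibble::tibble(
    genotype = "mdx", age_months = 3L, region = "ventral", image_id = "z",
    metric = "m", value = 9))
  expect_message(cmp3 <- compare_all(tab3), "n < 2")
  expect_equal(nrow(cmp3), 2)   # one surviving pair + pooled contrast
})

test_that("comparisons are invariant to row shuffling", {
  withr::with_seed(9, {
    tab <- null_metric_table(n_per_group = 5)
    shuf <- tab[sample(nrow(tab)), ]
  })
  a <- compare_all(tab)
  b <- compare_all(shuf)
  key <- function(x) x[order(x$group_a, x$group_b), ]
  expect_equal(key(a)$raw_p, key(b)$raw_p)
  expect_equal(key(a)$adjusted_p, key(b)$adjusted_p)
})

test_that("percent difference and regional spread match direct arithmetic", {
  expect_equal(round(percent_difference(519.81, 210.17)), 147)
  expect_equal(percent_difference(3, 2), 50)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(3, 0), class = "dmq_domain_error")
  expect_error(percent_difference(3, -1), class = "dmq_domain_error")

  expect_equal(regional_spread(c(100, 150, 120)), 50)
  expect_equal(regional_spread(c(7, 7, 7)), 0)
  expect_error(regional_spread(c(100, NA, 120)), class = "dmq_domain_error")

  # table interface with known cell means
  tab <- tibble::tibble(
    genotype = "mdx", age_months = 3L,
    region = rep(c("dorsal", "midcostal", "ventral"), each = 2),
    image_id = letters[1:6], metric = "macrophage_density_per_mm2",
    value = c(250, 262.16, 500, 539.62, 200, 220.34))
  spread <- regional_spread(tab, "macrophage_density_per_mm2", "mdx", 3)
  expect_equal(spread, percent_difference(519.81, 210.17), tolerance = 1e-9)
  expect_error(regional_spread(tab[tab$region != "ventral", ],
                               "macrophage_density_per_mm2", "mdx", 3),
               class = "dmq_domain_error")
})
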