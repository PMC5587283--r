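test_that("cohort sampling is deterministic and honors degenerate SDs", {
  pars <- default_group_parameters()
  spec <- cohort_spec(pars, n_per_group = 4, seed = 21)
  t1 <- sample_cohort(spec)
  t2 <- sample_cohort(spec)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 108 * 4)
  expect_true(all(t1$value >= 0))

  pars0 <- pars; pars0$sd <- 0
  t0 <- sample_cohort(cohort_spec(pars0, n_per_group = 3, seed = 1))
  joined <- dplyr::left_join(t0, pars0,
                             by = c("genotype", "age_months", "region", "metric"))
  expect_equal(joined$value, joined$mean)
})

test_that("cohort configuration errors are caught", {
  pars <- default_group_parameters()
  expect_error(cohort_spec(pars[-1, ]), class = "dmq_config_error")
  bad <- pars; bad$sd[3] <- -1
  expect_error(cohort_spec(bad), class = "dmq_config_error")
})

test_that("sample means converge to group means at the expected rate", {
  # mdx pooled sarcomere 2.53 +/- 0.19: at n = 10000, mean within 0.006
  pars <- pooled_group_parameters()
  one <- pars[pars$genotype == "mdx" & pars$metric == "sarcomere_length_um" &
                pars$age_months == 3 & pars$region == "dorsal", ]
  allcells <- dplyr::bind_rows(lapply(seq_len(nrow(grid_df <- expand.grid(
    genotype = c("control", "mdx"), age_months = c(3L, 7L, 10L),
    region = c("dorsal", "midcostal", "ventral"), stringsAsFactors = FALSE))),
    function(i) {
      tibble::tibble(genotype = grid_df$genotype[i],
                     age_months = grid_df$age_months[i],
                     region = grid_df$region[i],
                     metric = "sarcomere_length_um",
                     mean = ifelse(grid_df$genotype[i] == "mdx", 2.53, 2.70),
                     sd = ifelse(grid_df$genotype[i] == "mdx", 0.19, 0.35))
    }))
  tab <- sample_cohort(cohort_spec(allcells, n_per_group = 10000, seed = 7))
  cell <- tab$value[tab$genotype == "mdx" & tab$age_months == 3 &
                      tab$region == "dorsal"]
  expect_equal(length(cell), 10000)
  expect_lte(abs(mean(cell) - 2.53), 0.006)
})

test_that("regional CSA ordering of 10-month controls survives sampling", {
  tab <- sample_cohort(cohort_spec(default_group_parameters(),
                                   n_per_group = 1000, seed = 3))
  csa <- tab[tab$metric == "csa_um2" & tab$genotype == "control" &
               tab$age_months == 10, ]
  m <- tapply(csa$value, csa$region, mean)
  expect_lt(m[["dorsal"]], m[["midcostal"]])
  expect_lt(m[["midcostal"]], m[["ventral"]])
})

test_that("truncated-normal moments helper matches brute-force simulation", {
  for (case in list(c(1.03, 5.11), c(14.83, 8.97), c(2.53, 0.19))) {
    an <- truncnorm0_moments(case[1], case[2])
    sim <- withr::with_seed(99, {
      x <- stats::rnorm(4e5, case[1], case[2])
      x[x >= 0]
    })
    expect_lt(abs(an$mean - mean(sim)), 4 * stats::sd(sim) / sqrt(length(sim)))
    expect_lt(abs(an$sd - stats::sd(sim)) / an$sd, 0.02)
  }
})
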