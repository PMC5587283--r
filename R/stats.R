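#' Per-group summary statistics
#'
#' Sample mean, sample SD (n-1 denominator) and n per genotype x age x
#' region cell and metric — the mean +/- SD panels of a cohort report.
#'
#' @param table A metric-table tibble (`genotype`, `age_months`, `region`,
#'   `metric`, `value`).
#' @return A tibble: grouping columns plus `n`, `mean`, `sd`.
#' @export
group_summary <- function(table) {
  stopifnot(is.data.frame(table))
  if (!all(c("genotype", "age_months", "region", "metric", "value") %in% names(table))) {
    stop_dmq("dmq_config_error", "not a metric table")
  }
  bad <- !is.finite(table$value)
  if (any(bad)) {
    warning(sprintf("dropping %d non-finite values", sum(bad)))
    table <- table[!bad, ]
  }
  dplyr::summarise(
    dplyr::group_by(table, .data$metric, .data$genotype, .data$age_months, .data$region),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    .groups = "drop"
  )
}

#' Holm-Sidak step-down adjusted p-values
#'
#' The step-down Sidak procedure: sort the m raw p-values ascending; the
#' i-th sorted value is adjusted to `1 - (1 - p_(i))^(m - i + 1)`, then
#' running maxima enforce monotonicity and values are clipped at 1.
#' Controls the family-wise error rate at the nominal level while being
#' uniformly more powerful than Holm-Bonferroni.
#'
#' @param p Raw p-values in `[0, 1]` (any order).
#' @param m Family size; defaults to `length(p)`. May exceed `length(p)`
#'   when some family members were skipped upstream.
#' @return Adjusted p-values in the input order.
#' @export
holm_sidak <- function(p, m = length(p)) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop_dmq("dmq_domain_error", "p-values must lie in [0, 1]")
  }
  if (m < length(p)) {
    stop_dmq("dmq_domain_error", "family size m cannot be smaller than length(p)")
  }
  ord <- order(p)
  ps <- p[ord]
  k <- m - seq_along(ps) + 1
  adj <- pmin(1, 1 - (1 - ps)^k)
  adj <- cummax(adj)
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

group_id <- function(genotype, age_months, region) {
  paste(genotype, paste0(age_months, "mo"), region, sep = ":")
}

#' All pairwise group comparisons with Holm-Sidak correction
#'
#' For each metric, runs a two-sample t test (Welch by default) for every
#' pair of genotype x age x region groups plus the pooled mdx-vs-control
#' genotype contrast, then adjusts the whole per-metric family with
#' [holm_sidak()]. Groups with fewer than 2 observations are skipped (with
#' a message) and do not enter the family.
#'
#' @param table A metric-table tibble.
#' @param alpha Significance level applied to adjusted p-values.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @param include_pooled Include the pooled genotype contrast per metric.
#' @return A tibble: `metric`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `raw_p`, `adjusted_p`, `significant`.
#' @export
compare_all <- function(table, alpha = 0.05, var_equal = FALSE,
                        include_pooled = TRUE) {
  stopifnot(is.data.frame(table))
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  metrics <- unique(table$metric)
  res <- list()
  for (met in metrics) {
    tm <- table[table$metric == met, ]
    gid <- group_id(tm$genotype, tm$age_months, tm$region)
    values <- split(tm$value, gid)
    ns <- vapply(values, length, integer(1))
    small <- names(values)[ns < 2L]
    if (length(small)) {
      message(sprintf("metric '%s': skipping groups with n < 2: %s",
                      met, paste(small, collapse = ", ")))
      values <- values[ns >= 2L]
    }
    gids <- names(values)
    ga <- gb <- character(0)
    na_ <- nb_ <- integer(0)
    ma <- mb <- pp <- numeric(0)
    if (length(gids) >= 2L) {
      for (i in seq_len(length(gids) - 1L)) for (j in (i + 1L):length(gids)) {
        a <- values[[i]]; b <- values[[j]]
        ga <- c(ga, gids[i]); gb <- c(gb, gids[j])
        na_ <- c(na_, length(a)); nb_ <- c(nb_, length(b))
        ma <- c(ma, mean(a)); mb <- c(mb, mean(b))
        pp <- c(pp, tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
                             error = function(e) NA_real_))
      }
    }
    if (include_pooled) {
      a <- tm$value[tm$genotype == "mdx"]
      b <- tm$value[tm$genotype == "control"]
      if (length(a) >= 2L && length(b) >= 2L) {
        ga <- c(ga, "mdx:pooled"); gb <- c(gb, "control:pooled")
        na_ <- c(na_, length(a)); nb_ <- c(nb_, length(b))
        ma <- c(ma, mean(a)); mb <- c(mb, mean(b))
        pp <- c(pp, tryCatch(stats::t.test(a, b, var.equal = var_equal)$p.value,
                             error = function(e) NA_real_))
      }
    }
    if (!length(pp)) next
    fam <- tibble::tibble(metric = met, group_a = ga, group_b = gb,
                          n_a = na_, n_b = nb_, mean_a = ma, mean_b = mb,
                          raw_p = pp)
    ok <- !is.na(fam$raw_p)
    fam$adjusted_p <- NA_real_
    fam$adjusted_p[ok] <- holm_sidak(fam$raw_p[ok], m = sum(ok))
    fam$significant <- !is.na(fam$adjusted_p) & fam$adjusted_p < alpha
    res[[length(res) + 1L]] <- fam
  }
  if (!length(res)) {
    stop_dmq("dmq_config_error", "no comparable groups in table")
  }
  dplyr::bind_rows(res)
}

#' Percent difference between two group means
#'
#' `100 * (a - b) / b`: the increase of `a` relative to reference `b`.
#'
#' @param a,b Group means; `b` must be positive.
#' @return Percent (scalar).
#' @export
percent_difference <- function(a, b) {
  assert_scalar_number(a, "a")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop_dmq("dmq_domain_error", "reference mean b must be positive")
  }
  100 * (a - b) / b
}

#' Maximum regional spread of a metric, as a percent difference
#'
#' The largest pairwise percent difference among the three regional means
#' (dorsal, midcostal, ventral) for one genotype and age — always the
#' largest regional mean relative to the smallest.
#'
#' @param x Either a metric-table tibble (then `metric`, `genotype`, `age`
#'   select the cell means) or a numeric vector of three regional means.
#' @param metric,genotype,age Selectors used when `x` is a table.
#' @return Percent (scalar).
#' @export
regional_spread <- function(x, metric = NULL, genotype = NULL, age = NULL) {
  if (is.numeric(x)) {
    means <- x
  } else {
    stopifnot(is.data.frame(x))
    tm <- x[x$metric == metric & x$genotype == genotype & x$age_months == age, ]
    sm <- dplyr::summarise(dplyr::group_by(tm, .data$region),
                           mean = mean(.data$value), .groups = "drop")
    means <- sm$mean[match(.REGIONS, sm$region)]
  }
  if (length(means) != 3L || any(!is.finite(means))) {
    stop_dmq("dmq_domain_error", "all three regional means are required")
  }
  best <- 0
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    if (means[i] > means[j]) {
      best <- max(best, percent_difference(means[i], means[j]))
    }
  }
  best
}
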