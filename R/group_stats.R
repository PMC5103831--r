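# Metabolite-style grouped statistics: one-way ANOVA per analyte,
# Benjamini-Hochberg FDR across analytes, and Tukey-Kramer HSD post-hoc
# pairwise comparisons within each analyte.

check_groups <- function(value, group) {
  if (length(value) != length(group))
    abort("`value` and `group` must have equal length.")
  n <- table(group)
  if (length(n) < 2) abort("need at least 2 groups.")
  if (any(n < 2)) abort("every group needs at least 2 replicates.")
  invisible(NULL)
}

#' One-way ANOVA for a single analyte
#'
#' Standard between/within decomposition fitted with `lm()`. Degenerate
#' inputs are resolved explicitly: when both between- and within-group sums
#' of squares are zero (all values identical) F is defined as 0 with p = 1;
#' when the within-group variance is zero but groups differ, p is reported
#' as 0 with `degenerate = TRUE`.
#'
#' @param data Data frame with the measurement and grouping columns.
#' @param value,group Column names (tidy-eval) of the measurement and the
#'   group label; defaults `value` and `group`.
#' @return One-row tibble: `f_statistic`, `p_value`, `df_between`,
#'   `df_within`, `ss_between`, `ss_within`, `ms_within`, `degenerate`.
#' @examples
#' d <- tibble::tibble(group = rep(c("a", "b", "c"), each = 3),
#'                     value = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
#' one_way_anova(d)$f_statistic  # 3
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  v <- data[[value]]
  g <- factor(data[[group]])
  check_groups(v, g)
  # degenerate fits are handled by the explicit conventions below; silence
  # anova.lm's perfect-fit warning
  tab <- suppressWarnings(stats::anova(stats::lm(v ~ g)))
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  dfb <- tab$Df[1]; dfw <- tab$Df[2]
  if (ssw <= .Machine$double.eps * max(1, ssb)) {
    if (ssb <= .Machine$double.eps) {
      return(tibble(f_statistic = 0, p_value = 1, df_between = dfb,
                    df_within = dfw, ss_between = 0, ss_within = 0,
                    ms_within = 0, degenerate = TRUE))
    }
    return(tibble(f_statistic = Inf, p_value = 0, df_between = dfb,
                  df_within = dfw, ss_between = ssb, ss_within = 0,
                  ms_within = 0, degenerate = TRUE))
  }
  tibble(
    f_statistic = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
    df_between = dfb, df_within = dfw,
    ss_between = ssb, ss_within = ssw, ms_within = ssw / dfw,
    degenerate = FALSE
  )
}

#' One-way ANOVA across many analytes with BH correction
#'
#' Computes the one-way decomposition for every analyte with vectorized
#' grouped sums (algebraically identical to [one_way_anova()], which is the
#' cross-check route, but fast for thousands of analytes) and adjusts the
#' p-values across analytes with the Benjamini-Hochberg step-up procedure.
#'
#' @param data Long data frame with columns `analyte`, `group`, `value`
#'   (names configurable).
#' @param analyte,value,group Column names.
#' @return Tibble with one row per analyte: the [one_way_anova()] columns
#'   plus `q_value` (BH-adjusted across analytes).
#' @export
anova_table <- function(data, analyte = "analyte", value = "value",
                        group = "group") {
  d <- tibble(
    analyte = data[[analyte]], group = data[[group]], value = data[[value]]
  )
  counts <- d |> dplyr::count(.data$analyte, .data$group)
  if (any(counts$n < 2) ||
      any(dplyr::count(counts, .data$analyte)$n < 2))
    abort("every analyte needs >= 2 groups with >= 2 replicates each.")

  res <- d |>
    dplyr::group_by(.data$analyte, .data$group) |>
    dplyr::summarise(n = dplyr::n(), s = sum(.data$value),
                     ss = sum(.data$value^2), .groups = "drop_last") |>
    dplyr::summarise(
      k = dplyr::n(), n_tot = sum(.data$n),
      ss_between = sum(.data$s^2 / .data$n) - sum(.data$s)^2 / sum(.data$n),
      ss_within = sum(.data$ss) - sum(.data$s^2 / .data$n),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ss_between = pmax(.data$ss_between, 0),
      ss_within = pmax(.data$ss_within, 0),
      df_between = .data$k - 1L,
      df_within = .data$n_tot - .data$k,
      ms_within = .data$ss_within / .data$df_within,
      f_statistic = (.data$ss_between / .data$df_between) / .data$ms_within,
      p_value = stats::pf(.data$f_statistic, .data$df_between,
                          .data$df_within, lower.tail = FALSE),
      degenerate = .data$ss_within <= .Machine$double.eps *
        pmax(1, .data$ss_between)
    )
  # explicit degenerate-variance conventions
  zero_both <- res$degenerate & res$ss_between <= .Machine$double.eps
  res$f_statistic[zero_both] <- 0
  res$p_value[zero_both] <- 1
  zero_within <- res$degenerate & !zero_both
  res$f_statistic[zero_within] <- Inf
  res$p_value[zero_within] <- 0

  res |>
    dplyr::mutate(q_value = bh_adjust(.data$p_value)) |>
    dplyr::select("analyte", "f_statistic", "p_value", "q_value",
                  "df_between", "df_within", "ms_within", "degenerate")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: q_(i) = min over j >= i of p_(j) * m / j, clipped at
#' 1, returned in the input order. Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    abort("all p-values must lie in [0, 1].")
  stats::p.adjust(p, method = "BH")
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs post-hoc comparison in the Tukey-Kramer form for (possibly)
#' unequal group sizes: q = |mean_i - mean_j| / sqrt(MSW * (1/n_i + 1/n_j)
#' / 2), with the adjusted p-value from the studentized range distribution
#' with k groups and the ANOVA within-group degrees of freedom. When the
#' within-group mean square is zero the comparisons are flagged degenerate
#' and no p-value is reported.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return Tibble with k(k-1)/2 rows: `group1`, `group2`, `difference`,
#'   `q_statistic`, `p_adjusted`, `significant`, `degenerate`.
#' @export
tukey_hsd <- function(data, value = "value", group = "group", alpha = 0.05) {
  v <- data[[value]]
  g <- factor(data[[group]])
  check_groups(v, g)
  an <- one_way_anova(data, value, group)
  msw <- an$ms_within
  dfw <- an$df_within
  means <- tapply(v, g, mean)
  ns <- tapply(v, g, length)
  k <- nlevels(g)
  pairs <- utils::combn(levels(g), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    diff <- means[[g2]] - means[[g1]]
    if (msw <= 0) {
      return(tibble(group1 = g1, group2 = g2, difference = diff,
                    q_statistic = NA_real_, p_adjusted = NA_real_,
                    significant = NA, degenerate = TRUE))
    }
    q <- abs(diff) / sqrt(msw * (1 / ns[[g1]] + 1 / ns[[g2]]) / 2)
    p <- stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
    tibble(group1 = g1, group2 = g2, difference = diff, q_statistic = q,
           p_adjusted = p, significant = p < alpha, degenerate = FALSE)
  })
  out
}

#' Tukey HSD for every analyte of a long table
#'
#' Applies [tukey_hsd()] per analyte. Pairwise p-values are already adjusted
#' within each analyte by the studentized range distribution; no additional
#' cross-analyte correction is applied.
#'
#' @inheritParams anova_table
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `analyte` + the [tukey_hsd()] columns.
#' @export
tukey_table <- function(data, analyte = "analyte", value = "value",
                        group = "group", alpha = 0.05) {
  d <- tibble(
    analyte = data[[analyte]], group = data[[group]], value = data[[value]]
  )
  d |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(~ tukey_hsd(.x, alpha = alpha)) |>
    dplyr::ungroup()
}
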