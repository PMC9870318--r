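#' Two-way fixed-effects ANOVA (type x step)
#'
#' Fits `value ~ A * B` with sum-to-zero contrasts and Type-III sums of
#' squares, the convention of common GraphPad-style analyses of unbalanced
#' cell counts (neuron types have unequal n). Both factors are treated as
#' categorical; no repeated factors.
#'
#' @param data Long-format data frame.
#' @param value,factor_a,factor_b Column names (tidy-eval) of the response
#'   and the two factors.
#' @return An `ephys_anova` object; [tidy()] gives one row per effect with
#'   `term`, `sumsq`, `df`, `df_resid`, `statistic` (F), `p.value`.
#' @examples
#' d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:5)
#' d$value <- rnorm(nrow(d))
#' tidy(two_way_anova(d, value, a, b))
#' @export
two_way_anova <- function(data, value, factor_a, factor_b) {
  v <- rlang::enquo(value); fa <- rlang::enquo(factor_a); fb <- rlang::enquo(factor_b)
  d <- tibble(value = dplyr::pull(data, !!v),
              A = factor(dplyr::pull(data, !!fa)),
              B = factor(dplyr::pull(data, !!fb)))
  d <- filter(d, !is.na(.data$value))
  if (nlevels(droplevels(d$A)) < 2 || nlevels(droplevels(d$B)) < 2)
    abort("both factors need at least 2 levels")
  d$A <- droplevels(d$A); d$B <- droplevels(d$B)
  cells <- count(d, .data$A, .data$B)
  grid <- tidyr::expand_grid(A = levels(d$A), B = levels(d$B))
  missing_cells <- dplyr::anti_join(grid, cells, by = c("A", "B"))
  if (nrow(missing_cells) > 0)
    abort(sprintf("empty design cell: %s x %s",
                  missing_cells$A[1], missing_cells$B[1]))
  small <- filter(cells, .data$n < 2)
  if (nrow(small) > 0)
    abort(sprintf("cell %s x %s has n = 1; ANOVA needs replication",
                  small$A[1], small$B[1]))

  fit <- lm(value ~ A * B, data = d,
            contrasts = list(A = "contr.sum", B = "contr.sum"))
  an <- car::Anova(fit, type = 3)
  rows <- c("A", "B", "A:B")
  lab <- c(rlang::as_name(fa), rlang::as_name(fb),
           paste0(rlang::as_name(fa), ":", rlang::as_name(fb)))
  df_res <- an["Residuals", "Df"]
  tab <- tibble(term = lab,
                sumsq = an[rows, "Sum Sq"],
                df = an[rows, "Df"],
                df_resid = df_res,
                statistic = an[rows, "F value"],
                p.value = an[rows, "Pr(>F)"])
  structure(list(table = tab, fit = fit, cells = cells,
                 type = "two-way (Type III)"),
            class = "ephys_anova")
}

#' One-way fixed-effects ANOVA
#'
#' @param data Data frame.
#' @param value,group Response and grouping columns (tidy-eval).
#' @return An `ephys_anova` object.
#' @export
one_way_anova <- function(data, value, group) {
  v <- rlang::enquo(value); g <- rlang::enquo(group)
  d <- tibble(value = dplyr::pull(data, !!v),
              g = factor(dplyr::pull(data, !!g)))
  d <- filter(d, !is.na(.data$value))
  d$g <- droplevels(d$g)
  if (nlevels(d$g) < 2) abort("`group` needs at least 2 levels")
  small <- count(d, .data$g) |> filter(.data$n < 2)
  if (nrow(small) > 0)
    abort(sprintf("group %s has n = 1; ANOVA needs replication", small$g[1]))
  fit <- aov(value ~ g, data = d)
  an <- summary(fit)[[1]]
  tab <- tibble(term = rlang::as_name(g),
                sumsq = an["g", "Sum Sq"],
                df = an["g", "Df"],
                df_resid = an["Residuals", "Df"],
                statistic = an["g", "F value"],
                p.value = an["g", "Pr(>F)"])
  structure(list(table = tab, fit = fit,
                 cells = count(d, .data$g), type = "one-way"),
            class = "ephys_anova")
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise group comparisons with studentized-range (Tukey HSD)
#' adjustment, as the post-hoc to a significant ANOVA.
#'
#' @inheritParams one_way_anova
#' @param conf.level Confidence level of the adjusted intervals.
#' @return An `ephys_tukey` object; [tidy()] gives `contrast`, `estimate`,
#'   `conf.low`, `conf.high`, `adj.p.value`.
#' @export
tukey_hsd <- function(data, value, group, conf.level = 0.95) {
  v <- rlang::enquo(value); g <- rlang::enquo(group)
  d <- tibble(value = dplyr::pull(data, !!v),
              g = factor(dplyr::pull(data, !!g)))
  d <- filter(d, !is.na(.data$value))
  d$g <- droplevels(d$g)
  fit <- aov(value ~ g, data = d)
  tk <- TukeyHSD(fit, conf.level = conf.level)$g
  tab <- tibble(contrast = rownames(tk),
                estimate = tk[, "diff"],
                conf.low = tk[, "lwr"],
                conf.high = tk[, "upr"],
                adj.p.value = tk[, "p adj"])
  structure(list(table = tab, conf.level = conf.level),
            class = "ephys_tukey")
}

#' Per-step Tukey families for two-way designs
#'
#' Runs a Tukey HSD across groups separately at each step level (the
#' post-hoc family is within each step, mirroring per-step multiple-
#' comparison panels).
#'
#' @inheritParams two_way_anova
#' @param step Step/level column (tidy-eval).
#' @return Tibble of tidy Tukey rows with a leading `step` column.
#' @export
tukey_by_step <- function(data, value, factor_a, step) {
  v <- rlang::enquo(value); fa <- rlang::enquo(factor_a); st <- rlang::enquo(step)
  d <- tibble(value = dplyr::pull(data, !!v),
              g = factor(dplyr::pull(data, !!fa)),
              step = dplyr::pull(data, !!st))
  d <- filter(d, !is.na(.data$value))
  purrr::map(split(d, d$step), function(ds) {
    if (nlevels(droplevels(ds$g)) < 2) return(NULL)
    mutate(tidy(tukey_hsd(ds, value, g)), step = ds$step[1], .before = 1)
  }) |>
    purrr::list_rbind()
}

#' Group summaries: mean, SEM, n
#'
#' @param data Data frame.
#' @param value Response column (tidy-eval).
#' @param ... Grouping columns (tidy-eval).
#' @return Tibble of `mean`, `sem`, `n` per group; `sem` is `NA` for single
#'   observations.
#' @export
summarize_groups <- function(data, value, ...) {
  data |>
    group_by(...) |>
    summarise(
      mean = mean({{ value }}, na.rm = TRUE),
      sem = {
        x <- {{ value }}
        x <- x[!is.na(x)]
        if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
      },
      n = sum(!is.na({{ value }})),
      .groups = "drop")
}

#' @export
print.ephys_anova <- function(x, ...) {
  cat(sprintf("<ephys_anova> %s\n", x$type))
  print(x$table)
  invisible(x)
}

#' @export
print.ephys_tukey <- function(x, ...) {
  cat(sprintf("<ephys_tukey> Tukey HSD (%.0f%% CI)\n", 100 * x$conf.level))
  print(x$table)
  invisible(x)
}
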