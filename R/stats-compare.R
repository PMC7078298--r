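#' Paired Wilcoxon signed-rank comparison
#'
#' Compares matched per-animal values (e.g. the lasered eye against the
#' contralateral eye of the same animal). The p-value is exact (full
#' enumeration of sign assignments) when there are no ties among the
#' absolute differences, no zero differences and n <= `exact_max`;
#' otherwise the normal approximation with tie correction is used and the
#' method field says so. If every difference is zero the comparison is
#' degenerate: p = 1 with `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors of equal length, matched elementwise.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return A `glia_test` object; see [tidy.glia_test()].
#' @export
compare_paired <- function(a, b, exact_max = 25) {
  if (length(a) != length(b)) abort("paired samples must have equal length")
  d <- a - b
  if (all(d == 0)) {
    return(new_glia_test("wilcoxon_paired", statistic = 0, p = 1,
                         n = c(length(a), length(b)), exact = TRUE,
                         degenerate = TRUE))
  }
  dn <- d[d != 0]
  use_exact <- length(dn) <= exact_max && !any(duplicated(abs(dn)))
  ht <- suppressWarnings(
    wilcox.test(a, b, paired = TRUE, exact = use_exact, correct = TRUE))
  new_glia_test("wilcoxon_paired", statistic = unname(ht$statistic),
                p = ht$p.value, n = c(length(a), length(b)),
                exact = use_exact, degenerate = FALSE,
                zeros_dropped = sum(d == 0))
}

#' Unpaired Mann-Whitney U comparison
#'
#' Compares independent samples (e.g. lasered or contralateral eyes
#' against naive animals). The statistic is the Mann-Whitney U of the
#' first sample. The p-value is exact (enumeration over all
#' arrangements) when there are no ties and both samples are small;
#' otherwise the tie-corrected normal approximation is used.
#'
#' @param a,b Numeric vectors (independent samples).
#' @param exact_max_total Use the exact distribution when
#'   `length(a) + length(b)` does not exceed this and there are no ties.
#' @return A `glia_test` object.
#' @export
compare_unpaired <- function(a, b, exact_max_total = 30) {
  if (length(a) == 0 || length(b) == 0) abort("empty group")
  use_exact <- (length(a) + length(b)) <= exact_max_total &&
    !any(duplicated(c(a, b)))
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE))
  new_glia_test("mann_whitney", statistic = unname(ht$statistic),
                p = ht$p.value, n = c(length(a), length(b)),
                exact = use_exact, degenerate = FALSE)
}

new_glia_test <- function(method, statistic, p, n, exact,
                          degenerate = FALSE, ...) {
  structure(list(method = method, statistic = statistic, p.value = p,
                 n1 = n[1], n2 = n[2], exact = exact,
                 degenerate = degenerate, ...),
            class = "glia_test")
}

#' @export
print.glia_test <- function(x, ...) {
  cat(sprintf("<glia_test> %s: statistic = %.4g, p = %.4g (%s)%s\n",
              x$method, x$statistic, x$p.value,
              if (x$exact) "exact" else "normal approximation",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Tidy a two-sample comparison
#'
#' @param x A `glia_test`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `statistic`, `p_value`, `n1`, `n2`,
#'   `exact`, `degenerate`.
#' @export
tidy.glia_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p.value,
         n1 = x$n1, n2 = x$n2, exact = x$exact, degenerate = x$degenerate)
}

#' One-way ANOVA with Bonferroni-corrected pairwise contrasts
#'
#' Fits a one-way ANOVA across k groups and reports every pairwise
#' contrast with pooled-SD t statistics; raw p-values are Bonferroni
#' adjusted as `min(1, m * p)` where `m` is the family size (by default
#' the number of pairwise contrasts). If the within-group variance is
#' zero and all group means are equal the fit is degenerate: F is
#' reported as `NA` with `degenerate = TRUE`.
#'
#' @param values Numeric response vector.
#' @param groups Factor (or coercible) of group labels, same length.
#' @param m Bonferroni family size; default `choose(k, 2)`.
#' @return A `glia_anova` list with elements `anova` (glance-style
#'   one-row tibble) and `pairwise` (tibble of contrasts); see
#'   [tidy.glia_anova()] and [glance.glia_anova()].
#' @export
anova_bonferroni <- function(values, groups, m = NULL) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) abort("ANOVA needs at least two groups")
  ns <- table(groups)
  if (any(ns < 2)) abort("every group needs n >= 2")
  if (is.null(m)) m <- choose(k, 2)
  degenerate <- isTRUE(all.equal(stats::var(values), 0)) ||
    stats::var(values) == 0
  if (degenerate) {
    an <- tibble(f_statistic = NA_real_, p_value = NA_real_,
                 df_between = k - 1L, df_within = length(values) - k,
                 degenerate = TRUE)
    pw <- tidyr::expand_grid(i = seq_len(k), j = seq_len(k)) |>
      dplyr::filter(.data$i < .data$j) |>
      dplyr::transmute(
        group1 = levels(groups)[.data$i], group2 = levels(groups)[.data$j],
        estimate = 0, p_raw = NA_real_, p_adjusted = NA_real_,
        m = m, significant = FALSE)
    return(structure(list(anova = an, pairwise = pw), class = "glia_anova"))
  }
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  raw <- suppressWarnings(
    pairwise.t.test(values, groups, p.adjust.method = "none",
                    pool.sd = TRUE))
  means <- tapply(values, groups, mean)
  lv <- levels(groups)
  pw <- tidyr::expand_grid(i = seq_along(lv), j = seq_along(lv)) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(
      group1 = lv[.data$i], group2 = lv[.data$j],
      estimate = unname(means[.data$j] - means[.data$i]),
      p_raw = purrr::map2_dbl(.data$i, .data$j,
                              ~ raw$p.value[lv[.y], lv[.x]])) |>
    dplyr::mutate(p_adjusted = pmin(1, m * .data$p_raw),
                  m = m,
                  significant = .data$p_adjusted < 0.05) |>
    dplyr::select("group1", "group2", "estimate", "p_raw",
                  "p_adjusted", "m", "significant")
  an <- tibble(
    f_statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
    df_between = s[["Df"]][1], df_within = s[["Df"]][2],
    degenerate = FALSE)
  structure(list(anova = an, pairwise = pw), class = "glia_anova")
}

#' @export
print.glia_anova <- function(x, ...) {
  if (isTRUE(x$anova$degenerate)) {
    cat("<glia_anova> degenerate (zero variance); no F statistic\n")
  } else {
    cat(sprintf("<glia_anova> F(%d, %d) = %.4g, p = %.4g\n",
                x$anova$df_between, x$anova$df_within,
                x$anova$f_statistic, x$anova$p_value))
  }
  print(x$pairwise)
  invisible(x)
}

#' @rdname anova_bonferroni
#' @param x A `glia_anova`.
#' @param ... Unused.
#' @export
tidy.glia_anova <- function(x, ...) x$pairwise

#' @rdname anova_bonferroni
#' @export
glance.glia_anova <- function(x, ...) x$anova

#' Retinal-zone homogeneity analysis
#'
#' Tests whether a measurement differs among the four retinal zones
#' (superior, inferior, nasal, temporal) of lasered eyes: a 4-group
#' one-way ANOVA with Bonferroni-corrected pairwise contrasts. Supports
#' restriction to a subset of fields (e.g. nearest the optic disc) via
#' prior filtering by the caller.
#'
#' @param records Tibble with columns `zone` and `value` (per-field or
#'   per-animal values).
#' @return A `glia_anova`, with the zone pairs as contrasts.
#' @export
zone_analysis <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("zone", "value") %in% names(records)))
  zones <- unique(records$zone)
  if (length(zones) < 2) abort("zone analysis needs at least two zones")
  ns <- table(records$zone)
  if (any(ns < 2)) abort("every zone needs n >= 2")
  anova_bonferroni(records$value, records$zone)
}
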