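# Statistical toolkit for trait tables: group comparisons, effect sizes,
# normality moments, correlation, broad-sense heritability, fold changes and
# linkage-map summaries.

#' Significance stars
#'
#' The reporting convention used throughout: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001.
#'
#' @param p p-value(s).
#' @return character vector of stars ("" when not significant).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Compare two groups (Welch or Mann-Whitney)
#'
#' `welch`: unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided. `mann_whitney`: the U statistic; for
#' `n1 + n2 <= 20` the two-sided p-value is computed by exact enumeration of
#' all group assignments of the pooled values (ties handled by enumeration),
#' otherwise by the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples (missing values dropped listwise).
#' @param test `"welch"` or `"mann_whitney"`.
#' @param exact_max largest `n1 + n2` for which the exact Mann-Whitney
#'   enumeration is used.
#' @return object of class `comparison_result` with the statistic, p-value,
#'   group locations and the star string.
#' @examples
#' compare_groups(1:5, 6:10, test = "mann_whitney")$p_value # 0.007937
#' @export
compare_groups <- function(x, y, test = c("welch", "mann_whitney"),
                           exact_max = 20L) {
  test <- match.arg(test)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (test == "welch") {
    if (n1 < 2L || n2 < 2L) {
      cf_stop("Welch's test needs n >= 2 per group", "cf_parameter_error")
    }
    v1 <- stats::var(x); v2 <- stats::var(y)
    if (v1 == 0 && v2 == 0) {
      cf_stop("both groups have zero variance", "cf_degenerate_error")
    }
    se2 <- v1 / n1 + v2 / n2
    stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(stat), df)
    res <- list(test = "welch", statistic = stat, df = df, p_value = p,
                location = c(mean_x = mean(x), mean_y = mean(y)))
  } else {
    if (n1 < 1L || n2 < 1L) {
      cf_stop("Mann-Whitney needs n >= 1 per group", "cf_parameter_error")
    }
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (n1 + n2 <= exact_max) {
      p <- mw_exact_p(c(x, y), n1, U)
    } else {
      mu <- n1 * n2 / 2
      tie_tab <- table(r)
      n <- n1 + n2
      sigma2 <- n1 * n2 / 12 *
        ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    res <- list(test = "mann_whitney", statistic = U, df = NA_real_,
                p_value = min(p, 1),
                location = c(median_x = stats::median(x),
                             median_y = stats::median(y)))
  }
  res$p_value <- min(res$p_value, 1)
  res$n <- c(n1 = n1, n2 = n2)
  res$stars <- significance_stars(res$p_value)
  class(res) <- "comparison_result"
  res
}

# Exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) group
# assignments of the pooled sample: symmetric-tail definition
# P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|).
mw_exact_p <- function(pooled, n1, U_obs) {
  n <- length(pooled)
  r <- rank(pooled)
  idx <- utils::combn(n, n1)
  Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  center <- n1 * (n - n1) / 2
  mean(abs(Us - center) >= abs(U_obs - center) - 1e-9)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.5g %s (n = %d/%d)\n",
              x$test, x$statistic, x$p_value, x$stars, x$n[1], x$n[2]))
  invisible(x)
}

#' Cohen's D effect size
#'
#' Pooled-sd standardized mean difference
#' `D = |mean(x) - mean(y)| / s_pooled`, with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`, and the
#' effect classes small (D > 0.2), medium (D > 0.5), strong (D > 0.8);
#' otherwise negligible.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @return object of class `effect_size` with `D` and `class`.
#' @examples
#' cohens_d(rnorm(100, 1), rnorm(100, 0))$class
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) {
    cf_stop("Cohen's D needs n >= 2 per group", "cf_parameter_error")
  }
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) cf_stop("pooled sd is zero", "cf_degenerate_error")
  D <- abs(mean(x) - mean(y)) / sp
  structure(list(D = D, class = classify_effect(D)), class = "effect_size")
}

#' Classify an effect size
#'
#' @param D Cohen's D value.
#' @return `"negligible"`, `"small"`, `"medium"` or `"strong"`.
#' @examples
#' classify_effect(0.69) # "medium"
#' @export
classify_effect <- function(D) {
  vapply(D, function(d) {
    if (d > 0.8) "strong" else if (d > 0.5) "medium"
    else if (d > 0.2) "small" else "negligible"
  }, character(1))
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's D = %.3f (%s)\n", x$D, x$class))
  invisible(x)
}

#' Moment-based normality check
#'
#' Pearson's moment coefficient of skewness `g1 = m3 / m2^(3/2)` and excess
#' kurtosis `g2 = m4 / m2^2 - 3`. The non-normality flag uses the
#' documented heuristic `|g1| > 1 or |g2| > 2` (no cutoffs are standard for
#' this check; these are deliberately permissive).
#'
#' @param x numeric sample, n >= 4.
#' @return list with `skewness`, `excess_kurtosis`, `non_normal` flag.
#' @export
normality_check <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) {
    cf_stop("normality check needs n >= 4", "cf_parameter_error")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) cf_stop("constant input", "cf_degenerate_error")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3
  list(skewness = g1, excess_kurtosis = g2,
       non_normal = abs(g1) > 1 || abs(g2) > 2)
}

#' Pearson correlation with p-value
#'
#' @param x,y numeric vectors (pairwise-complete, n >= 3, nonzero variance).
#' @return list with `r`, `p_value`, `n`, `stars`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) cf_stop("correlation needs n >= 3", "cf_parameter_error")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    cf_stop("zero variance input", "cf_degenerate_error")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, p_value = p, n = n, stars = significance_stars(p))
}

#' Broad-sense heritability (Mahmud-Kramer)
#'
#' `H2 = (V_F2 - sqrt(V_P1 * V_P2)) / V_F2`: the F2 phenotypic variance in
#' excess of the environmental variance estimated as the geometric mean of
#' the parental variances, as a fraction of the F2 variance. Clipped to
#' [0, 1] with a flag when clipping was needed.
#'
#' @param table a `trait_table` with P1, P2 and F2 generations (n >= 3 each).
#' @param trait trait column name; defaults to the single numeric column.
#' @return list with `H2`, the variance components and `clipped` flag.
#' @examples
#' tab <- generate_trait_table(
#'   trait_gen_model(100, 5, 90, 8, target_H2 = 0.6, n_f2 = 500, seed = 2))
#' heritability_h2(tab)$H2
#' @export
heritability_h2 <- function(table, trait = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(trait)) {
    num <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                   c("plant_id"))
    if (length(num) != 1L) {
      cf_stop("specify `trait`: table has several numeric columns",
              "cf_parameter_error")
    }
    trait <- num
  }
  v <- function(gen) {
    xs <- table[[trait]][table$generation == gen]
    xs <- xs[is.finite(xs)]
    if (length(xs) < 3L) {
      cf_stop(sprintf("generation %s needs n >= 3", gen), "cf_parameter_error")
    }
    stats::var(xs)
  }
  v_p1 <- v("P1"); v_p2 <- v("P2"); v_f2 <- v("F2")
  if (v_f2 == 0) cf_stop("F2 variance is zero", "cf_degenerate_error")
  v_e <- sqrt(v_p1 * v_p2)
  h2 <- (v_f2 - v_e) / v_f2
  clipped <- h2 < 0 || h2 > 1
  list(H2 = max(0, min(1, h2)), V_P1 = v_p1, V_P2 = v_p2, V_F2 = v_f2,
       V_E = v_e, clipped = clipped)
}

#' Fold change between two means
#'
#' @param mean_a,mean_b group means; `mean_b` must be nonzero.
#' @return list with `ratio` and the nearest-integer `fold`.
#' @examples
#' fold_change(13.7, 1.7) # ratio 8.06, fold 8
#' @export
fold_change <- function(mean_a, mean_b) {
  if (!is_scalar_number(mean_a) || !is_scalar_number(mean_b)) {
    cf_stop("means must be finite numbers", "cf_parameter_error")
  }
  if (mean_b == 0) cf_stop("division by zero mean", "cf_degenerate_error")
  ratio <- mean_a / mean_b
  list(ratio = ratio, fold = round(ratio))
}

#' One-way ANOVA utility
#'
#' Convenience wrapper (classic equal-variance one-way ANOVA) for loading
#' ratios across groups; provided for completeness, no reference value is
#' claimed for it.
#'
#' @param x numeric response.
#' @param group grouping vector.
#' @return list with `F`, `df`, `p_value`.
#' @export
one_way_anova <- function(x, group) {
  g <- factor(group)
  if (nlevels(g) < 2L) cf_stop("need >= 2 groups", "cf_parameter_error")
  fit <- stats::anova(stats::lm(x ~ g))
  list(F = fit$`F value`[1], df = c(fit$Df[1], fit$Df[2]),
       p_value = fit$`Pr(>F)`[1])
}

#' Summarize a linkage map
#'
#' Total length is the sum of per-chromosome spans (max - min position).
#' The default mean inter-marker distance is `total length / n_markers`
#' (the convention that reproduces a printed 783.8 cM / 1041 markers =
#' 0.75 cM); `per_gap = TRUE` uses the per-gap convention
#' `total / (n_markers - n_chromosomes)` instead.
#'
#' @param map data.frame with columns `marker_id`, `chromosome`,
#'   `position_cM`.
#' @param chromosomes allowed chromosome codes (default rye 1R..7R).
#' @param per_gap use the per-gap mean-distance convention.
#' @return object of class `map_summary` with `n_markers`,
#'   `n_chromosomes`, `total_length_cM`, `mean_distance_cM` (rounded to 2
#'   decimals in the print method only).
#' @export
summarize_linkage_map <- function(map, chromosomes = paste0(1:7, "R"),
                                  per_gap = FALSE) {
  need <- c("marker_id", "chromosome", "position_cM")
  if (!all(need %in% names(map))) {
    cf_stop(sprintf("map table needs columns: %s", paste(need, collapse = ", ")),
            "cf_validation_error")
  }
  bad <- setdiff(unique(map$chromosome), chromosomes)
  if (length(bad)) {
    cf_stop(sprintf("unknown chromosome code(s): %s", paste(bad, collapse = ", ")),
            "cf_validation_error")
  }
  if (any(!is.finite(map$position_cM)) || any(map$position_cM < 0)) {
    cf_stop("positions must be finite and >= 0", "cf_validation_error")
  }
  spans <- tapply(map$position_cM, map$chromosome,
                  function(p) max(p) - min(p))
  total <- sum(spans)
  n_m <- nrow(map)
  n_c <- length(unique(map$chromosome))
  denom <- if (per_gap) n_m - n_c else n_m
  structure(
    list(n_markers = n_m, n_chromosomes = n_c, total_length_cM = total,
         mean_distance_cM = if (denom > 0) total / denom else 0,
         per_gap = per_gap,
         spans_cM = spans),
    class = "map_summary"
  )
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf(
    "linkage map: %d markers on %d chromosomes, %.2f cM total, mean inter-marker distance %.2f cM (%s convention)\n",
    x$n_markers, x$n_chromosomes, x$total_length_cM, x$mean_distance_cM,
    if (x$per_gap) "per-gap" else "total/n_markers"
  ))
  invisible(x)
}

#' Read a linkage map TSV
#'
#' Expected columns: `marker_id`, `chromosome`, `position_cM`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_linkage_map <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
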