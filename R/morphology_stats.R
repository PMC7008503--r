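#' Collagen packing efficiency
#'
#' Fraction of pixels above a count threshold, pooled over all planes of a
#' stack: a proxy for collagen coverage/density on binary-masked SHG
#' images. The default threshold is 15 counts on 12-bit data; "above" is
#' strict (`> threshold`) by default.
#'
#' @param stack An [image_stack()] (or a bare matrix / 3-D array).
#' @param threshold Count threshold (default 15).
#' @param strict Use `> threshold` (default) rather than `>=`.
#'
#' @return A `packing_result`: `fraction`, `n_pixels_on`, `n_pixels_total`,
#'   `threshold`, and `per_plane`, a tibble of per-plane fractions.
#' @examples
#' img <- image_stack(matrix(c(0, 100), 10, 10), pixel_pitch_um = 0.354)
#' packing_efficiency(img)$fraction # 0.5
#' @export
packing_efficiency <- function(stack, threshold = 15, strict = TRUE) {
  planes <- if (inherits(stack, "image_stack")) stack$planes else stack
  if (is.matrix(planes)) planes <- array(planes, dim = c(dim(planes), 1))
  if (!is.array(planes) || length(dim(planes)) != 3 || length(planes) == 0) {
    abort("`stack` must be a nonempty image stack, matrix or 3-D array.")
  }
  check_number(threshold, "threshold", lower = 0)
  check_flag(strict, "strict")
  on <- if (strict) planes > threshold else planes >= threshold
  per_plane <- tibble(
    plane = seq_len(dim(planes)[3]),
    fraction = apply(on, 3, mean)
  )
  structure(
    list(
      threshold = threshold, fraction = mean(on),
      n_pixels_on = sum(on), n_pixels_total = length(planes),
      per_plane = per_plane
    ),
    class = "packing_result"
  )
}

#' @export
print.packing_result <- function(x, ...) {
  cat(sprintf("Packing efficiency: %.4f (%d / %d pixels > %g counts)\n",
              x$fraction, x$n_pixels_on, x$n_pixels_total, x$threshold))
  invisible(x)
}

#' Group comparison statistics
#'
#' One-way ANOVA over the groups, followed by a two-sample Student's
#' t-test when there are exactly two groups or Tukey's honest significant
#' difference post-hoc test for three or more. Significance is declared at
#' alpha = 0.05.
#'
#' @param data A data frame with one observation per row.
#' @param value,group Column names (strings) of the measurement and the
#'   grouping factor (defaults `"value"`, `"group"`).
#' @param alpha Significance level (default 0.05).
#'
#' @return A `group_comparison` object: `groups` (per-group mean, SE, n),
#'   `anova` (F statistic, p-value), `pairwise` (t-test or Tukey HSD
#'   rows), `test`, `alpha`. `tidy()` returns the pairwise table;
#'   `glance()` the ANOVA row.
#' @examples
#' d <- data.frame(group = rep(c("a", "b"), each = 5),
#'                 value = c(rnorm(5), rnorm(5, 2)))
#' compare_groups(d)
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           alpha = 0.05) {
  data <- as_tibble(data)
  if (!all(c(value, group) %in% names(data))) {
    abort(sprintf("`data` needs columns `%s` and `%s`.", value, group))
  }
  df <- tibble(value = data[[value]], group = factor(data[[group]]))
  df <- df[complete.cases(df), ]
  counts <- table(df$group)
  if (length(counts) < 2) abort("need at least 2 groups.")
  if (any(counts < 2)) abort("need at least 2 observations per group.")

  groups <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    )
  fit <- aov(value ~ group, data = df)
  atab <- summary(fit)[[1]]
  anova_row <- tibble(
    statistic = atab["group", "F value"],
    p_value = atab["group", "Pr(>F)"],
    df_between = atab["group", "Df"],
    df_within = atab["Residuals", "Df"]
  )

  if (length(counts) == 2) {
    lv <- levels(df$group)
    tt <- t.test(df$value[df$group == lv[1]], df$value[df$group == lv[2]],
                 var.equal = TRUE)
    pairwise <- tibble(
      contrast = paste(lv[1], "-", lv[2]),
      estimate = mean(df$value[df$group == lv[1]]) -
        mean(df$value[df$group == lv[2]]),
      statistic = unname(tt$statistic), p_value = tt$p.value,
      significant = tt$p.value < alpha
    )
    test <- "one-way ANOVA + Student's t"
  } else {
    tk <- TukeyHSD(fit)$group
    pairwise <- tibble(
      contrast = rownames(tk),
      estimate = tk[, "diff"], statistic = NA_real_,
      p_value = tk[, "p adj"], significant = tk[, "p adj"] < alpha
    )
    test <- "one-way ANOVA + Tukey HSD"
  }
  structure(
    list(groups = groups, anova = anova_row, pairwise = pairwise,
         test = test, alpha = alpha),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (alpha = %g)\n", x$test, x$alpha))
  cat(sprintf("  ANOVA F = %.4g, p = %.4g\n",
              x$anova$statistic, x$anova$p_value))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::mutate(x$anova, test = x$test, alpha = x$alpha,
                significant = .data$p_value < x$alpha)
}
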