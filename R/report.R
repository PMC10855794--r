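#' Aggregate replicate measurements
#'
#' Mean, sample standard deviation (n - 1 denominator) and count, as the
#' experimental convention reports quantities from at least three
#' independently prepared samples. A warning is raised below three
#' replicates; a single value yields an undefined (NA) SD.
#'
#' @param values Numeric vector of replicate values.
#' @return A one-row tibble with `mean`, `sd`, `n`.
#' @examples
#' aggregate_replicates(c(2, 4, 6))
#' @export
aggregate_replicates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) {
    abort("no replicate values to aggregate.", class = "lensepr_error_report")
  }
  if (n < 3) {
    warn(sprintf("only %d replicate(s); at least 3 independent experiments are expected.", n),
      class = "lensepr_warning_replicates"
    )
  }
  tibble(
    mean = mean(values),
    sd = if (n > 1) sd(values) else NA_real_,
    n = n
  )
}

#' Two-sample Student's t-test
#'
#' Two-tailed two-sample t-test between replicate groups, Welch (unequal
#' variance) by default with a pooled-variance option. Significance is the
#' plain `p <= alpha` rule with no multiple-testing adjustment. When both
#' groups have zero variance and equal means the statistic is defined as
#' t = 0, p = 1 (and as p = 0 for distinct constant groups), with a message.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `t_statistic`, `degrees_of_freedom`, `p_value`,
#'   `significant`, `variant`.
#' @examples
#' t_test(c(1, 2, 3), c(4, 5, 6), variant = "pooled")
#' @export
t_test <- function(group_a, group_b, variant = c("welch", "pooled"), alpha = 0.05) {
  variant <- arg_match(variant)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 values.", class = "lensepr_error_report")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    equal <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    inform(sprintf(
      "both groups have zero variance; defining t = %s, p = %s.",
      if (equal) "0" else "Inf", if (equal) "1" else "0"
    ))
    return(tibble(
      t_statistic = if (equal) 0 else sign(mean(group_a) - mean(group_b)) * Inf,
      degrees_of_freedom = NA_real_,
      p_value = if (equal) 1 else 0,
      significant = !equal,
      variant = variant
    ))
  }
  res <- t.test(group_a, group_b,
    var.equal = (variant == "pooled"),
    alternative = "two.sided"
  )
  tibble(
    t_statistic = unname(res$statistic),
    degrees_of_freedom = unname(res$parameter),
    p_value = res$p.value,
    significant = res$p.value <= alpha,
    variant = variant
  )
}
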