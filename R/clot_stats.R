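#' Clot degradation percentage from dry weights
#'
#' The assay's printed formula divides the weight loss by the FINAL dry
#' weight: (initial - final) / final x 100 (`convention = "as_printed"`).
#' Most lysis assays divide by the initial weight instead;
#' `"fraction_of_initial"` gives (initial - final) / initial x 100. The
#' convention used is attached as an attribute.
#'
#' @param initial_weight,final_weight dry weights, grams (vectorised).
#' @param convention `"as_printed"` (default) or `"fraction_of_initial"`.
#' @return numeric percentage(s) with attribute `convention`.
#' @export
#' @examples
#' degradation_pct(0.15, 0.10) # 50
degradation_pct <- function(initial_weight, final_weight,
                            convention = c("as_printed", "fraction_of_initial")) {
  convention <- match.arg(convention)
  denom <- if (convention == "as_printed") final_weight else initial_weight
  if (any(denom == 0)) abort("zero denominator weight")
  out <- (initial_weight - final_weight) / denom * 100
  attr(out, "convention") <- convention
  out
}

#' Per-record degradation table
#'
#' @param records tibble of clot records with columns `group`,
#'   `replicate`, `initial_weight`, `final_weight` (grams).
#' @param convention as in [degradation_pct()].
#' @return `records` with a `degradation_pct` column and a `convention`
#'   attribute.
#' @export
clot_degradation <- function(records, convention = "as_printed") {
  out <- mutate(records, degradation_pct = as.numeric(
    degradation_pct(initial_weight, final_weight, convention)))
  attr(out, "convention") <- convention
  out
}

#' One-way ANOVA with Bonferroni and Holm post-hoc tests
#'
#' Classical one-way fixed-effects ANOVA, followed by all pairwise
#' two-sample t tests (pooled variance by default, Welch by flag) whose
#' raw p-values are adjusted by both the Bonferroni and the Holm
#' step-down procedures, reported side by side.
#'
#' @param data data frame.
#' @param value,group column names (strings) of the response and the
#'   group label.
#' @param alpha significance level for the reject flags.
#' @param var_equal pooled-variance t tests if `TRUE` (default), Welch
#'   otherwise.
#' @return object of class `clot_anova`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `alpha`, `group_means` tibble, and `posthoc`
#'   tibble (`group1`, `group2`, `p_raw`, `p_bonferroni`, `p_holm`,
#'   `reject_bonferroni`, `reject_holm`).
#' @export
anova_posthoc <- function(data, value = "degradation_pct", group = "group",
                          alpha = 0.05, var_equal = TRUE) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("each group needs at least 2 values")

  gm <- tibble(group = levels(g),
               n = as.integer(table(g)),
               mean = as.numeric(tapply(v, g, mean)),
               sd = as.numeric(tapply(v, g, stats::sd)))

  df_b <- nlevels(g) - 1L
  df_w <- length(v) - nlevels(g)
  ss_w <- sum((v - gm$mean[match(g, gm$group)])^2)
  if (ss_w == 0) {
    # all groups internally constant: F degenerates; identical groups get
    # the no-signal path rather than 0/0
    ss_b <- sum(gm$n * (gm$mean - mean(v))^2)
    if (ss_b == 0) {
      f_stat <- 0; p_value <- 1
    } else {
      f_stat <- Inf; p_value <- 0
    }
  } else {
    fit <- stats::aov(v ~ g)
    tab <- summary(fit)[[1]]
    f_stat <- tab$`F value`[1]
    p_value <- tab$`Pr(>F)`[1]
    if (sum(gm$n * (gm$mean - mean(v))^2) == 0) { f_stat <- 0; p_value <- 1 }
  }

  pairs <- utils::combn(levels(g), 2)
  p_raw <- apply(pairs, 2, function(pr) {
    x <- v[g == pr[1]]; y <- v[g == pr[2]]
    if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      if (mean(x) == mean(y)) return(1) else return(0)
    }
    stats::t.test(x, y, var.equal = var_equal)$p.value
  })
  posthoc <- tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p_raw = p_raw,
    p_bonferroni = stats::p.adjust(p_raw, method = "bonferroni"),
    p_holm = stats::p.adjust(p_raw, method = "holm")
  )
  posthoc$reject_bonferroni <- posthoc$p_bonferroni < alpha
  posthoc$reject_holm <- posthoc$p_holm < alpha

  structure(
    list(f_stat = f_stat, df_between = df_b, df_within = df_w,
         p_value = p_value, alpha = alpha, var_equal = var_equal,
         group_means = gm, posthoc = posthoc),
    class = "clot_anova"
  )
}

#' @export
print.clot_anova <- function(x, ...) {
  cat(sprintf("<clot_anova> F(%d, %d) = %.3f, p = %.4g (alpha = %g)\n",
              x$df_between, x$df_within, x$f_stat, x$p_value, x$alpha))
  print(x$posthoc)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise post-hoc table of a `clot_anova`
#'
#' @param x a `clot_anova` object.
#' @param ... unused.
#' @return the `posthoc` tibble.
#' @export
tidy.clot_anova <- function(x, ...) x$posthoc

#' One-row model summary of a `clot_anova`
#'
#' @param x a `clot_anova` object.
#' @param ... unused.
#' @return tibble with `f_stat`, `df_between`, `df_within`, `p_value`,
#'   `alpha`.
#' @export
glance.clot_anova <- function(x, ...) {
  tibble(f_stat = x$f_stat, df_between = x$df_between,
         df_within = x$df_within, p_value = x$p_value, alpha = x$alpha)
}
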