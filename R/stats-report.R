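#' Specify a statistical comparison
#'
#' Declares which standard test to run on a pipeline output table:
#' `two_way_anova` (factorial with interaction, Type III sums of squares
#' under sum-to-zero coding), `t_test` (Welch two-sample), `ks_test`
#' (two-sample Kolmogorov-Smirnov), or `chi_square` (independence, no
#' continuity correction). Optionally sizes the Bonferroni family for the
#' adjusted p-values and requests Cohen's d.
#'
#' @param response response column name.
#' @param factors character vector of factor column names (2 for the
#'   factorial ANOVA, 1 for the two-sample tests).
#' @param test one of `"two_way_anova"`, `"t_test"`, `"ks_test"`,
#'   `"chi_square"`.
#' @param family_size Bonferroni family size (default 1 = no correction).
#' @param effect_size compute Cohen's d for two-group comparisons (default
#'   TRUE).
#' @return a `comparison_spec` list.
#' @export
comparison_spec <- function(response, factors,
                            test = c("two_way_anova", "t_test", "ks_test",
                                     "chi_square"),
                            family_size = 1, effect_size = TRUE) {
  test <- match.arg(test)
  if (family_size < 1) stop("family_size must be >= 1")
  structure(list(response = response, factors = factors, test = test,
                 family_size = family_size, effect_size = effect_size),
            class = "comparison_spec")
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(x) - mean(y)) / s_p` with
#' `s_p^2 = ((n1 - 1) s1^2 + (n2 - 1) s2^2) / (n1 + n2 - 2)`.
#'
#' @param x,y numeric samples.
#' @return Cohen's d.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
             (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size, capped at 1. Always at least
#' the raw p-value.
#'
#' @param p numeric p-values.
#' @param family_size number of comparisons in the family.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, family_size) pmin(p * family_size, 1)

#' Run a declared statistical comparison on a data table
#'
#' Dispatches to the standard routine named by the spec and returns a tidy
#' report. The factorial ANOVA requires at least 2 observations per cell and
#' no empty cells; it is fitted with sum-to-zero contrasts and Type III sums
#' of squares, appropriate for the unbalanced group sizes typical of animal
#' cohorts.
#'
#' @param data data.frame holding the response and factor columns (for
#'   `chi_square`, two categorical columns named in `factors`, or pass a
#'   contingency table via `response = NULL`).
#' @param spec a [comparison_spec()].
#' @return data.frame: `term`, `statistic`, `df`, `df2`, `p_value`,
#'   `p_adjusted`, `cohens_d`.
#' @export
run_comparison <- function(data, spec) {
  stopifnot(inherits(spec, "comparison_spec"))
  fs <- spec$family_size
  report <- switch(
    spec$test,
    two_way_anova = {
      if (length(spec$factors) != 2)
        stop("two_way_anova needs exactly 2 factors")
      f1 <- spec$factors[1]; f2 <- spec$factors[2]
      dat <- data[, c(spec$response, f1, f2)]
      dat[[f1]] <- factor(dat[[f1]]); dat[[f2]] <- factor(dat[[f2]])
      cells <- base::table(dat[[f1]], dat[[f2]])
      if (any(cells == 0))
        stop("empty cell(s) in the factorial design: ",
             paste(which(cells == 0, arr.ind = TRUE), collapse = ","))
      if (any(cells < 2))
        stop("each cell of the factorial design needs >= 2 observations")
      fml <- stats::as.formula(paste(spec$response, "~", f1, "*", f2))
      fit <- stats::lm(fml, data = dat,
                       contrasts = stats::setNames(
                         list("contr.sum", "contr.sum"), c(f1, f2)))
      a <- car::Anova(fit, type = 3)
      rows <- setdiff(rownames(a), c("(Intercept)", "Residuals"))
      df2 <- a["Residuals", "Df"]
      data.frame(term = rows, statistic = a[rows, "F value"],
                 df = a[rows, "Df"], df2 = df2,
                 p_value = a[rows, "Pr(>F)"])
    },
    t_test = {
      g <- split(data[[spec$response]], data[[spec$factors[1]]])
      if (length(g) != 2) stop("t_test needs exactly 2 groups")
      tt <- stats::t.test(g[[1]], g[[2]])
      data.frame(term = spec$factors[1], statistic = unname(tt$statistic),
                 df = unname(tt$parameter), df2 = NA_real_,
                 p_value = tt$p.value)
    },
    ks_test = {
      g <- split(data[[spec$response]], data[[spec$factors[1]]])
      if (length(g) != 2) stop("ks_test needs exactly 2 groups")
      ks <- suppressWarnings(stats::ks.test(g[[1]], g[[2]]))
      data.frame(term = spec$factors[1], statistic = unname(ks$statistic),
                 df = NA_real_, df2 = NA_real_, p_value = ks$p.value)
    },
    chi_square = {
      tab <- base::table(data[[spec$factors[1]]], data[[spec$factors[2]]])
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected == 0))
        stop("chi-square undefined: zero expected count")
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(term = paste(spec$factors, collapse = ":"),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), df2 = NA_real_,
                 p_value = ct$p.value)
    })
  report$p_adjusted <- bonferroni(report$p_value, fs)
  report$cohens_d <- NA_real_
  if (isTRUE(spec$effect_size) && spec$test %in% c("t_test", "ks_test")) {
    g <- split(data[[spec$response]], data[[spec$factors[1]]])
    report$cohens_d <- cohens_d(g[[1]], g[[2]])
  }
  if (isTRUE(spec$effect_size) && spec$test == "two_way_anova") {
    g <- split(data[[spec$response]], data[[spec$factors[1]]])
    if (length(g) == 2) report$cohens_d[1] <- cohens_d(g[[1]], g[[2]])
  }
  rownames(report) <- NULL
  report
}
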