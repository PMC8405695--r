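#' @include AllClasses.R constants.R
NULL

#' Normality-gated two-sample comparison
#'
#' Reproduces the study's statistical workflow for one variable: each
#' group is tested for normality with the Shapiro-Wilk test; if both
#' groups pass (p > alpha) the groups are compared with a two-tailed
#' independent Student's t-test, otherwise with the independent-samples
#' Mann-Whitney U test. A zero-variance group cannot be tested for
#' normality and is routed to the Mann-Whitney path; two completely tied
#' samples give p = 1 (no evidence of a difference).
#'
#' @param valuesA,valuesB numeric vectors, one per group (n >= 3 each).
#' @param alpha normality gate level (default 0.05).
#' @return list with \code{test} ("t" or "mann_whitney"), \code{pValue},
#'   \code{normalityP} (length-2, NA for degenerate groups), \code{mean},
#'   \code{sd} (sample SD, n-1) and \code{n} per group.
#' @examples
#' set.seed(1)
#' compareGroups(rnorm(14, 148, 10), rnorm(14, 125, 11))
#' @export
compareGroups <- function(valuesA, valuesB, alpha = 0.05) {
  valuesA <- valuesA[is.finite(valuesA)]
  valuesB <- valuesB[is.finite(valuesB)]
  if (length(valuesA) < 3L || length(valuesB) < 3L)
    stop("each group needs at least 3 finite values")
  swp <- vapply(list(valuesA, valuesB), function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal <- !is.na(swp) & swp > alpha
  if (all(normal)) {
    test <- "t"
    p <- stats::t.test(valuesA, valuesB, var.equal = TRUE)$p.value
  } else {
    test <- "mann_whitney"
    if (stats::sd(c(valuesA, valuesB)) == 0) {
      p <- 1
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(valuesA, valuesB, exact = FALSE)$p.value)
      if (is.na(p)) p <- 1
    }
  }
  list(test = test, pValue = p, normalityP = swp,
       mean = c(mean(valuesA), mean(valuesB)),
       sd = c(stats::sd(valuesA), stats::sd(valuesB)),
       n = c(length(valuesA), length(valuesB)))
}

#' Per-group summary table and between-group ratios
#'
#' Mean, sample SD (n-1) and n per group for every numeric cohort
#' variable, plus the between-group ratio of means (larger over smaller,
#' rounded to one decimal) when exactly two groups are present.
#'
#' @param table cohort data.frame with a \code{group} column and numeric
#'   variables (e.g. from [simulateCohort()]).
#' @param variables which columns to summarise; default all numeric ones.
#' @return list with \code{summary} (long data.frame: variable, group, n,
#'   mean, sd) and \code{ratios} (named vector, or NULL for a single
#'   group).
#' @examples
#' summarizeCohort(simulateCohort(seed = 2))$ratios
#' @export
summarizeCohort <- function(table, variables = NULL) {
  stopifnot(is.data.frame(table), nrow(table) > 0, "group" %in% names(table))
  if (is.null(variables))
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  groups <- unique(table$group)
  rows <- list()
  for (v in variables) {
    for (g in groups) {
      x <- table[[v]][table$group == g]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = g, n = sum(is.finite(x)),
        mean = mean(x, na.rm = TRUE), sd = stats::sd(x[is.finite(x)]),
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  ratios <- NULL
  if (length(groups) == 2L) {
    ratios <- vapply(variables, function(v) {
      m <- summary$mean[summary$variable == v]
      round(max(abs(m)) / min(abs(m)), 1)
    }, numeric(1))
  }
  list(summary = summary, ratios = ratios)
}

#' Compare all cohort variables between two groups
#'
#' Runs [compareGroups()] for every numeric variable of a two-group
#' cohort table and collects the results in one data.frame.
#'
#' @inheritParams summarizeCohort
#' @param alpha normality gate level.
#' @return data.frame with one row per variable: test used, p-value,
#'   group means, SDs and ns.
#' @export
compareCohort <- function(table, variables = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  groups <- unique(table$group)
  if (length(groups) != 2L)
    stop("cohort comparison needs exactly two groups")
  if (is.null(variables))
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  rows <- lapply(variables, function(v) {
    a <- table[[v]][table$group == groups[1]]
    b <- table[[v]][table$group == groups[2]]
    r <- compareGroups(a, b, alpha = alpha)
    data.frame(variable = v, test = r$test, p_value = r$pValue,
               mean_a = r$mean[1], sd_a = r$sd[1], n_a = r$n[1],
               mean_b = r$mean[2], sd_b = r$sd[2], n_b = r$n[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- as.character(groups)
  out
}
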