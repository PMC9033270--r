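#' Two-group comparison tests
#'
#' Unpaired two-group tests for colony-level metrics: Welch's t (the default
#' reading of an "unpaired t-test"), Student's t, Mann–Whitney U (the
#' "nonparametric t-test"; exact enumeration for small tie-free samples,
#' normal approximation with continuity and tie correction otherwise), or a
#' permutation test on the difference of means (exhaustive over all label
#' assignments when feasible, otherwise `n_perm` random permutations with the
#' +1 correction). All p-values are two-sided and symmetric in group order.
#'
#' @param values_by_group named list of two numeric vectors.
#' @param test one of `"welch_t"`, `"student_t"`, `"mann_whitney"`,
#'   `"permutation"`.
#' @param n_perm permutation count for the random regime (default 1e4).
#' @param seed seed for random permutations.
#' @return data.frame with `test`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values_by_group,
                           test = c("welch_t", "student_t", "mann_whitney",
                                    "permutation"),
                           n_perm = 1e4, seed = 1) {
  test <- match.arg(test)
  stopifnot(is.list(values_by_group), length(values_by_group) == 2)
  a <- as.numeric(values_by_group[[1]])
  b <- as.numeric(values_by_group[[2]])
  if (test %in% c("welch_t", "student_t") && (length(a) < 2 || length(b) < 2)) {
    stop_config("parametric tests need at least 2 values per group")
  }
  res <- switch(test,
    welch_t = {
      h <- t.test(a, b, var.equal = FALSE)
      c(h$statistic, h$p.value)
    },
    student_t = {
      h <- t.test(a, b, var.equal = TRUE)
      c(h$statistic, h$p.value)
    },
    mann_whitney = {
      pooled <- c(a, b)
      if (length(unique(pooled)) == 1) {
        warning("constant pooled data; rank test uninformative")
        c(NA_real_, 1)
      } else {
        exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(pooled)
        h <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
        c(h$statistic, h$p.value)
      }
    },
    permutation = permutation_test(a, b, n_perm = n_perm, seed = seed)
  )
  data.frame(test = test, statistic = unname(res[1]),
             p_value = min(1, unname(res[2])),
             n_a = length(a), n_b = length(b), row.names = NULL)
}

# Two-sided permutation test on the difference of means. Exhaustive when
# choose(n, n_a) <= max_exhaustive, else n_perm random label permutations.
permutation_test <- function(a, b, n_perm = 1e4, seed = 1,
                             max_exhaustive = 2e4) {
  obs <- mean(a) - mean(b)
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  tol <- 1e-12 * max(1, abs(obs))
  if (choose(n, na) <= max_exhaustive) {
    sets <- utils::combn(n, na)
    tot <- sum(pooled)
    stats <- colSums(matrix(pooled[sets], nrow = na)) / na -
      (tot - colSums(matrix(pooled[sets], nrow = na))) / (n - na)
    p <- mean(abs(stats) >= abs(obs) - tol)
  } else {
    cnt <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(j) {
        i <- sample.int(n, na)
        s <- mean(pooled[i]) - mean(pooled[-i])
        abs(s) >= abs(obs) - tol
      }, logical(1)))
    })
    p <- (1 + cnt) / (n_perm + 1)
  }
  c(obs, p)
}

#' Two-way ANOVA with type-II sums of squares
#'
#' For balanced or near-balanced factorial designs (e.g. lineage x genotype).
#'
#' @param data data.frame.
#' @param response,factor_a,factor_b column names.
#' @return data.frame with `term`, `statistic` (F), `p_value` for the two
#'   main effects and the interaction.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  stopifnot(all(c(response, factor_a, factor_b) %in% names(data)))
  d <- data.frame(y = data[[response]],
                  A = factor(data[[factor_a]]),
                  B = factor(data[[factor_b]]))
  fit <- stats::lm(y ~ A * B, data = d)
  tab <- car::Anova(fit, type = 2)
  terms <- rownames(tab)
  keep <- terms != "Residuals"
  data.frame(term = c(factor_a, factor_b, paste(factor_a, factor_b, sep = ":")),
             statistic = tab$`F value`[keep],
             p_value = tab$`Pr(>F)`[keep], row.names = NULL)
}

#' Multiple-testing adjustment
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method `"bh"` (Benjamini–Hochberg step-up), `"bonferroni"` or
#'   `"none"`.
#' @return adjusted p-values (capped at 1).
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_config("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = switch(method, bh = "BH", bonferroni = "bonferroni",
                              none = "none"))
}

#' Condition report: ratios to control with tests
#'
#' For each metric and condition: n, mean, SD, the ratio of the condition
#' mean to the control mean, and the chosen test against the control — the
#' tabular form behind "ratio of marker-positive area to control" summaries
#' across treatment conditions.
#'
#' @param metrics long data.frame with columns `condition`, `metric`, `value`
#'   (extra columns such as `colony_id` are ignored).
#' @param control name of the control condition (must be present).
#' @param test passed to [compare_groups()].
#' @param n_perm,seed passed to [compare_groups()].
#' @return data.frame with `metric`, `condition`, `n`, `mean`, `sd`,
#'   `ratio_to_control`, `test`, `p_value` (NA for the control rows).
#' @export
condition_report <- function(metrics, control, test = "permutation",
                             n_perm = 1e4, seed = 1) {
  stopifnot(all(c("condition", "metric", "value") %in% names(metrics)))
  if (!control %in% metrics$condition) {
    stop_config("control condition '", control, "' not present")
  }
  rows <- list()
  for (m in unique(metrics$metric)) {
    sub <- metrics[metrics$metric == m, ]
    ctrl <- sub$value[sub$condition == control]
    for (cond in unique(sub$condition)) {
      v <- sub$value[sub$condition == cond]
      p <- NA_real_
      if (cond != control) {
        p <- compare_groups(list(v, ctrl), test = test, n_perm = n_perm,
                            seed = seed)$p_value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, condition = cond, n = length(v), mean = mean(v),
        sd = sd(v), ratio_to_control = mean(v) / mean(ctrl),
        test = ifelse(cond == control, NA_character_, test), p_value = p)
    }
  }
  do.call(rbind, rows)
}
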