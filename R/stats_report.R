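#' Group comparison following standard reporting conventions
#'
#' Summarizes each group (n, mean, sd, sem) and applies the named test:
#' two-tailed paired or unpaired Student's t-test for two groups (classical
#' equal-variance t by default; Welch available), one-way ANOVA with
#' Tukey's multiple comparisons for more than two groups, or
#' repeated-measures one-way ANOVA with Bonferroni-adjusted paired
#' pairwise t-tests for matched designs (complete blocks: each replicate
#' must contribute every group). Significance is judged at alpha = 0.05.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation (>= 2 groups, >= 2 values
#'   each).
#' @param design One of "two_group_paired", "two_group_unpaired",
#'   "oneway_tukey", "rm_bonferroni".
#' @param replicate_id Matched replicate/experiment identifier per
#'   observation; required for paired and repeated-measures designs.
#' @param welch Use Welch's correction for unpaired t (default FALSE).
#' @param alpha Significance threshold (default 0.05).
#' @return A `stats_result`: `summary` (per-group data.frame), `omnibus_p`,
#'   `pairwise` (data.frame with adjusted p per pair), `method`, `matched`,
#'   `significant`.
#' @export
compare_groups <- function(values, groups,
                           design = c("two_group_unpaired",
                                      "two_group_paired",
                                      "oneway_tukey", "rm_bonferroni"),
                           replicate_id = NULL, welch = FALSE,
                           alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  counts <- table(groups)
  if (length(counts) < 2L) stop("need at least two groups")
  if (any(counts < 2L)) stop("every group needs n >= 2")
  matched <- design %in% c("two_group_paired", "rm_bonferroni")
  if (matched) {
    if (is.null(replicate_id) || anyNA(replicate_id))
      stop("matched designs require replicate_id for every observation")
    blocks <- table(factor(replicate_id), groups)
    if (any(blocks != 1L))
      stop("matched designs require complete blocks: each replicate must ",
           "contribute exactly one value per group")
  }
  if (startsWith(design, "two_group") && length(counts) != 2L)
    stop("two-group designs require exactly two groups")

  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = stats::sd(v), sem = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))

  lv <- levels(groups)
  if (design == "two_group_unpaired") {
    tt <- stats::t.test(values[groups == lv[1]], values[groups == lv[2]],
                        var.equal = !welch)
    omnibus_p <- tt$p.value
    pairwise <- data.frame(group1 = lv[1], group2 = lv[2],
                           estimate = summ$mean[1] - summ$mean[2],
                           statistic = unname(tt$statistic),
                           p = tt$p.value, p_adj = tt$p.value,
                           stringsAsFactors = FALSE)
    method <- if (welch) "Welch two-sample t-test (two-tailed)"
              else "Student's unpaired t-test (two-tailed)"
  } else if (design == "two_group_paired") {
    ord1 <- order(replicate_id[groups == lv[1]])
    ord2 <- order(replicate_id[groups == lv[2]])
    v1 <- values[groups == lv[1]][ord1]
    v2 <- values[groups == lv[2]][ord2]
    tt <- stats::t.test(v1, v2, paired = TRUE)
    omnibus_p <- tt$p.value
    pairwise <- data.frame(group1 = lv[1], group2 = lv[2],
                           estimate = mean(v1 - v2),
                           statistic = unname(tt$statistic),
                           p = tt$p.value, p_adj = tt$p.value,
                           stringsAsFactors = FALSE)
    method <- "Student's paired t-test (two-tailed)"
  } else if (design == "oneway_tukey") {
    df <- data.frame(y = values, g = groups)
    fit <- stats::aov(y ~ g, data = df)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    pr <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pairwise <- data.frame(group1 = pr[, 1], group2 = pr[, 2],
                           estimate = tk[, "diff"],
                           statistic = NA_real_,
                           p = NA_real_, p_adj = tk[, "p adj"],
                           stringsAsFactors = FALSE, row.names = NULL)
    method <- "One-way ANOVA with Tukey's multiple comparisons"
  } else { # rm_bonferroni
    df <- data.frame(y = values, g = groups,
                     block = factor(replicate_id))
    fit <- stats::aov(y ~ g + Error(block), data = df)
    tab <- summary(fit)[["Error: Within"]][[1]]
    omnibus_p <- tab[["Pr(>F)"]][1]
    pairs <- utils::combn(lv, 2)
    pw <- apply(pairs, 2, function(p) {
      o1 <- order(replicate_id[groups == p[1]])
      o2 <- order(replicate_id[groups == p[2]])
      v1 <- values[groups == p[1]][o1]
      v2 <- values[groups == p[2]][o2]
      tt <- stats::t.test(v1, v2, paired = TRUE)
      c(estimate = mean(v1 - v2), statistic = unname(tt$statistic),
        p = tt$p.value)
    })
    pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                           estimate = pw["estimate", ],
                           statistic = pw["statistic", ],
                           p = pw["p", ],
                           p_adj = stats::p.adjust(pw["p", ], "bonferroni"),
                           stringsAsFactors = FALSE)
    method <- paste("Repeated-measures one-way ANOVA with Bonferroni's",
                    "multiple comparisons")
  }
  structure(list(summary = summ, omnibus_p = omnibus_p, pairwise = pairwise,
                 method = method, matched = matched, alpha = alpha,
                 significant = is.finite(omnibus_p) && omnibus_p < alpha),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat("<stats_result>", x$method, "\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("omnibus p = %.4g (%s at alpha = %.2g)\n", x$omnibus_p,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
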