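# The phenotype statistics battery: Fisher exact (2x2), Holm-Bonferroni,
# Wilcoxon rank-sum, Welch t, Kaplan-Meier + log-rank, top-quantile
# survival subsetting and Wilson proportion intervals. Standard model
# fits are delegated to stats/survival; the 2x2 exact test is computed
# directly so its two-sided rule (point-probability, 1e-12 relative
# slack) is explicit.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on the margins, the two-sided p-value is the sum of
#' hypergeometric probabilities of all tables whose point probability is
#' at most that of the observed table (within a 1e-12 relative slack for
#' floating-point ties). A table with an all-zero row or column is
#' degenerate: p = 1 with a warning.
#'
#' @param tab 2x2 matrix of nonnegative counts (rows = groups,
#'   columns = outcome / no outcome), or a vector `c(a, b, c, d)` filled
#'   row-wise.
#' @return List with `p_value`, `odds_ratio` (sample OR, may be Inf/NaN).
#' @examples
#' fisher_exact_2x2(matrix(c(1, 9, 9, 1), 2, byrow = TRUE))$p_value
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  if (any(dim(tab) != 2L) || any(tab < 0) || any(tab != round(tab)))
    stop("tab must be a 2x2 matrix of nonnegative integers", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin (all-zero row or column); p = 1",
            call. = FALSE)
    return(list(p_value = 1, odds_ratio = NaN))
  }
  m <- a + b          # row-1 total
  n <- c_ + d         # row-2 total
  k <- a + c_         # column-1 total
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(a, m, n, k)
  p <- sum(dens[dens <= d_obs * (1 + 1e-12)])
  list(p_value = min(1, p), odds_ratio = (a * d) / (b * c_))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sort ascending, multiply the i-th smallest p by (m - i + 1), enforce
#' monotonicity by running maxima, cap at 1, restore input order.
#' Delegates to [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
holm_bonferroni <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "holm")
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum distribution when the pooled sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. Wraps
#' [stats::wilcox.test()] with that rule made explicit.
#'
#' @param x,y Numeric samples (nonempty).
#' @param mode `"auto"` applies the rule above; `"exact"`/`"normal"`
#'   force a mode.
#' @return List with `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `mode` used.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
                  auto = (length(x) + length(y) <= 12L) && !ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && ties)
    stop("exact mode is not defined with ties", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       mode = if (exact) "exact" else "normal")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom
#' ([stats::t.test()] default). The degenerate case of zero variance in
#' both groups returns t = 0, p = 1 for equal means (with a warning) and
#' p = 0 for unequal means.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 observations per group", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    warning("zero variance in both groups", call. = FALSE)
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf,
                df = NA_real_, p_value = 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Assemble a survival event table
#'
#' @param subject_id Identifiers.
#' @param group Group labels.
#' @param time Observation times (days, >= 0).
#' @param status 1 = death observed, 0 = censored (escaped flies map to
#'   censored). Character `"dead"`/`"censored"` also accepted.
#' @param sex Optional sex labels.
#' @return data.frame of class `event_table`.
#' @export
event_table <- function(subject_id, group, time, status, sex = NA) {
  if (is.character(status)) {
    if (!all(status %in% c("dead", "censored")))
      stop("status labels must be 'dead' or 'censored'", call. = FALSE)
    status <- status == "dead"
  }
  status <- as.integer(status)
  if (any(time < 0)) stop("times must be >= 0", call. = FALSE)
  if (!all(status %in% c(0L, 1L)))
    stop("status must be 0 (censored) or 1 (dead)", call. = FALSE)
  out <- data.frame(subject_id = as.character(subject_id),
                    group = as.character(group),
                    sex = sex, time = as.numeric(time), status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("event_table", class(out))
  out
}

#' Kaplan-Meier estimate with Greenwood log-log confidence bands
#'
#' Product-limit estimate per group via [survival::survfit()] with
#' `conf.type = "log-log"`; censoring reduces the risk set without a
#' step.
#'
#' @param events An [event_table()].
#' @param conf_level Confidence level (default 0.95).
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `lower`, `upper`.
#' @export
km_estimate <- function(events, conf_level = 0.95) {
  if (sum(events$status) == 0L && nrow(events) == 0L)
    stop("no observations", call. = FALSE)
  one_group <- length(unique(events$group)) == 1L
  fml <- if (one_group) survival::Surv(time, status) ~ 1
         else survival::Surv(time, status) ~ group
  fit <- survival::survfit(fml, data = events, conf.type = "log-log",
                           conf.int = conf_level)
  s <- summary(fit, censored = TRUE)
  grp <- if (one_group) rep(unique(events$group), length(s$time))
         else sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor, surv = s$surv,
             lower = ifelse(is.na(s$lower), NA_real_, s$lower),
             upper = ifelse(is.na(s$upper), NA_real_, s$upper),
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over pooled death
#' times (1 df), via [survival::survdiff()].
#'
#' @param events An [event_table()] with exactly two groups and at least
#'   one death.
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank_test <- function(events) {
  if (length(unique(events$group)) != 2L)
    stop("need exactly two groups", call. = FALSE)
  if (sum(events$status) == 0L)
    stop("no deaths observed", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, status) ~ group,
                           data = events, rho = 0)
  chisq <- unname(sd$chisq)
  list(statistic = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Longest-lived subset per group
#'
#' Within each group, retains the `ceiling(q * n)` subjects with the
#' largest observed death times, where `n` is the number of deaths in
#' the group (censored subjects are not eligible). Ties at the cutoff
#' break deterministically by `subject_id` order.
#'
#' @param events An [event_table()].
#' @param q Quantile in (0, 1]; 0.25 selects the top quarter.
#' @return The retained subset of `events`.
#' @export
top_quantile_subset <- function(events, q = 0.25) {
  if (!(is.numeric(q) && length(q) == 1L && q > 0 && q <= 1))
    stop("q must be in (0, 1]", call. = FALSE)
  keep <- lapply(split(events, events$group), function(g) {
    d <- g[g$status == 1L, , drop = FALSE]
    if (nrow(d) == 0L) stop("group with no deaths", call. = FALSE)
    n_keep <- ceiling(q * nrow(d))
    d <- d[order(-d$time, d$subject_id), , drop = FALSE]
    d[seq_len(n_keep), , drop = FALSE]
  })
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  class(out) <- class(events)
  out
}

#' Wilson score interval for a proportion
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)` within \[0, 1\].
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  if (n < 1L || k < 0L || k > n) stop("need 0 <= k <= n, n >= 1",
                                      call. = FALSE)
  ci <- suppressWarnings(
    stats::prop.test(k, n, conf.level = level, correct = FALSE)$conf.int
  )
  c(lower = ci[1], upper = ci[2])
}

#' Within-group composition percentages
#'
#' For a long count table (`group`, `category`, `count`), computes each
#' category's percentage of its group total within each category family.
#' Categories must be assigned to families of mutually exclusive
#' outcomes (e.g. male/female; heterozygote/homozygote) via `family`;
#' with a single family the group total is the plain column sum.
#'
#' @param counts data.frame with columns `group`, `category`, `count`,
#'   and optionally `family`.
#' @param digits Decimal places for the rendered percentage (default 1,
#'   as percentages are conventionally reported).
#' @return `counts` with `total` and `percent` columns added.
#' @export
composition_percentages <- function(counts, digits = 1) {
  stopifnot(all(c("group", "category", "count") %in% names(counts)))
  if (is.null(counts$family)) counts$family <- "all"
  key <- interaction(counts$group, counts$family, drop = TRUE)
  totals <- tapply(counts$count, key, sum)
  counts$total <- as.integer(totals[as.character(key)])
  counts$percent <- round(100 * counts$count / counts$total, digits)
  counts
}
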