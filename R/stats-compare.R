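## Region comparison: one-way ANOVA with Tukey-Kramer post hoc.
## The ANOVA is delegated to stats::aov; the Tukey-Kramer table is
## assembled from the model mean square with studentized-range tail
## probabilities (stats::ptukey), which keeps the q statistics exposed
## and supports unequal group sizes (the Kramer adjustment).

checkGrouped <- function(values, group) {
    stopifnot(length(values) == length(group))
    keep <- is.finite(values) & !is.na(group)
    values <- values[keep]
    group <- factor(group[keep])
    sizes <- table(group)
    if (length(sizes) < 2)
        stop("at least 2 groups are required")
    if (any(sizes < 2))
        stop("every group needs >= 2 values for the ANOVA")
    list(values = values, group = droplevels(group))
}

#' One-way ANOVA across regions
#'
#' @param values numeric measurements (one metric).
#' @param group region label per value (>= 2 groups of >= 2 values).
#' @return list with `f_statistic`, `p_value`, `df` (between, within)
#'   and `ms_within`.
#' @examples
#' regionAnova(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'             rep(c("NM", "EM", "LM"), each = 3))
#' @export
regionAnova <- function(values, group) {
    g <- checkGrouped(values, group)
    if (diff(range(g$values)) == 0)
        stop("F is undefined: zero within-group and between-group variance")
    fit <- stats::aov(g$values ~ g$group)
    tab <- summary(fit)[[1]]
    msw <- tab["Residuals", "Mean Sq"]
    msb <- tab[1, "Mean Sq"]
    if (!is.finite(msw) || (msw == 0 && msb == 0))
        stop("F is undefined: zero within-group and between-group variance")
    f <- if (msw == 0) Inf else msb / msw
    df <- c(between = tab[1, "Df"], within = tab["Residuals", "Df"])
    p <- stats::pf(f, df[1], df[2], lower.tail = FALSE)
    list(f_statistic = unname(f), p_value = unname(p), df = df,
         ms_within = unname(msw))
}

significanceStars <- function(p) {
    cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
        labels = c("****", "***", "**", "*", "n.s."))
}

#' Tukey-Kramer post hoc comparisons
#'
#' For each unordered pair of groups,
#' q = |mean_i - mean_j| / sqrt(MSW/2 * (1/n_i + 1/n_j)), with the
#' adjusted p from the studentized-range distribution on (k, N - k)
#' degrees of freedom. Unequal group sizes are allowed.
#'
#' @param values numeric measurements.
#' @param group region label per value.
#' @param alpha significance level for the `significant` flag.
#' @return An [S4Vectors::DataFrame], one row per pair: group_1,
#'   group_2, mean_diff, se, q, p_adj, significant, stars,
#'   untestable. Pairs involving a group of size 1 are flagged
#'   untestable (NA statistics).
#' @export
tukeyKramer <- function(values, group, alpha = 0.05) {
    stopifnot(length(values) == length(group))
    keep <- is.finite(values) & !is.na(group)
    v <- values[keep]
    gr <- droplevels(factor(group[keep]))
    ns <- tapply(v, gr, length)
    if (nlevels(gr) < 2)
        stop("at least 2 groups are required")
    k <- nlevels(gr)
    N <- length(v)
    dfw <- N - k
    if (dfw < 1)
        stop("no residual degrees of freedom for the Tukey-Kramer test")
    means <- tapply(v, gr, mean)
    ssw <- sum(tapply(v, gr, function(x) sum((x - mean(x))^2)))
    msw <- ssw / dfw
    if (msw == 0 && stats::var(v) == 0)
        stop("all values identical: pairwise comparisons are undefined")
    pairs <- utils::combn(levels(gr), 2)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
        g1 <- pairs[1, j]; g2 <- pairs[2, j]
        if (ns[[g1]] < 2 || ns[[g2]] < 2)
            return(data.frame(group_1 = g1, group_2 = g2,
                              mean_diff = means[[g1]] - means[[g2]],
                              se = NA_real_, q = NA_real_,
                              p_adj = NA_real_, significant = NA,
                              stars = NA_character_, untestable = TRUE))
        se <- sqrt(msw / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
        diffm <- means[[g1]] - means[[g2]]
        q <- if (se == 0) { if (diffm == 0) 0 else Inf }
             else abs(diffm) / se
        p <- stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
        data.frame(group_1 = g1, group_2 = g2, mean_diff = diffm,
                   se = se, q = unname(q), p_adj = unname(p),
                   significant = unname(p) < alpha,
                   stars = as.character(significanceStars(unname(p))),
                   untestable = FALSE)
    })
    S4Vectors::DataFrame(do.call(rbind, rows))
}

#' Full region comparison report
#'
#' One-way ANOVA plus the Tukey-Kramer pairwise table for one metric.
#' XRD metrics are compared at per-pattern granularity; pSHG at
#' per-acquisition-mean granularity (the caller supplies whichever
#' values are appropriate; the two granularities are never pooled).
#'
#' @param values numeric measurements.
#' @param group region label per value.
#' @param alpha significance level.
#' @param metric optional metric name carried into the report.
#' @return list with `metric`, `anova` (see [regionAnova()]) and
#'   `pairwise` (see [tukeyKramer()]).
#' @export
compareRegions <- function(values, group, alpha = 0.05,
                           metric = NA_character_) {
    an <- regionAnova(values, group)
    pw <- tukeyKramer(values, group, alpha = alpha)
    list(metric = metric, anova = an, pairwise = pw, alpha = alpha)
}
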