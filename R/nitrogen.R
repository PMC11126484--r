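#' Soil carbon-to-nitrogen ratio
#'
#' @param tc total carbon, g/kg.
#' @param tn total nitrogen, g/kg (> 0).
#' @return TC/TN, dimensionless.
#' @export
cn_ratio <- function(tc, tn) {
  if (any(tn <= 0)) stop("tn must be > 0", call. = FALSE)
  tc / tn
}

#' Net nitrification rate
#'
#' NO3--N accumulation over the incubation divided by its length — the
#' standard net-rate definition. Negative rates (net immobilization) are
#' reported, not clipped.
#'
#' @param no3_start,no3_end NO3--N at the start and end of the incubation,
#'   mg N/kg dry soil.
#' @param days incubation length, days (> 0).
#' @return Rate in mg N/kg dry soil/day.
#' @examples
#' net_nitrification_rate(1.95, 60.75, 28) # 2.10
#' @export
net_nitrification_rate <- function(no3_start, no3_end, days) {
  if (any(days <= 0)) stop("days must be > 0", call. = FALSE)
  (no3_end - no3_start) / days
}

#' Percent inhibition of nitrification
#'
#' Compares NO3--N accumulation with and without an inhibitor (e.g. 0.1%
#' v/v acetylene, which blocks ammonia monooxygenase):
#' `100 * (1 - delta_inhibited / delta_uninhibited)`, clipped to \[0, 100\].
#'
#' @param delta_inhibited NO3--N accumulation under the inhibitor, mg N/kg.
#' @param delta_uninhibited NO3--N accumulation without it, mg N/kg (> 0).
#' @return Inhibition in percent.
#' @export
inhibition_percent <- function(delta_inhibited, delta_uninhibited) {
  if (any(delta_uninhibited <= 0)) {
    stop("delta_uninhibited must be > 0", call. = FALSE)
  }
  pmin(100, pmax(0, 100 * (1 - delta_inhibited / delta_uninhibited)))
}

#' Log10-transform gene abundances
#'
#' Abundance data are log10-transformed before ANOVA, the usual variance
#' stabilization for qPCR copy numbers. Nonpositive values are rejected with
#' the offending positions named, rather than silently producing -Inf/NaN.
#'
#' @param values positive numeric vector of gene abundances.
#' @return `log10(values)`.
#' @export
log10_abundance <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    stop("log10_abundance requires positive values; offending record(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  log10(values)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA across >= 2 groups, each with >= 2
#' observations, via [stats::lm()]/[stats::anova()]. The degenerate case of
#' zero between- and zero within-group variance (all observations equal) is
#' defined as F = 0, p = 1. Significance is flagged at the 5% level.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return List with `f`, `p`, `df_between`, `df_within`, `significant`
#'   (p < 0.05).
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4))) # F = 1.5 on (1, 4) df
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2)) {
    stop("each group needs at least two values", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df_between <- nlevels(g) - 1L
  df_within <- length(y) - nlevels(g)
  if (isTRUE(all.equal(stats::var(y), 0)) || stats::var(y) == 0) {
    return(list(f = 0, p = 1, df_between = df_between,
                df_within = df_within, significant = FALSE))
  }
  tab <- anova(lm(y ~ g))
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  list(f = f, p = p, df_between = df_between, df_within = df_within,
       significant = p < 0.05)
}

#' Pairwise Welch t-tests with Holm correction
#'
#' Optional post-hoc report accompanying [one_way_anova()]: all pairwise
#' group comparisons by Welch's t-test, p-values Holm-adjusted. This is an
#' extension beyond the primary ANOVA, for exploring which groups differ.
#'
#' @param groups named (or unnamed) list of >= 2 numeric vectors.
#' @return data.frame with columns group1, group2, t, p, p_adj.
#' @export
pairwise_welch <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- apply(pairs, 2, function(ij) {
    tt <- t.test(groups[[ij[1]]], groups[[ij[2]]])
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    t = res["t", ], p = res["p", ])
  out$p_adj <- p.adjust(out$p, method = "holm")
  out
}
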