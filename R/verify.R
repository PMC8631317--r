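## Coerce replicate input to a list of numeric vectors. Accepts a list of
## vectors, or a data frame with columns `replicate` and a value column.
as_replicates <- function(x, value = "width_um") {
  if (is.data.frame(x)) {
    val <- intersect(c(value, "value"), names(x))[1]
    if (is.na(val) || !"replicate" %in% names(x)) {
      abort("replicate data frames need `replicate` and a value column.")
    }
    x <- split(x[[val]], x$replicate)
  }
  if (!is.list(x)) x <- list(x)
  x <- lapply(x, as.numeric)
  if (length(x) < 1 || any(!lengths(x))) {
    abort("each group needs at least one non-empty replicate.")
  }
  x
}

#' Percent width difference relative to a wild-type reference
#'
#' Verification-stage effect size: pools every replicate's cells and
#' reports `100 * (mean_mutant - mean_wt) / mean_wt`.
#'
#' @param mutant,wildtype Replicated samples: lists of per-replicate value
#'   vectors, or data frames with `replicate` and `width_um` columns.
#' @return Percent difference.
#' @export
#' @examples
#' relative_width(list(c(1.08, 1.09)), list(c(1.0, 1.0)))
relative_width <- function(mutant, wildtype) {
  m <- unlist(as_replicates(mutant))
  w <- unlist(as_replicates(wildtype))
  if (mean(w) <= 0) abort("wild-type mean must be > 0.")
  100 * (mean(m) - mean(w)) / mean(w)
}

#' Nested (hierarchical) t-test on replicate means
#'
#' Two-level comparison in which independent replicates -- not individual
#' cells -- are the experimental unit: each replicate is reduced to its
#' mean, and a two-sample pooled-variance t-test is run on the replicate
#' means with `df = R_a + R_b - 2`. For balanced designs this equals the
#' nested t-test of common statistics packages. When both groups'
#' replicate means are identical the statistic is defined as 0 with p = 1.
#'
#' @param a,b Replicated samples (see [relative_width()]); each group needs
#'   at least 2 replicates.
#' @return List: `t`, `df`, `p`, plus the replicate means.
#' @export
#' @examples
#' nested_t_test(list(0.9, 1.0, 1.1), list(1.4, 1.5, 1.6))
nested_t_test <- function(a, b) {
  a <- as_replicates(a)
  b <- as_replicates(b)
  if (length(a) < 2 || length(b) < 2) {
    abort("nested test undefined: each group needs >= 2 replicates.")
  }
  ma <- vapply(a, mean, 0)
  mb <- vapply(b, mean, 0)
  na <- length(ma)
  nb <- length(mb)
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(ma) + (nb - 1) * var(mb)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- mean(ma) - mean(mb)
  if (se == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    t <- diff / se
    p <- 2 * pt(-abs(t), df)
  }
  list(t = t, df = df, p = p, means_a = ma, means_b = mb)
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA across two or more groups (used, e.g., to test
#' whether replicate acquisitions of the same strain differ). Degenerate
#' input with zero variance everywhere leaves F undefined and errors.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("need >= 2 groups.")
  }
  if (any(lengths(groups) < 2)) abort("each group needs >= 2 values.")
  df <- data.frame(
    value = unlist(groups),
    group = factor(rep(seq_along(groups), lengths(groups)))
  )
  if (all(vapply(groups, var, 0) == 0)) {
    abort("undefined F statistic: zero within-group variance in every group.")
  }
  fit <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  list(
    F = unname(fit$statistic),
    df1 = unname(fit$parameter[1]),
    df2 = unname(fit$parameter[2]),
    p = fit$p.value
  )
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided comparison of two samples: exact enumeration when the pooled
#' size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b Numeric vectors.
#' @return List: `U` (statistic for the first sample), `p`, `exact`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) abort("both samples must be non-empty.")
  exact <- (length(a) + length(b) <= 20) && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Star notation for p-values
#'
#' The printed convention: `****` p < 0.0001, `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, `ns` otherwise. Boundary values fall in the
#' less significant bin.
#'
#' @param p Probabilities in `[0, 1]`. Vectorised.
#' @return Character vector of star codes.
#' @export
#' @examples
#' format_significance(c(5e-5, 0.03, 0.5))
format_significance <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("`p` must lie in [0, 1].")
  }
  dplyr::case_when(
    p < 0.0001 ~ "****",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Confirm screen candidates against a wild-type reference
#'
#' Verification-stage decision over >= 3 independent replicate
#' experiments. A candidate is confirmed when (i) its pooled width differs
#' from the wild type by at least `cutoff` percent, (ii) the nested t-test
#' against the wild type gives p < `alpha`, and (iii) the per-replicate
#' deltas all share one sign ("reproducibly wider or thinner"); OR when
#' the fraction of its cells flagged `uneven_width` exceeds
#' `uneven_threshold` -- the rescue clause for strains whose mean width is
#' nearly normal but whose individual cells have strongly non-uniform
#' diameters. Candidates with fewer than 3 replicates are marked
#' `insufficient replication` and never confirmed.
#'
#' @param cells Per-cell tibble: `strain_id`, `replicate`, `width_um`,
#'   optional logical `uneven_width`.
#' @param wt_strain Strain id of the wild-type reference (must share the
#'   candidates' replicate ids).
#' @param cutoff Minimum absolute percent width difference (default 8).
#' @param alpha Significance level for the nested t-test.
#' @param uneven_threshold Cell fraction triggering the uneven-width rescue.
#' @return Tibble, one row per candidate: `strain_id`, `n_replicates`,
#'   `delta_vs_wt_pct`, `t`, `df`, `p_value`, `stars`, `same_sign`,
#'   `uneven_frac`, `confirmed`, `reason`.
#' @export
confirm_hits <- function(cells, wt_strain = "WT", cutoff = 8, alpha = 0.05,
                         uneven_threshold = 0.10) {
  stopifnot(all(c("strain_id", "replicate", "width_um") %in% names(cells)))
  if (!"uneven_width" %in% names(cells)) cells$uneven_width <- FALSE
  wt <- dplyr::filter(cells, .data$strain_id == wt_strain)
  if (nrow(wt) == 0) abort("wild-type strain absent from `cells`.")
  wt_reps <- split(wt$width_um, wt$replicate)
  cand <- dplyr::filter(cells, .data$strain_id != wt_strain)
  purrr::map_dfr(split(cand, cand$strain_id), function(cc) {
    reps <- split(cc$width_um, cc$replicate)
    nr <- length(reps)
    delta <- relative_width(reps, wt_reps)
    uneven_frac <- mean(cc$uneven_width)
    uneven_ok <- uneven_frac > uneven_threshold
    if (nr < 3) {
      return(tibble::tibble(
        strain_id = cc$strain_id[1], n_replicates = nr,
        delta_vs_wt_pct = delta, t = NA_real_, df = NA_real_,
        p_value = NA_real_, stars = NA_character_, same_sign = NA,
        uneven_frac = uneven_frac, confirmed = FALSE,
        reason = "insufficient replication"
      ))
    }
    shared <- intersect(names(reps), names(wt_reps))
    per_rep_delta <- vapply(shared, function(r) {
      100 * (mean(reps[[r]]) - mean(wt_reps[[r]])) / mean(wt_reps[[r]])
    }, 0)
    same_sign <- length(per_rep_delta) >= 2 &&
      (all(per_rep_delta > 0) || all(per_rep_delta < 0))
    nt <- nested_t_test(reps, wt_reps)
    effect_ok <- abs(delta) >= cutoff && nt$p < alpha && same_sign
    confirmed <- effect_ok || uneven_ok
    reason <- dplyr::case_when(
      effect_ok ~ sprintf("|delta| >= %g%%, p < %g, reproducible sign", cutoff, alpha),
      uneven_ok ~ sprintf("uneven-width cells > %.0f%%", 100 * uneven_threshold),
      abs(delta) < cutoff ~ sprintf("|delta| < %g%%", cutoff),
      nt$p >= alpha ~ "not significant",
      TRUE ~ "sign not reproducible"
    )
    tibble::tibble(
      strain_id = cc$strain_id[1], n_replicates = nr,
      delta_vs_wt_pct = delta, t = nt$t, df = nt$df, p_value = nt$p,
      stars = format_significance(nt$p), same_sign = same_sign,
      uneven_frac = uneven_frac, confirmed = confirmed, reason = reason
    )
  })
}
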