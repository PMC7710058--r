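## Group statistics mirroring the behavioral analysis: a paired Wilcoxon
## signed-rank test of L_w versus L_b within a condition, and a
## Kruskal-Wallis omnibus test across conditions followed by Dunn rank
## post-hoc contrasts with Sidak family-wise adjustment.

#' Paired signed-rank test of stimulus versus blank licking
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-animal differences
#' \code{L_w - L_b}. Zero differences are dropped before ranking (the
#' classic convention); the number dropped is always reported. The exact
#' null distribution is used for effective n <= 25 with untied absolute
#' differences; otherwise the normal approximation with continuity
#' correction.
#'
#' @param L_w,L_b Equal-length numeric vectors of per-animal anticipatory
#'   rates (Hz); at least 5 pairs.
#' @return List: \code{statistic} (V), \code{p.value}, \code{n},
#'   \code{n_effective}, \code{n_zero_dropped}, \code{method}.
#' @examples
#' pairedSignedRank(c(5, 6, 7, 8, 9, 10), c(2, 2, 3, 3, 4, 4))
#' @export
pairedSignedRank <- function(L_w, L_b) {
  if (length(L_w) != length(L_b))
    stop("L_w and L_b must be paired per animal (equal lengths)")
  n <- length(L_w)
  if (n < 5L)
    stop("signed-rank test refused for n < 5 pairs (underpowered; ",
         "the exact test cannot reach p < 0.05 two-sided)")
  d <- L_w - L_b
  d <- d[!is.na(d)]
  zero <- d == 0
  d_eff <- d[!zero]
  n_eff <- length(d_eff)
  if (n_eff == 0L) {
    return(list(statistic = NA_real_, p.value = 1, n = n, n_effective = 0L,
                n_zero_dropped = sum(zero),
                method = "Wilcoxon signed-rank (all differences zero)"))
  }
  exact <- n_eff <= 25L && !anyDuplicated(abs(d_eff))
  wt <- suppressWarnings(
    stats::wilcox.test(d_eff, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value, n = n,
       n_effective = n_eff, n_zero_dropped = sum(zero),
       method = if (exact) "Wilcoxon signed-rank (exact)" else
         "Wilcoxon signed-rank (normal approximation, continuity corrected)")
}

#' Sidak family-wise adjustment
#'
#' \code{p_adj = 1 - (1 - p)^m}: monotone in p and bounded by 1.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size (default \code{length(p)}).
#' @return Adjusted p-values.
#' @export
sidakAdjust <- function(p, m = length(p)) {
  pmin(1, 1 - (1 - p)^m)
}

#' Compare performance across experimental groups
#'
#' Kruskal-Wallis omnibus rank test across conditions, followed by Dunn
#' post-hoc z contrasts (tie-corrected pooled rank variance) with Sidak
#' family-wise adjustment. By default contrasts are restricted to each group
#' against a reference condition (the medium-intensity group in the
#' intensity comparisons); pass \code{reference = NULL} for all pairs.
#'
#' @param performance Numeric vector of per-animal performance values (Hz).
#' @param group Condition labels, same length.
#' @param reference Reference condition for the contrasts, or \code{NULL}
#'   for all pairwise contrasts.
#' @return List: \code{omnibus} (\code{htest} from
#'   \code{stats::kruskal.test}), \code{contrasts} (\code{data.frame} with
#'   \code{group1}, \code{group2}, \code{z}, \code{p_raw}, \code{p_adjusted},
#'   \code{n1}, \code{n2}), \code{degenerate} flag, \code{n_per_group}.
#' @examples
#' set.seed(1)
#' perf <- c(rnorm(8), rnorm(8), rnorm(8, 3))
#' grp <- rep(c("a", "b", "c"), each = 8)
#' groupCompare(perf, grp, reference = "a")$contrasts
#' @export
groupCompare <- function(performance, group, reference = NULL) {
  stopifnot(length(performance) == length(group))
  group <- as.character(group)
  levels <- unique(group)
  if (length(levels) < 2L)
    stop("group comparison needs at least 2 groups")
  n_per <- table(group)
  if (any(n_per < 3L))
    stop("every group needs at least 3 animals; offending: ",
         paste(names(n_per)[n_per < 3L], collapse = ", "))
  if (!is.null(reference) && !reference %in% levels)
    stop("reference group '", reference, "' not present")

  if (stats::var(performance) == 0) {
    return(list(omnibus = NULL, contrasts = NULL, degenerate = TRUE,
                n_per_group = as.list(n_per)))
  }
  om <- stats::kruskal.test(performance, factor(group))

  N <- length(performance)
  rk <- rank(performance)
  mean_rank <- tapply(rk, group, mean)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))

  pairs <- if (is.null(reference)) {
    utils::combn(levels, 2L, simplify = FALSE)
  } else {
    lapply(setdiff(levels, reference), function(g) c(reference, g))
  }
  rows <- lapply(pairs, function(pr) {
    n1 <- n_per[[pr[1L]]]; n2 <- n_per[[pr[2L]]]
    z <- (mean_rank[[pr[1L]]] - mean_rank[[pr[2L]]]) /
      sqrt(sigma2 * (1 / n1 + 1 / n2))
    data.frame(group1 = pr[1L], group2 = pr[2L], z = z,
               p_raw = 2 * stats::pnorm(-abs(z)), n1 = n1, n2 = n2,
               stringsAsFactors = FALSE)
  })
  ct <- do.call(rbind, rows)
  ct$p_adjusted <- sidakAdjust(ct$p_raw, m = nrow(ct))
  list(omnibus = om, contrasts = ct, degenerate = FALSE,
       n_per_group = as.list(n_per))
}

#' Assemble a cohort table across conditions
#'
#' Binds per-condition [simulateCohort()] results into one table with one
#' row per animal (id, condition, last-20% L_w and L_b, performance, learned
#' and participated flags) — the shape consumed by [groupCompare()].
#'
#' @param ... [simulateCohort()] return values (or their \code{$results}
#'   data frames).
#' @return \code{data.frame}, one row per animal.
#' @export
cohortTable <- function(...) {
  tabs <- lapply(list(...), function(x) if (is.list(x) && !is.data.frame(x))
    x$results else x)
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$animal_id))
  out
}
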