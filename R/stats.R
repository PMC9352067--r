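# Pairwise comparison battery: two-tailed Fisher exact tests on region
# use, and Wilcoxon rank-sum tests with Hodges-Lehmann shift estimates on
# migration parameters. Raw p-values are reported (no multiple-testing
# correction) to mirror standard practice for these pairwise batteries; a
# Holm option is available.

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass criterion: the sum of
#' hypergeometric probabilities, at fixed margins, of all tables no more
#' probable than the observed one (the convention of R's
#' \code{fisher.test}). A table with a zero margin carries no information;
#' by convention p = 1 with a warning.
#'
#' @param tab 2x2 matrix (or something coercible) of non-negative counts;
#'   rows = groups, columns = used/not-used.
#' @return the p-value.
#' @export
fisher_exact_two_tailed <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1 by convention",
            call. = FALSE)
    return(1)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Wilcoxon rank-sum test with Hodges-Lehmann shift estimate
#'
#' Two-sided rank-sum test: exact null enumeration when the combined
#' sample size is at most 20 with no ties, otherwise the normal
#' approximation with tie and continuity corrections. The shift estimate
#' is the Hodges-Lehmann estimator (the median of all pairwise
#' differences x - y) with its confidence interval obtained by inverting
#' the rank-sum statistic.
#'
#' @param x,y numeric samples.
#' @param conf.level confidence level for the shift interval.
#' @return one-row data.frame: `statistic` (W), `p_value`,
#'   `shift_estimate`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
wilcoxon_rank_sum <- function(x, y, conf.level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("empty sample in rank-sum test", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- tryCatch(
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = TRUE, conf.int = TRUE,
                         conf.level = conf.level)),
    error = function(e) NULL)
  if (is.null(wt)) {
    # conf-int inversion can fail on heavily tied / constant samples;
    # the test itself is still defined
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    wt$conf.int <- c(NA_real_, NA_real_)
  }
  # degenerate comparisons (both samples constant and equal) have no
  # rank information; report no evidence of a shift
  if (!is.finite(wt$p.value)) wt$p.value <- 1
  hl <- median(outer(x, y, "-"))
  data.frame(statistic = unname(wt$statistic),
             p_value = wt$p.value,
             shift_estimate = hl,
             ci_low = wt$conf.int[1],
             ci_high = wt$conf.int[2],
             n1 = length(x), n2 = length(y))
}

subspecies_pairs <- function(ssp) {
  if (length(ssp) < 2) return(NULL)
  ssp <- sort(ssp)
  t(utils::combn(ssp, 2))
}

#' Pairwise Fisher tests of region use between subspecies
#'
#' One two-tailed Fisher exact test per region per subspecies pair,
#' restricted to subspecies with at least `fisher_min_n` complete-track
#' individuals; smaller groups are skipped with a reason.
#'
#' @param use_counts data.frame from [summarize_region_use()].
#' @param thresholds a [flyway_thresholds()] object.
#' @param season season string recorded in the output.
#' @param holm if `TRUE`, add Holm-adjusted p-values (`p_adj`).
#' @return data.frame: `test`, `season`, `region_id`, `subspecies_1`,
#'   `subspecies_2`, `n1`, `n2`, `used_1`, `used_2`, `p`, and `skipped`
#'   rows (p = NA) with `reason`.
#' @export
pairwise_region_tests <- function(use_counts,
                                  thresholds = flyway_thresholds(),
                                  season = NA_character_, holm = FALSE) {
  denom <- tapply(use_counts$used + use_counts$not_used,
                  use_counts$subspecies, max)
  pairs <- subspecies_pairs(names(denom))
  rows <- list()
  for (r in sort(unique(use_counts$region_id))) {
    for (i in seq_len(NROW(pairs))) {
      s1 <- pairs[i, 1]; s2 <- pairs[i, 2]
      n1 <- denom[[s1]]; n2 <- denom[[s2]]
      small <- c(s1, s2)[c(n1, n2) < thresholds$fisher_min_n]
      u1 <- use_counts$used[use_counts$region_id == r &
                              use_counts$subspecies == s1]
      u2 <- use_counts$used[use_counts$region_id == r &
                              use_counts$subspecies == s2]
      if (length(small)) {
        p <- NA_real_
        reason <- paste0("n < ", thresholds$fisher_min_n, " for ",
                         paste(small, collapse = ", "))
      } else {
        tab <- rbind(c(u1, n1 - u1), c(u2, n2 - u2))
        p <- if (sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) {
          1  # region used by no one (or everyone): no contrast
        } else stats::fisher.test(tab)$p.value
        reason <- NA_character_
      }
      rows[[length(rows) + 1]] <-
        data.frame(test = "fisher_exact", season = season, region_id = r,
                   subspecies_1 = s1, subspecies_2 = s2,
                   n1 = n1, n2 = n2, used_1 = u1, used_2 = u2,
                   p = p, reason = reason, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (holm) out$p_adj <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

# ordinal days unwrapped at the year boundary relative to each bird's
# south initiation, so a winter date in January sorts after December
unwrapped_day <- function(t, south_initiation) {
  od <- ordinal_day(t)
  ref <- ordinal_day(south_initiation)
  ifelse(!is.na(od) & !is.na(ref) & od < ref, od + 365, od)
}

#' Pairwise rank-sum tests of migration parameters between subspecies
#'
#' One Wilcoxon rank-sum test per period per parameter per subspecies
#' pair, restricted to subspecies with at least `wilcoxon_min_n` birds.
#' Dates are compared on leap-normalized ordinal days, unwrapped at the
#' year boundary relative to each bird's south-initiation day. Birds
#' missing a parameter (partial tracks) drop out of that test only.
#'
#' @param params data.frame from [parameter_table()].
#' @param thresholds a [flyway_thresholds()] object.
#' @param holm if `TRUE`, add Holm-adjusted p-values.
#' @return data.frame: `test`, `period`, `parameter`, `subspecies_1`,
#'   `subspecies_2`, `n1`, `n2`, `estimate`, `ci_low`, `ci_high`, `p`.
#' @export
pairwise_parameter_tests <- function(params,
                                     thresholds = flyway_thresholds(),
                                     holm = FALSE) {
  south_init <- params$initiation[match(paste(params$bird_id, "south"),
                                        paste(params$bird_id,
                                              params$period))]
  params$initiation_day <- unwrapped_day(params$initiation, south_init)
  params$arrival_day <- unwrapped_day(params$arrival, south_init)
  vars <- c("initiation_day", "arrival_day", "duration_days",
            "distance_km", "n_stationary", "median_stop_days")
  counts <- tapply(params$bird_id, params$subspecies,
                   function(v) length(unique(v)))
  eligible <- names(counts)[counts >= thresholds$wilcoxon_min_n]
  pairs <- subspecies_pairs(eligible)
  rows <- list()
  for (period in c("south", "winter", "north")) {
    sub <- params[params$period == period, , drop = FALSE]
    for (v in vars) {
      for (i in seq_len(NROW(pairs))) {
        s1 <- pairs[i, 1]; s2 <- pairs[i, 2]
        x <- sub[[v]][sub$subspecies == s1]
        y <- sub[[v]][sub$subspecies == s2]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < thresholds$wilcoxon_min_n ||
            length(y) < thresholds$wilcoxon_min_n) next
        res <- wilcoxon_rank_sum(x, y)
        rows[[length(rows) + 1]] <-
          data.frame(test = "wilcoxon_rank_sum", period = period,
                     parameter = v, subspecies_1 = s1, subspecies_2 = s2,
                     n1 = res$n1, n2 = res$n2, estimate = res$shift_estimate,
                     ci_low = res$ci_low, ci_high = res$ci_high,
                     p = res$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(test = character(0), period = character(0),
               parameter = character(0), subspecies_1 = character(0),
               subspecies_2 = character(0), n1 = integer(0),
               n2 = integer(0), estimate = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), p = numeric(0))
  if (holm && nrow(out)) out$p_adj <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}
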