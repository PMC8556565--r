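#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected rank-based H statistic with a chi-square reference
#' distribution on k - 1 degrees of freedom (delegating the statistic to
#' [stats::kruskal.test()]). Degenerate input where every value is equal
#' returns H = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups,
#'   total n >= 3).
#' @return list of class `kw_result`: `H`, `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$H  # 3.857 (hand ranks)
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  n <- lengths(groups)
  if (any(n < 1L)) stop("every group needs at least one observation")
  if (sum(n) < 3L) stop("need at least three observations in total")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  if (length(unique(x)) == 1L)
    return(structure(list(H = 0, df = length(groups) - 1L, p_value = 1),
                     class = "kw_result"))
  kt <- kruskal.test(x, g)
  structure(list(H = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value),
            class = "kw_result")
}

#' Flag outliers by the 1.5 IQR fence rule
#'
#' A value is an outlier when it lies strictly outside
#' `(q1 - 1.5 (q3 - q1), q3 + 1.5 (q3 - q1))`, with the quartiles
#' computed by linear interpolation of the order statistics
#' ([stats::quantile()] type 7). A zero IQR collapses the fences onto the
#' constant, and equality does not flag. Flagged values are reported, not
#' removed: downstream comparisons keep them.
#'
#' @param values numeric sample (n >= 4; fewer warns and flags nothing).
#' @return logical vector of flags, one per value.
#' @examples
#' iqr_outliers(c(1, 2, 3, 4, 100))  # only 100
#' @export
iqr_outliers <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 4L) {
    warning("fewer than 4 values: no outlier flags assigned")
    return(rep(FALSE, length(values)))
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE,
                na.rm = TRUE)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Boxplot summaries of a thickness table
#'
#' For every (age, layer) group: sample size, mean, median, quartiles
#' (linear-interpolation convention, matching [iqr_outliers()]) and the
#' flagged outlier values.
#'
#' @param table data.frame with columns `age_label`, `layer`,
#'   `thickness_um` (as produced by [thickness_table()]).
#' @return data.frame with one row per group; the `outliers` column is a
#'   list column of flagged values.
#' @export
summarize_groups <- function(table) {
  need <- c("age_label", "layer", "thickness_um")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (nrow(table) == 0L) stop("empty thickness table")
  keys <- unique(table[, c("age_label", "layer")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- table$age_label %in% keys$age_label[i] &
      table$layer == keys$layer[i]
    v <- table$thickness_um[sel]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    fl <- if (length(v) >= 4L) iqr_outliers(v) else rep(FALSE, length(v))
    data.frame(age_label = keys$age_label[i], layer = keys$layer[i],
               n = length(v), mean = mean(v), median = q[2],
               q1 = q[1], q3 = q[3],
               outliers = I(list(v[fl])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise Kruskal-Wallis comparisons between time points
#'
#' Applies the two-group Kruskal-Wallis test to every pair of age levels
#' for each layer (uncorrected p values; multiplicity handling is left to
#' downstream model-based analysis).
#'
#' @param table thickness table (see [summarize_groups()]).
#' @return data.frame with layer, the two ages, H and p.
#' @export
pairwise_kruskal <- function(table) {
  need <- c("age_label", "layer", "thickness_um")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  ages <- unique(table$age_label)
  layers <- unique(table$layer)
  rows <- list()
  for (layer in layers) {
    for (i in seq_along(ages)) {
      for (j in seq_along(ages)) {
        if (j <= i) next
        a <- table$thickness_um[table$layer == layer &
                                  table$age_label == ages[i]]
        b <- table$thickness_um[table$layer == layer &
                                  table$age_label == ages[j]]
        if (length(a) < 1L || length(b) < 1L || length(a) + length(b) < 3L)
          next
        kw <- kruskal_wallis(list(a, b))
        rows[[length(rows) + 1L]] <- data.frame(
          layer = layer, age_a = ages[i], age_b = ages[j],
          H = kw$H, p_value = kw$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, rows)
}

#' Bland-Altman agreement between two paired measurement series
#'
#' Bias (mean difference), normal-theory limits of agreement at the
#' requested two-sided coverage, and the largest absolute difference the
#' interval admits -- the figure quoted when comparing semi-automatic and
#' manual thickness measurements.
#'
#' @param a,b paired numeric vectors of equal length >= 3.
#' @param coverage two-sided coverage of the agreement interval
#'   (default 0.90).
#' @return list with `bias`, `sd_diff`, `lower`, `upper`,
#'   `max_abs_difference`, `coverage`, `n`.
#' @export
bland_altman <- function(a, b, coverage = 0.90) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 3L) stop("need at least three pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  z <- qnorm(1 - (1 - coverage) / 2)
  lims <- bias + c(-1, 1) * z * s
  list(bias = bias, sd_diff = s, lower = lims[1], upper = lims[2],
       max_abs_difference = max(abs(lims)), coverage = coverage,
       n = length(d))
}
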