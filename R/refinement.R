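#' Per-sample, per-window mutation counts
#'
#' Builds the samples x windows burden matrix: entry (s, w) is the number
#' of records of sample s whose position lies inside window w (1-based
#' inclusive bounds). The matrix has `catalog$n_samples` rows: samples with
#' zero mutations appear as zero rows. Columns follow the panel's rank
#' order. A record falling inside two coordinate-overlapping windows is
#' counted in both.
#'
#' @param catalog a `mutation_catalog`.
#' @param panel a `window_panel`.
#' @param sample_ids optional character vector of all cohort sample ids
#'   (length `n_samples`); defaults to the distinct ids among the records,
#'   padded with placeholder ids for zero-mutation samples.
#' @return An object of class `burden_matrix`: list with `counts` (integer
#'   matrix), `sample_ids`, `window_ids`, `cohort_name`, `windows`.
#' @export
per_sample_window_counts <- function(catalog, panel, sample_ids = NULL) {
  rec <- catalog$records
  w <- panel$windows
  if (is.null(sample_ids)) {
    sample_ids <- sort(unique(rec$sample_id))
    n_pad <- catalog$n_samples - length(sample_ids)
    if (n_pad > 0L) {
      sample_ids <- c(sample_ids,
                      sprintf("%s_zeromut_%03d", catalog$cohort_name, seq_len(n_pad)))
    }
  }
  stopifnot(length(sample_ids) == catalog$n_samples,
            all(unique(rec$sample_id) %in% sample_ids))
  wid <- .window_id(w$chrom, w$start, w$end)
  counts <- matrix(0L, nrow = length(sample_ids), ncol = nrow(w),
                   dimnames = list(sample_ids, wid))
  if (nrow(rec) && nrow(w)) {
    hits <- .overlap_pairs(rec$chrom, rec$pos, rec$pos, w$chrom, w$start, w$end)
    if (nrow(hits)) {
      tab <- table(factor(rec$sample_id[hits$q], levels = sample_ids),
                   factor(hits$s, levels = seq_len(nrow(w))))
      counts <- matrix(as.integer(tab), nrow = length(sample_ids),
                       dimnames = list(sample_ids, wid))
    }
  }
  structure(list(counts = counts, sample_ids = sample_ids, window_ids = wid,
                 cohort_name = catalog$cohort_name, windows = w),
            class = "burden_matrix")
}

#' Construct a burden matrix directly from a count matrix
#'
#' Mostly for simulation studies: columns are assumed to be in rank order
#' (column 1 = rank 1, the most mutated window).
#'
#' @param counts samples x windows integer matrix.
#' @param cohort_name cohort label.
#' @return A `burden_matrix`.
#' @export
burden_matrix <- function(counts, cohort_name = "") {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("w%03d", seq_len(ncol(counts)))
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("s%03d", seq_len(nrow(counts)))
  structure(list(counts = counts, sample_ids = rownames(counts),
                 window_ids = colnames(counts), cohort_name = cohort_name,
                 windows = NULL),
            class = "burden_matrix")
}

#' One-way ANOVA across windows
#'
#' Fixed-effects one-way ANOVA with window as the grouping factor and each
#' window's per-sample mutation counts as that group's observations.
#' Degenerate all-equal data returns F = 0 with p = 1 by convention.
#'
#' @param m a `burden_matrix` with at least 2 windows and 2 samples.
#' @return list with `F` and `p`.
#' @export
anova_across_windows <- function(m) {
  x <- m$counts
  k <- ncol(x)
  n <- nrow(x)
  if (k < 2L) stop("ANOVA needs at least 2 windows (no between-group contrast)")
  if (n < 2L) stop("ANOVA needs at least 2 samples")
  grand <- mean(x)
  col_means <- colMeans(x)
  ss_between <- n * sum((col_means - grand)^2)
  ss_within <- sum(sweep(x, 2L, col_means)^2)
  df1 <- k - 1L
  df2 <- k * (n - 1L)
  if (ss_within == 0 && ss_between == 0) {
    return(list(F = 0, p = 1))
  }
  if (ss_within == 0) {
    return(list(F = Inf, p = 0))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Tukey HSD selection of hotspot windows
#'
#' All-pairs Tukey(-Kramer) HSD on the window groups: pooled mean-square
#' error, studentized-range distribution with k groups and N - k error
#' degrees of freedom. For each window, `frac_lower_ranked_beaten` is the
#' share of lower-ranked windows (columns to its right) with Tukey-adjusted
#' p < `alpha` and a smaller mean; a window is a hotspot iff that share
#' exceeds `majority`. The lowest-ranked window has no lower-ranked
#' comparators (fraction 0) and is never a hotspot.
#'
#' @param m a `burden_matrix`, columns in rank order.
#' @param alpha familywise significance level (default 0.05).
#' @param majority required share of lower-ranked windows beaten,
#'   strictly exceeded (default 0.5).
#' @return data.frame of per-window decisions: `window_id`, `rank`, `mean`,
#'   `anova_F`, `anova_p`, `frac_lower_ranked_beaten`, `is_hotspot`.
#' @export
tukey_select <- function(m, alpha = 0.05, majority = 0.5) {
  x <- m$counts
  k <- ncol(x)
  n <- nrow(x)
  if (k < 2L) stop("Tukey selection needs at least 2 windows")
  col_means <- colMeans(x)
  ss_within <- sum(sweep(x, 2L, col_means)^2)
  df2 <- k * (n - 1L)
  if (ss_within == 0) {
    stop("pooled within-window variance is zero: counts are degenerate, ",
         "Tukey HSD is undefined")
  }
  mse <- ss_within / df2
  # adjusted p for every ordered pair (i beats j)
  se <- sqrt(mse / 2 * (1 / n + 1 / n))
  p_adj <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    q_obs <- abs(col_means[i] - col_means) / se
    p_adj[i, ] <- ptukey(q_obs, nmeans = k, df = df2, lower.tail = FALSE)
  }
  an <- anova_across_windows(m)
  frac <- vapply(seq_len(k), function(i) {
    lower <- seq_len(k)[-seq_len(i)]  # columns ranked below i
    if (!length(lower)) return(0)
    mean(p_adj[i, lower] < alpha & col_means[i] > col_means[lower])
  }, numeric(1))
  data.frame(
    window_id = m$window_ids,
    rank = seq_len(k),
    mean = unname(col_means),
    anova_F = an$F,
    anova_p = an$p,
    frac_lower_ranked_beaten = frac,
    is_hotspot = frac > majority,
    row.names = NULL
  )
}

#' Refine a ranked panel into a final hotspot panel
#'
#' Composition of [per_sample_window_counts()], [anova_across_windows()]
#' (gate: proceed only if the overall p < `alpha`) and [tukey_select()].
#' Windows flagged as hotspots are returned as a panel in rank order.
#'
#' @param catalog a `mutation_catalog`.
#' @param panel a `window_panel` (rank-ordered, e.g. a top-10\% panel).
#' @param alpha significance level for both the ANOVA gate and the Tukey
#'   comparisons (default 0.05).
#' @param majority hotspot threshold on the share of lower-ranked windows
#'   beaten (default 0.5).
#' @param sample_ids optional full cohort sample ids, passed through.
#' @return A `window_panel` of hotspot windows; the per-window decision
#'   table is attached as attribute `decisions`.
#' @export
refine_panel <- function(catalog, panel, alpha = 0.05, majority = 0.5,
                         sample_ids = NULL) {
  m <- per_sample_window_counts(catalog, panel, sample_ids)
  an <- anova_across_windows(m)
  if (!(an$p < alpha)) {
    out <- window_panel(panel$windows[0, ],
                        name = paste0(panel$name, "_hotspots"),
                        source_cohort = panel$source_cohort)
    attr(out, "decisions") <- NULL
    return(out)
  }
  dec <- tukey_select(m, alpha = alpha, majority = majority)
  keep <- which(dec$is_hotspot)
  out <- window_panel(panel$windows[keep, , drop = FALSE],
                      name = paste0(panel$name, "_hotspots"),
                      source_cohort = panel$source_cohort)
  attr(out, "decisions") <- dec
  out
}
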