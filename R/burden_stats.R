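#' Per-window mutation frequency for a cohort
#'
#' Mutations captured by each window of a panel, divided by the cohort's
#' sample count: mutations per sample per window. Per-sample normalization
#' makes cohorts of different size comparable.
#'
#' @param catalog a `mutation_catalog` with `n_samples > 0`.
#' @param panel a `window_panel`.
#' @return Named numeric vector (one value per window) with attributes
#'   `panel_name` and `cohort_name`.
#' @export
window_frequency <- function(catalog, panel) {
  if (catalog$n_samples == 0L) stop("catalog has n_samples = 0")
  w <- panel$windows
  rec <- catalog$records
  cap <- integer(nrow(w))
  if (nrow(rec) && nrow(w)) {
    hits <- .overlap_pairs(rec$chrom, rec$pos, rec$pos, w$chrom, w$start, w$end)
    tab <- table(factor(hits$s, levels = seq_len(nrow(w))))
    cap <- as.integer(tab)
  }
  vals <- cap / catalog$n_samples
  names(vals) <- .window_id(w$chrom, w$start, w$end)
  attr(vals, "panel_name") <- panel$name
  attr(vals, "cohort_name") <- catalog$cohort_name
  vals
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation; the two-sided p-value comes from the t
#' transform with n - 2 degrees of freedom. A constant vector makes the
#' correlation undefined and is an error, never a silent zero.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: input vector is constant")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Wilcoxon comparison of two burden vectors
#'
#' Paired: signed-rank test on the differences (zero differences dropped);
#' all-zero differences give p = 1 with a warning. Unpaired: rank-sum
#' (Mann-Whitney) test, exact when both groups have <= 25 observations and
#' there are no ties, otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param a,b numeric vectors; equal lengths required when `paired`.
#' @param paired logical (default FALSE).
#' @return Two-sided p-value.
#' @export
wilcoxon_compare <- function(a, b, paired = FALSE) {
  if (paired) {
    stopifnot(length(a) == length(b))
    d <- a - b
    if (all(d == 0)) {
      warning("all paired differences are zero; p = 1")
      return(1)
    }
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                       correct = TRUE))
    return(wt$p.value)
  }
  pooled <- c(a, b)
  use_exact <- length(a) <= 25L && length(b) <= 25L && !anyDuplicated(pooled)
  wt <- suppressWarnings(wilcox.test(a, b, paired = FALSE, exact = use_exact,
                                     correct = TRUE))
  wt$p.value
}

#' Per-window fold change in mean mutation burden between cohorts
#'
#' For each window: mean per-sample count in cohort a over mean in cohort b
#' ("average mutations per sample" ratio), with an unpaired Wilcoxon
#' rank-sum p-value on the per-sample counts. Windows where cohort b's mean
#' is zero are reported with `fold = Inf` and flagged, not dropped; windows
#' empty in both cohorts get `fold = NaN`.
#'
#' @param m_a,m_b `burden_matrix` objects computed on the same panel.
#' @return data.frame: `window_id`, `mean_a`, `mean_b`, `fold`, `b_zero`, `p`.
#' @export
fold_changes <- function(m_a, m_b) {
  stopifnot(identical(m_a$window_ids, m_b$window_ids))
  mean_a <- colMeans(m_a$counts)
  mean_b <- colMeans(m_b$counts)
  fold <- ifelse(mean_b > 0, mean_a / mean_b,
                 ifelse(mean_a > 0, Inf, NaN))
  p <- vapply(seq_along(mean_a), function(j) {
    wilcoxon_compare(m_a$counts[, j], m_b$counts[, j], paired = FALSE)
  }, numeric(1))
  data.frame(window_id = m_a$window_ids,
             mean_a = unname(mean_a), mean_b = unname(mean_b),
             fold = unname(fold), b_zero = unname(mean_b == 0), p = p,
             row.names = NULL)
}

#' Build an equal-sized cold-spot control panel
#'
#' Tiles the footprint into fixed-width windows and picks the `size` least
#' mutated ones (zero-capture tiles first, ties by chromosome then start)
#' as a negative-control panel for burden comparisons. With a catalog,
#' tiles are scored by their exact mutation count; without one, by their bp
#' overlap with the ranked mutation-covering windows — tiles overlapping no
#' ranked window provably contain zero mutations, since every record lies
#' inside some ranked window. Tiles intersecting `avoid` (e.g. the hotspot
#' panel) are excluded, so the cold panel is disjoint from it.
#'
#' @param ranked_windows ranked windows from [rank_windows()] (all placed
#'   windows, covering every mutation).
#' @param size number of cold windows (match the hotspot panel size).
#' @param footprint the `region_set` to tile.
#' @param width window width in bp (default 100).
#' @param catalog optional `mutation_catalog` for exact tile counts.
#' @param avoid optional `window_panel` (or windows data.frame) whose
#'   windows the cold panel must not intersect.
#' @return A `window_panel` of `size` windows with `capture_count` set to
#'   the tile's (exact or proxy) mutation score.
#' @export
coldspot_panel <- function(ranked_windows, size, footprint, width = 100L,
                           catalog = NULL, avoid = NULL) {
  width <- as.integer(width)
  r <- footprint$regions
  tiles <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
    s1 <- r$start[i] + 1L  # 1-based first position of the region
    starts <- seq.int(s1, by = width, length.out = max(0L, (r$end[i] - r$start[i]) %/% width))
    if (!length(starts)) return(NULL)
    data.frame(chrom = r$chrom[i], start = starts, end = starts + width - 1L,
               gene = r$gene[i])
  }))
  if (is.null(tiles) || nrow(tiles) < size) {
    stop("footprint too small: cannot tile ", size, " windows of width ", width)
  }
  if (!is.null(avoid)) {
    aw <- if (inherits(avoid, "window_panel")) avoid$windows else avoid
    hits <- .overlap_pairs(tiles$chrom, tiles$start, tiles$end,
                           aw$chrom, aw$start, aw$end)
    if (nrow(hits)) tiles <- tiles[-unique(hits$q), , drop = FALSE]
  }
  if (nrow(tiles) < size) {
    stop("footprint too small after excluding avoided windows")
  }
  if (!is.null(catalog)) {
    rec <- catalog$records
    score <- integer(nrow(tiles))
    if (nrow(rec)) {
      hits <- .overlap_pairs(rec$chrom, rec$pos, rec$pos,
                             tiles$chrom, tiles$start, tiles$end)
      tab <- table(factor(hits$s, levels = seq_len(nrow(tiles))))
      score <- as.integer(tab)
    }
  } else {
    score <- integer(nrow(tiles))
    hits <- .overlap_pairs(tiles$chrom, tiles$start, tiles$end,
                           ranked_windows$chrom, ranked_windows$start,
                           ranked_windows$end)
    if (nrow(hits)) {
      ov <- pmin(tiles$end[hits$q], ranked_windows$end[hits$s]) -
        pmax(tiles$start[hits$q], ranked_windows$start[hits$s]) + 1L
      agg <- tapply(ov, hits$q, sum)
      score[as.integer(names(agg))] <- as.integer(agg)
    }
  }
  o <- order(score, .norm_chrom(tiles$chrom), tiles$start)
  sel <- tiles[o[seq_len(size)], , drop = FALSE]
  sel$width <- width
  sel$capture_count <- score[o[seq_len(size)]]
  sel$rank <- seq_len(size)
  window_panel(sel, name = "coldspot", source_cohort = "")
}
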