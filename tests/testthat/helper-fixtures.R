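# small builders and independent oracles shared across tests

mk_catalog <- function(sample_id, chrom, pos, cohort = "toy", n_samples = NULL,
                       ref = NULL, alt = NULL) {
  n <- length(pos)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  mutation_catalog(
    data.frame(sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
               pos = pos, ref = ref, alt = alt, gene = rep("", n)),
    cohort_name = cohort, n_samples = n_samples
  )
}

mk_panel <- function(chrom, start, end, name = "p", gene = "") {
  n <- length(start)
  window_panel(
    data.frame(chrom = rep_len(chrom, n), start = start, end = end,
               width = end - start + 1L, gene = rep_len(gene, n),
               capture_count = 0L, rank = seq_len(n)),
    name = name
  )
}

mk_regions <- function(chrom, start, end, gene = "") {
  region_set(data.frame(chrom = chrom, start = start, end = end,
                        gene = rep_len(gene, length(start))), name = "toy")
}

# brute-force point-in-interval count (1-based inclusive)
bf_count_in <- function(pos, lo, hi) sum(pos >= lo & pos <= hi)

# exact minimum number of width-w intervals covering all points on one
# chromosome: left-to-right stabbing (anchor at leftmost uncovered point),
# a classic exactly-optimal algorithm for fixed-width interval point cover
bf_min_cover <- function(pos, width) {
  pos <- sort(unique(pos))
  k <- 0L
  while (length(pos)) {
    k <- k + 1L
    pos <- pos[pos > pos[1] + width - 1L]
  }
  k
}

# maximum number of points any single anchored window can capture
bf_best_single <- function(pos, width) {
  max(vapply(unique(pos), function(p) sum(pos >= p & pos <= p + width - 1L),
             numeric(1)))
}

# capture counts of a fixed non-sliding tiling (tiles [k*w+1, (k+1)*w])
bf_tiling_counts <- function(pos, width) {
  tile <- (pos - 1L) %/% width
  as.integer(table(tile))
}

# pairwise-concordance AUC, ties count 1/2
bf_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# overlap-based recovery of planted hotspots by a refined panel
recovery_scores <- function(hotspot_panel, truth) {
  w <- hotspot_panel$windows
  tw <- truth$windows
  if (nrow(w) == 0L) return(c(recall = 0, precision = NA_real_))
  hit <- outer(seq_len(nrow(w)), seq_len(nrow(tw)), Vectorize(function(i, j) {
    w$chrom[i] == tw$chrom[j] && w$start[i] <= tw$end[j] && w$end[i] >= tw$start[j]
  }))
  c(recall = mean(apply(hit, 2L, any)),
    precision = mean(apply(hit, 1L, any)))
}
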