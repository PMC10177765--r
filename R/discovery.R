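#' Construct a window panel
#'
#' @param windows data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `width`, `gene`, `capture_count`, `rank`.
#' @param name panel name.
#' @param source_cohort cohort the panel was discovered in.
#' @return An object of class `window_panel`.
#' @export
window_panel <- function(windows, name = "", source_cohort = "") {
  req <- c("chrom", "start", "end", "width", "gene", "capture_count", "rank")
  if (nrow(windows) == 0L) {
    windows <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), width = integer(0),
                          gene = character(0), capture_count = integer(0),
                          rank = integer(0))
  }
  missing_cols <- setdiff(req, names(windows))
  if (length(missing_cols)) {
    stop("windows is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  windows <- windows[order(windows$rank), req]
  rownames(windows) <- NULL
  structure(list(windows = windows, name = name, source_cohort = source_cohort),
            class = "window_panel")
}

#' @export
print.window_panel <- function(x, ...) {
  cat(sprintf("window_panel '%s': %d windows, total width %d bp (cohort: %s)\n",
              x$name, nrow(x$windows), sum(x$windows$width), x$source_cohort))
  invisible(x)
}

# greedy maximal-capture placement on one chromosome.
# pos: record positions (with multiplicity), 1-based.
.place_windows_chrom <- function(pos, width) {
  pv <- sort(pos)
  starts <- integer(0)
  counts <- integer(0)
  while (length(pv)) {
    cand <- unique(pv)
    cnt <- findInterval(cand + width - 1L, pv) - findInterval(cand - 1L, pv)
    best <- max(cnt)
    sel <- cand[which(cnt == best)[1L]]  # cand ascending: smallest start wins ties
    starts <- c(starts, sel)
    counts <- c(counts, best)
    pv <- pv[pv < sel | pv > sel + width - 1L]
  }
  data.frame(start = starts, count = counts)
}

#' Place fixed-width mutation-capture windows
#'
#' Greedy maximal-capture placement: candidate windows are anchored at each
#' distinct mutated position p as `[p, p + width - 1]`; the candidate
#' capturing the most not-yet-captured mutation records is selected
#' repeatedly (ties broken by smallest chromosome, then smallest start)
#' until every record is captured. Each record is credited to exactly one
#' window, so capture counts sum to the catalog's record count. Windows may
#' extend past exon ends — the anchoring mutation is inside the footprint —
#' but never straddle chromosomes.
#'
#' @param catalog a `mutation_catalog`, normally already restricted to
#'   `footprint` via [restrict_to_regions()].
#' @param footprint optional `region_set` used only to annotate each window
#'   with the gene of the region containing its anchor.
#' @param width window width in bp (default 100).
#' @return data.frame of windows: `chrom`, `start`, `end`, `width`, `gene`,
#'   `capture_count`, ordered by chromosome and start.
#' @export
place_windows <- function(catalog, footprint = NULL, width = 100L) {
  stopifnot(width >= 1L)
  rec <- catalog$records
  if (nrow(rec) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), width = integer(0),
                      gene = character(0), capture_count = integer(0)))
  }
  width <- as.integer(width)
  chrom_n <- .norm_chrom(rec$chrom)
  out <- lapply(sort(unique(chrom_n)), function(ch) {
    res <- .place_windows_chrom(rec$pos[chrom_n == ch], width)
    data.frame(chrom = ch, start = res$start,
               end = res$start + width - 1L, width = width,
               gene = "", capture_count = res$count)
  })
  win <- do.call(rbind, out)
  win <- win[order(win$chrom, win$start), ]
  rownames(win) <- NULL
  if (!is.null(footprint) && nrow(footprint$regions)) {
    r <- footprint$regions
    hits <- .overlap_pairs(win$chrom, win$start, win$start,
                           r$chrom, r$start + 1L, r$end)
    if (nrow(hits)) {
      first <- !duplicated(hits$q)
      win$gene[hits$q[first]] <- r$gene[hits$s[first]]
    }
  }
  win
}

#' Rank windows by mutation capture
#'
#' Sorts by `capture_count` descending, ties by (chromosome, start)
#' ascending, and assigns ranks 1..N.
#'
#' @param windows data.frame as returned by [place_windows()].
#' @return The same data.frame sorted, with a `rank` column.
#' @export
rank_windows <- function(windows) {
  stopifnot("capture_count" %in% names(windows))
  o <- order(-windows$capture_count, .norm_chrom(windows$chrom), windows$start)
  out <- windows[o, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top fraction of ranked windows as a panel
#'
#' Takes the first `ceiling(q * N)` ranked windows; the ceiling guarantees a
#' non-empty panel for any q > 0.
#'
#' @param ranked ranked windows from [rank_windows()].
#' @param q fraction in (0, 1] (default 0.10).
#' @param name panel name.
#' @param source_cohort cohort label.
#' @return A [window_panel()].
#' @export
top_fraction_panel <- function(ranked, q = 0.10, name = "top", source_cohort = "") {
  stopifnot(q > 0, q <= 1)
  if (nrow(ranked) == 0L) stop("cannot build a panel from an empty ranked list")
  n_take <- ceiling(q * nrow(ranked))
  window_panel(head(ranked[order(ranked$rank), ], n_take), name, source_cohort)
}

#' Panel set algebra: shared, unique and union windows
#'
#' A window of `a` is shared iff it intersects (>= 1 bp) any window of `b`,
#' and symmetrically; `shared_in_a` and `shared_in_b` are reported
#' separately because the overlap need not be 1-to-1. The union panel keeps
#' all windows of `a` plus the windows of `b` that intersect none of `a`
#' (overlapping cross-panel windows are represented once, by the `a`
#' member); it is re-ranked by capture count.
#'
#' @param a,b `window_panel` objects.
#' @return list with `shared_in_a`, `shared_in_b`, `unique_a`, `unique_b`,
#'   and `union_panel` (a `window_panel`).
#' @export
panel_overlap <- function(a, b) {
  wa <- a$windows
  wb <- b$windows
  hits <- .overlap_pairs(wa$chrom, wa$start, wa$end, wb$chrom, wb$start, wb$end)
  shared_a_idx <- unique(hits$q)
  shared_b_idx <- unique(hits$s)
  keep_b <- setdiff(seq_len(nrow(wb)), shared_b_idx)
  union_windows <- rbind(wa, wb[keep_b, , drop = FALSE])
  union_windows <- rank_windows(union_windows)
  list(
    shared_in_a = length(shared_a_idx),
    shared_in_b = length(shared_b_idx),
    unique_a = nrow(wa) - length(shared_a_idx),
    unique_b = nrow(wb) - length(shared_b_idx),
    union_panel = window_panel(union_windows,
                               name = paste0(a$name, "+", b$name),
                               source_cohort = paste(a$source_cohort,
                                                     b$source_cohort, sep = "+"))
  )
}
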