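#' Simulation configuration
#'
#' Defaults define a desk-scale study: a 20-gene, 12-kb exon footprint
#' (about 120 window-widths of background sequence) with 10 planted 100-bp
#' hotspot windows that together attract 30\% of each sample's mutations,
#' per-sample totals drawn negative-binomially (heavy overdispersion, as in
#' real mixed targeted/WES cohorts), and clinical covariates whose
#' distributions differ by risk label (high-risk samples are on average 10
#' years older and more often smokers). Cohort multipliers scale the
#' hotspot weight and/or mean burden per cohort; the default gives
#' high-risk samples 3x the hotspot weight of low-risk ones.
#'
#' @param seed integer master seed; all generator randomness derives from it.
#' @param n_genes,exons_per_gene,exon_width_bp footprint layout.
#' @param n_hotspots,hotspot_width_bp planted hotspot windows.
#' @param hotspot_weight fraction of a sample's mutations landing in
#'   planted hotspots (before cohort multipliers), in [0, 1).
#' @param hotspot_dirichlet_alpha Dirichlet concentration for per-hotspot
#'   weights.
#' @param burden_mean,burden_dispersion negative-binomial mean and size for
#'   per-sample mutation totals.
#' @param cohort_multipliers named list: cohort -> list(hotspot=, burden=).
#' @param age_means,age_sd,smoking_probs clinical covariate parameters per
#'   risk label.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       exons_per_gene = 3L,
                       exon_width_bp = 200L,
                       n_hotspots = 10L,
                       hotspot_width_bp = 100L,
                       hotspot_weight = 0.3,
                       hotspot_dirichlet_alpha = 20,
                       burden_mean = 30,
                       burden_dispersion = 2,
                       cohort_multipliers = list(
                         high = list(hotspot = 3, burden = 1)
                       ),
                       age_means = c(low = 55, high = 65),
                       age_sd = 8,
                       smoking_probs = list(
                         low = c(never = 0.65, former = 0.25, current = 0.10),
                         high = c(never = 0.20, former = 0.45, current = 0.35)
                       )) {
  stopifnot(hotspot_weight >= 0, hotspot_weight < 1, burden_mean > 0,
            burden_dispersion > 0, exon_width_bp >= hotspot_width_bp,
            n_hotspots <= n_genes * exons_per_gene)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_width_bp = as.integer(exon_width_bp),
                 n_hotspots = as.integer(n_hotspots),
                 hotspot_width_bp = as.integer(hotspot_width_bp),
                 hotspot_weight = hotspot_weight,
                 hotspot_dirichlet_alpha = hotspot_dirichlet_alpha,
                 burden_mean = burden_mean,
                 burden_dispersion = burden_dispersion,
                 cohort_multipliers = cohort_multipliers,
                 age_means = age_means, age_sd = age_sd,
                 smoking_probs = smoking_probs),
            class = "sim_config")
}

#' Generate a synthetic exon footprint
#'
#' Lays out `n_genes` genes of `exons_per_gene` disjoint exons each on four
#' synthetic chromosomes (round-robin), with fixed intron and intergenic
#' gaps. The layout is purely arithmetic, hence deterministic.
#'
#' @param config a `sim_config`.
#' @return A `region_set` (BED convention, 0-based half-open).
#' @export
generate_footprint <- function(config) {
  intron <- 500L
  intergenic <- 5000L
  n_chrom <- 4L
  offsets <- integer(n_chrom)  # next free 0-based coordinate per chromosome
  rows <- vector("list", config$n_genes * config$exons_per_gene)
  k <- 0L
  for (g in seq_len(config$n_genes)) {
    ci <- ((g - 1L) %% n_chrom) + 1L
    chrom <- sprintf("sim%d", ci)
    pos <- offsets[ci] + intergenic
    for (e in seq_len(config$exons_per_gene)) {
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = chrom, start = pos,
                              end = pos + config$exon_width_bp,
                              gene = sprintf("G%03d", g),
                              label = sprintf("G%03d_ex%d", g, e))
      pos <- pos + config$exon_width_bp + intron
    }
    offsets[ci] <- pos
  }
  region_set(do.call(rbind, rows), name = "synthetic_footprint")
}

#' Plant hotspot windows inside the footprint
#'
#' Picks `n_hotspots` distinct exons, places one hotspot window of
#' `hotspot_width_bp` uniformly inside each (hotspots are therefore
#' pairwise disjoint), and draws per-hotspot Dirichlet weights. Passing the
#' same object to two cohorts gives them a shared hotspot architecture;
#' drawing a second object with a different seed gives independent ones.
#'
#' @param config a `sim_config`.
#' @param footprint the `region_set` from [generate_footprint()].
#' @param seed seed for this draw (default: the config's master seed).
#' @return An object of class `hotspot_truth`: list with `windows`
#'   (1-based inclusive data.frame), `weights`, `width`.
#' @export
plant_hotspots <- function(config, footprint, seed = config$seed) {
  set.seed(as.integer(seed))
  r <- footprint$regions
  exon_idx <- sort(sample(nrow(r), config$n_hotspots))
  hw <- config$hotspot_width_bp
  offset <- vapply(exon_idx, function(i) {
    slack <- (r$end[i] - r$start[i]) - hw
    if (slack > 0L) sample.int(slack + 1L, 1L) - 1L else 0L
  }, integer(1))
  start1 <- r$start[exon_idx] + offset + 1L
  g <- rgamma(config$n_hotspots, shape = config$hotspot_dirichlet_alpha)
  structure(list(
    windows = data.frame(chrom = r$chrom[exon_idx], start = start1,
                         end = start1 + hw - 1L, gene = r$gene[exon_idx]),
    weights = g / sum(g),
    width = hw
  ), class = "hotspot_truth")
}

#' Ground-truth hotspots as a window panel
#'
#' @param hotspots a `hotspot_truth`.
#' @param name panel name.
#' @return A `window_panel` (ranked by Dirichlet weight).
#' @export
truth_panel <- function(hotspots, name = "planted_hotspots") {
  w <- hotspots$windows
  o <- order(-hotspots$weights)
  window_panel(data.frame(chrom = w$chrom[o], start = w$start[o],
                          end = w$end[o], width = hotspots$width,
                          gene = w$gene[o], capture_count = 0L,
                          rank = seq_len(nrow(w))),
               name = name, source_cohort = "synthetic")
}

# complement of the hotspot windows within the footprint, 1-based inclusive
.background_intervals <- function(footprint, hotspots) {
  r <- footprint$regions
  out <- list()
  for (ch in unique(.norm_chrom(r$chrom))) {
    ri <- .norm_chrom(r$chrom) == ch
    fp <- IRanges::reduce(IRanges::IRanges(r$start[ri] + 1L, r$end[ri]))
    hi <- .norm_chrom(hotspots$windows$chrom) == ch
    bg <- if (any(hi)) {
      IRanges::setdiff(fp, IRanges::IRanges(hotspots$windows$start[hi],
                                            hotspots$windows$end[hi]))
    } else fp
    if (length(bg)) {
      out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(bg),
                              end = IRanges::end(bg))
    }
  }
  do.call(rbind, out)
}

#' Generate a synthetic mutation cohort
#'
#' Per sample, a negative-binomial total mutation count; each mutation
#' independently lands in a planted hotspot with probability
#' `hotspot_weight * multiplier` (hotspot chosen by its Dirichlet weight,
#' position uniform within the window), otherwise uniformly over the
#' remaining footprint. Ref/alt bases are uniform over valid substitutions.
#'
#' @param config a `sim_config`.
#' @param footprint from [generate_footprint()].
#' @param hotspots from [plant_hotspots()].
#' @param cohort_name cohort label; looked up in
#'   `config$cohort_multipliers` (absent = multipliers of 1).
#' @param n_samples number of samples.
#' @param seed seed for this cohort's draw (default: master seed).
#' @return list with `catalog` (a `mutation_catalog`) and `truth` (list:
#'   `hotspots`, `totals`, `sample_ids`, `in_hotspot` logical per record).
#' @export
generate_cohort <- function(config, footprint, hotspots, cohort_name,
                            n_samples, seed = config$seed) {
  mult <- config$cohort_multipliers[[cohort_name]]
  m_hot <- if (is.null(mult$hotspot)) 1 else mult$hotspot
  m_bur <- if (is.null(mult$burden)) 1 else mult$burden
  w_eff <- config$hotspot_weight * m_hot
  if (w_eff >= 1) {
    stop("cohort multiplier makes effective hotspot weight >= 1")
  }
  set.seed(as.integer(seed))
  sample_ids <- sprintf("%s_%04d", cohort_name, seq_len(n_samples))
  totals <- rnbinom(n_samples, size = config$burden_dispersion,
                    mu = config$burden_mean * m_bur)
  m_total <- sum(totals)
  bg <- .background_intervals(footprint, hotspots)
  bg_w <- bg$end - bg$start + 1L
  is_hot <- rbinom(m_total, 1L, w_eff) == 1L
  chrom <- character(m_total)
  pos <- integer(m_total)
  if (any(is_hot)) {
    hi <- sample.int(length(hotspots$weights), sum(is_hot), replace = TRUE,
                     prob = hotspots$weights)
    chrom[is_hot] <- hotspots$windows$chrom[hi]
    pos[is_hot] <- hotspots$windows$start[hi] +
      (sample.int(hotspots$width, sum(is_hot), replace = TRUE) - 1L)
  }
  if (any(!is_hot)) {
    bi <- sample.int(nrow(bg), sum(!is_hot), replace = TRUE, prob = bg_w)
    chrom[!is_hot] <- bg$chrom[bi]
    pos[!is_hot] <- bg$start[bi] +
      (floor(runif(sum(!is_hot)) * bg_w[bi]))
  }
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, m_total, replace = TRUE)
  alt_i <- ((ref_i - 1L + sample.int(3L, m_total, replace = TRUE)) %% 4L) + 1L
  rec <- data.frame(
    sample_id = rep(sample_ids, times = totals),
    chrom = chrom, pos = pos, ref = bases[ref_i], alt = bases[alt_i],
    gene = ""
  )
  list(
    catalog = mutation_catalog(rec, cohort_name, n_samples = n_samples),
    truth = list(hotspots = hotspots, totals = stats::setNames(totals, sample_ids),
                 sample_ids = sample_ids, in_hotspot = is_hot)
  )
}

#' Generate clinical covariates for labeled samples
#'
#' Age is normal per risk label, truncated to [30, 95] by resampling; sex
#' is Bernoulli(0.5); smoking category follows the per-label probabilities.
#'
#' @param config a `sim_config`.
#' @param sample_ids character vector.
#' @param labels `"low"`/`"high"` per sample.
#' @param seed seed for this draw (default: master seed).
#' @return A `clinical_table` data.frame.
#' @export
generate_clinical <- function(config, sample_ids, labels, seed = config$seed) {
  stopifnot(length(sample_ids) == length(labels),
            all(labels %in% c("low", "high")))
  set.seed(as.integer(seed))
  n <- length(sample_ids)
  age <- rnorm(n, mean = config$age_means[labels], sd = config$age_sd)
  for (it in seq_len(100L)) {
    bad <- age < 30 | age > 95
    if (!any(bad)) break
    age[bad] <- rnorm(sum(bad), mean = config$age_means[labels[bad]],
                      sd = config$age_sd)
  }
  age <- pmin(pmax(age, 30), 95)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  smoking <- vapply(labels, function(lb) {
    p <- config$smoking_probs[[lb]]
    sample(names(p), 1L, prob = p)
  }, character(1))
  out <- data.frame(sample_id = sample_ids, risk_label = labels,
                    age = round(age, 1), sex = sex, smoking = smoking,
                    row.names = NULL)
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Canonical configuration for a normal-urothelium risk study
#'
#' Histologically normal urothelium carries far fewer somatic mutations
#' than tumor tissue and concentrates them less strongly in hotspots, so
#' the risk-study conditions lower the per-sample burden (NB mean 10) and
#' the base hotspot weight (0.10; the high-risk multiplier of 3 raises it
#' to 0.30). High-risk samples (bladder-cancer patients) are on average 10
#' years older (within-label sd 6) and much more often ever-smokers than
#' low-risk donors — in this regime personal risk factors, led by age, are
#' the strongest predictors, with hotspot burden adding on top.
#'
#' @param seed integer master seed.
#' @return A `sim_config`.
#' @export
risk_config <- function(seed = 1L) {
  sim_config(seed = seed, hotspot_weight = 0.1, burden_mean = 10, age_sd = 6)
}

#' Generate a full high/low-risk study
#'
#' Convenience wrapper producing everything risk modeling needs: a shared
#' footprint and planted-hotspot architecture, a low-risk and a high-risk
#' cohort (the high-risk cohort uses the `high` cohort multipliers, by
#' default 3x hotspot weight), pooled into one catalog, plus a clinical
#' table and the ground-truth hotspot panel.
#'
#' @param config a `sim_config`; defaults to [risk_config()].
#' @param n_low,n_high cohort sizes (defaults 483 and 233, the scale of
#'   published low/high-risk normal-urothelium cohorts).
#' @return list with `footprint`, `hotspots`, `catalog` (pooled, cohort
#'   "pooled"), `clinical`, `panel` (ground-truth hotspot panel), `truths`.
#' @export
generate_risk_study <- function(config = risk_config(), n_low = 483L, n_high = 233L) {
  fp <- generate_footprint(config)
  hs <- plant_hotspots(config, fp, seed = config$seed + 1L)
  low <- generate_cohort(config, fp, hs, "low", n_low, seed = config$seed + 2L)
  high <- generate_cohort(config, fp, hs, "high", n_high, seed = config$seed + 3L)
  rec <- rbind(low$catalog$records, high$catalog$records)
  pooled <- mutation_catalog(rec, "pooled", n_samples = n_low + n_high)
  ids <- c(low$truth$sample_ids, high$truth$sample_ids)
  labels <- rep(c("low", "high"), c(n_low, n_high))
  clin <- generate_clinical(config, ids, labels, seed = config$seed + 4L)
  list(footprint = fp, hotspots = hs, catalog = pooled, clinical = clin,
       panel = truth_panel(hs), truths = list(low = low$truth, high = high$truth))
}
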