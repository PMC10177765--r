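#' Construct a mutation catalog
#'
#' A mutation catalog holds a cohort's somatic single-nucleotide variants,
#' one record per called SNV, plus the cohort's sample count. `n_samples`
#' may exceed the number of distinct sample identifiers among the records:
#' samples with zero mutations are still part of the cohort and must enter
#' per-sample averages.
#'
#' @param records data.frame with columns `sample_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `gene`.
#' @param cohort_name character scalar naming the cohort.
#' @param n_samples integer; defaults to the number of distinct `sample_id`.
#' @return An object of class `mutation_catalog`.
#' @export
mutation_catalog <- function(records, cohort_name = "", n_samples = NULL) {
  req <- c("sample_id", "chrom", "pos", "ref", "alt", "gene")
  if (nrow(records) == 0L) {
    records <- data.frame(sample_id = character(0), chrom = character(0),
                          pos = integer(0), ref = character(0),
                          alt = character(0), gene = character(0))
  }
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, req]
  records$pos <- as.integer(records$pos)
  if (nrow(records)) {
    stopifnot(all(records$pos >= 1L), all(nchar(records$chrom) > 0L),
              all(records$ref != records$alt))
  }
  n_distinct <- length(unique(records$sample_id))
  if (is.null(n_samples)) n_samples <- n_distinct
  n_samples <- as.integer(n_samples)
  if (n_samples < n_distinct) {
    stop("n_samples (", n_samples, ") is smaller than the number of distinct sample_id (",
         n_distinct, ")")
  }
  structure(list(records = records, cohort_name = cohort_name,
                 n_samples = n_samples),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("mutation_catalog '%s': %d SNV records, %d samples\n",
              x$cohort_name, nrow(x$records), x$n_samples))
  invisible(x)
}

#' Construct a region set
#'
#' Target intervals (e.g. the exon footprint of a sequencing panel) in BED
#' convention: 0-based start, exclusive end.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `gene`, `label`.
#' @param name character name for the set.
#' @return An object of class `region_set`.
#' @export
region_set <- function(regions, name = "") {
  if (!all(c("chrom", "start", "end") %in% names(regions))) {
    stop("regions needs columns chrom, start, end")
  }
  if (is.null(regions$gene)) regions$gene <- ""
  if (is.null(regions$label)) regions$label <- ""
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (nrow(regions) && any(regions$start < 0L | regions$start >= regions$end)) {
    stop("regions must satisfy 0 <= start < end")
  }
  structure(list(regions = regions[, c("chrom", "start", "end", "gene", "label")],
                 name = name),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d regions, merged width %d bp\n",
              x$name, nrow(x$regions), region_width(x)))
  invisible(x)
}

#' Total width of a region set after merging overlaps
#'
#' @param footprint a `region_set`.
#' @return Integer total bp covered.
#' @export
region_width <- function(footprint) {
  r <- footprint$regions
  if (nrow(r) == 0L) return(0L)
  tot <- 0L
  for (ch in unique(.norm_chrom(r$chrom))) {
    i <- .norm_chrom(r$chrom) == ch
    ir <- IRanges::reduce(IRanges::IRanges(start = r$start[i] + 1L, end = r$end[i]))
    tot <- tot + sum(IRanges::width(ir))
  }
  as.integer(tot)
}

#' Read a mutation catalog from a tab-delimited table
#'
#' Two dialects are supported. `simple-tsv` expects columns
#' `sample`, `chrom`, `pos`, `ref`, `alt` and optionally `gene`;
#' `maf-like` expects `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2` and optionally `Hugo_Symbol`.
#' Only single-nucleotide substitutions are retained; indel and multi-base
#' rows are dropped with a message stating the count. Duplicate rows are
#' kept (see [dedup_catalog()] for explicit deduplication).
#'
#' @param path path to the tab-delimited file (with header).
#' @param dialect `"simple-tsv"` or `"maf-like"`.
#' @param cohort_name cohort label stored on the catalog.
#' @param n_samples optional externally known sample count (e.g. from a
#'   clinical table) so zero-mutation samples stay counted.
#' @return A [mutation_catalog()].
#' @export
read_mutations <- function(path, dialect = c("simple-tsv", "maf-like"),
                           cohort_name = basename(path), n_samples = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  tab <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
               comment.char = "#", check.names = FALSE),
    error = function(e) NULL
  )
  if (is.null(tab) || nrow(tab) == 0L) {
    warning("empty mutation table: ", path)
    return(mutation_catalog(data.frame(), cohort_name, n_samples))
  }
  colmap <- switch(dialect,
    "simple-tsv" = c(sample_id = "sample", chrom = "chrom", pos = "pos",
                     ref = "ref", alt = "alt", gene = "gene"),
    "maf-like" = c(sample_id = "Tumor_Sample_Barcode", chrom = "Chromosome",
                   pos = "Start_Position", ref = "Reference_Allele",
                   alt = "Tumor_Seq_Allele2", gene = "Hugo_Symbol")
  )
  required <- colmap[c("sample_id", "chrom", "pos", "ref", "alt")]
  for (col in required) {
    if (!col %in% names(tab)) {
      stop("mutation table ", path, " is missing required column '", col,
           "' for dialect ", dialect)
    }
  }
  gene <- if (colmap[["gene"]] %in% names(tab)) tab[[colmap[["gene"]]]] else ""
  rec <- data.frame(
    sample_id = tab[[colmap[["sample_id"]]]],
    chrom = tab[[colmap[["chrom"]]]],
    pos = suppressWarnings(as.integer(tab[[colmap[["pos"]]]])),
    ref = toupper(tab[[colmap[["ref"]]]]),
    alt = toupper(tab[[colmap[["alt"]]]]),
    gene = gene
  )
  is_snv <- !is.na(rec$pos) & rec$pos >= 1L &
    rec$ref %in% c("A", "C", "G", "T") & rec$alt %in% c("A", "C", "G", "T") &
    rec$ref != rec$alt
  n_dropped <- sum(!is_snv)
  if (n_dropped > 0L) {
    message("read_mutations: dropped ", n_dropped, " non-SNV row(s)")
  }
  mutation_catalog(rec[is_snv, , drop = FALSE], cohort_name, n_samples)
}

#' Write a mutation catalog as simple-tsv
#'
#' Round-trips with `read_mutations(dialect = "simple-tsv")`.
#'
#' @param catalog a `mutation_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(catalog, path) {
  out <- catalog$records
  names(out)[names(out) == "sample_id"] <- "sample"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove duplicated mutation records
#'
#' Deduplication is deliberately a separate explicit step: merged public
#' catalogs can contain the same call twice and whether that is signal or
#' artifact is a dataset-level judgement.
#'
#' @param catalog a `mutation_catalog`.
#' @return A `mutation_catalog` with exact duplicate rows removed.
#' @export
dedup_catalog <- function(catalog) {
  keep <- !duplicated(catalog$records)
  mutation_catalog(catalog$records[keep, , drop = FALSE],
                   catalog$cohort_name, catalog$n_samples)
}

#' Read target regions from a BED file
#'
#' BED is 0-based half-open. An optional 4th column becomes the gene label.
#'
#' @param path path to a BED file (3+ whitespace-delimited columns, no header).
#' @param name name for the region set.
#' @return A [region_set()].
#' @export
read_regions <- function(path, name = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(region_set(data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0)), name))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED line ", which(nf < 3L)[1L], " has fewer than 3 columns")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.integer(vapply(fields, `[`, "", 2L))
  end <- as.integer(vapply(fields, `[`, "", 3L))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop("BED line ", bad[1L], ": start must be < end")
  }
  gene <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), "")
  score <- ifelse(nf >= 5L, vapply(fields, function(f) f[min(5L, length(f))], ""), "")
  region_set(data.frame(chrom = chrom, start = start, end = end,
                        gene = gene, label = score), name)
}

#' Restrict a catalog to a sequencing footprint
#'
#' Keeps exactly the records whose position lies inside some region. A
#' 1-based position p is inside the 0-based half-open region `[start, end)`
#' iff `start < p <= end`. `n_samples` is unchanged: samples whose mutations
#' all fall outside the footprint drop to zero mutations but remain counted.
#'
#' @param catalog a `mutation_catalog`.
#' @param footprint a `region_set`.
#' @return A `mutation_catalog` of the retained records, with attribute
#'   `n_dropped` giving the number of records removed.
#' @export
restrict_to_regions <- function(catalog, footprint) {
  rec <- catalog$records
  if (nrow(rec) == 0L) {
    out <- catalog
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  r <- footprint$regions
  hits <- .overlap_pairs(rec$chrom, rec$pos, rec$pos,
                         r$chrom, r$start + 1L, r$end)
  keep <- sort(unique(hits$q))
  out <- mutation_catalog(rec[keep, , drop = FALSE],
                          catalog$cohort_name, catalog$n_samples)
  attr(out, "n_dropped") <- nrow(rec) - length(keep)
  out
}

#' Read a clinical covariate table
#'
#' CSV with columns `sample_id`, `risk_label` (`high`/`low`), `age`, `sex`
#' (`male`/`female`), `smoking` (`never`/`former`/`current`/`unknown`).
#'
#' @param path CSV path.
#' @return data.frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "risk_label", "age", "sex", "smoking")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop("clinical table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in clinical table")
  if (any(!is.na(tab$age) & tab$age <= 0)) stop("age must be positive")
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

#' Write a clinical table as CSV
#' @param clinical data.frame as from [read_clinical()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(as.data.frame(clinical), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a window panel as BED
#'
#' One line per window: chrom, 0-based start, exclusive end, `gene:rank`
#' name, mutation capture count as score. Windows are stored 1-based
#' inclusive; the BED line for a window `[s, e]` is `s-1, e`.
#'
#' @param panel a `window_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  w <- panel$windows
  if (nrow(w) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s:%d\t%d",
                   w$chrom, w$start - 1L, w$end,
                   ifelse(nzchar(w$gene), w$gene, "."), w$rank,
                   w$capture_count)
  writeLines(lines, path)
  invisible(path)
}
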