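#' Read a beta matrix from TSV
#'
#' Expects a tab-separated file whose first column holds CpG site ids and whose
#' remaining columns hold one sample each (sample ids in the header). The
#' loader is strict: non-numeric cells, values outside \[0, 1\], duplicated
#' ids and missing values are load errors that name the offending cell —
#' values are never silently coerced or imputed.
#'
#' @param path Path to a TSV file.
#' @return A [beta_matrix()] with row and column order preserved from file.
#' @export
read_beta_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("beta matrix TSV needs a site_id column plus >= 1 sample column")
  ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals), dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(num))
    abort(sprintf("non-numeric beta value '%s' at site '%s', sample '%s'",
                  vals[bad[1]], ids[i[1]], colnames(vals)[i[2]]))
  }
  rownames(num) <- ids
  beta_matrix(num)
}

#' Write a beta matrix to TSV
#'
#' @param beta A [beta_matrix()].
#' @param path Output path.
#' @param digits Significant digits used when printing beta-values.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, digits = 15) {
  df <- tibble(site_id = site_ids(beta))
  vals <- as.data.frame(signif(unclass(beta), digits))
  readr::write_tsv(dplyr::bind_cols(df, vals), path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' The sheet must carry `sample_id`, `group`, `sex`, `age` and `serology`
#' columns (see [validate_sample_sheet()]); any columns whose names match
#' known cell-type labels are read as cell-proportion annotations.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    sex = readr::col_character(),
    age = readr::col_double(),
    serology = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_sample_sheet(sheet)
}

#' Write a sample sheet to CSV
#'
#' @param sheet A sample-sheet tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(validate_sample_sheet(sheet), path, progress = FALSE)
  invisible(path)
}

#' Read a CpG annotation table from TSV
#'
#' @param path Path to a TSV with columns `site_id`, `chromosome`, `position`
#'   (1-based), `gene_symbol` (possibly empty), `gene_region`,
#'   `island_relation`.
#' @return A validated annotation tibble.
#' @export
read_cpg_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    chromosome = readr::col_character(),
    position = readr::col_double(),
    gene_symbol = readr::col_character(),
    gene_region = readr::col_character(),
    island_relation = readr::col_character()
  ), progress = FALSE)
  ann$gene_symbol[is.na(ann$gene_symbol)] <- ""
  validate_cpg_annotation(ann)
}

#' Write a CpG annotation table to TSV
#'
#' @param annotation Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_annotation <- function(annotation, path) {
  readr::write_tsv(validate_cpg_annotation(annotation), path, progress = FALSE)
  invisible(path)
}

#' Read a chromatin-mark peak track from BED
#'
#' Reads a BED3+ file of peak calls for one chromatin mark (e.g. H3K4me3,
#' H3K27ac, DHS) in one reference cell type. Intervals are stored in the
#' 0-based half-open BED convention exactly as read; conversion to 1-based
#' CpG coordinates happens only inside the overlap logic
#' ([chromatin_overlap()]).
#'
#' @param path Path to a BED file (>= 3 columns, no header).
#' @param mark_name Chromatin-mark label.
#' @param cell_type Reference cell-type label.
#' @return A `chromatin_track`: a tibble of intervals (`chromosome`, `start`,
#'   `end`) with `mark_name` and `cell_type` attributes.
#' @export
read_bed_track <- function(path, mark_name = "mark", cell_type = "unknown") {
  bed <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           X1 = readr::col_character(),
                           X2 = readr::col_double(),
                           X3 = readr::col_double(),
                           .default = readr::col_character()
                         ))
  if (ncol(bed) < 3) abort("BED track needs >= 3 columns (chrom, start, end)")
  chromatin_track(
    tibble(chromosome = bed$X1, start = bed$X2, end = bed$X3),
    mark_name = mark_name, cell_type = cell_type
  )
}

#' @rdname read_bed_track
#' @param intervals Tibble with `chromosome`, `start`, `end` (0-based
#'   half-open).
#' @export
chromatin_track <- function(intervals, mark_name = "mark", cell_type = "unknown") {
  intervals <- as_tibble(intervals)
  bad <- which(intervals$start >= intervals$end)
  if (length(bad) > 0) {
    abort(sprintf("interval with start >= end at line %d: %s %s %s",
                  bad[1], intervals$chromosome[bad[1]],
                  format(intervals$start[bad[1]]), format(intervals$end[bad[1]])))
  }
  if (any(intervals$start < 0)) abort("negative interval start")
  structure(intervals,
            mark_name = mark_name, cell_type = cell_type,
            class = c("chromatin_track", class(intervals)))
}

#' Write a chromatin track to BED
#'
#' @param track A `chromatin_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(track, path) {
  readr::write_tsv(as_tibble(track)[, c("chromosome", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write an EWAS result or DMC set to TSV
#'
#' Columns are written in a stable order — `site_id`, `chromosome`,
#' `position`, `gene_symbol`, per-group mean beta, `delta_beta`,
#' `coefficient`, `se`, `p`, then flags (`direction`, significance) — so the
#' files diff cleanly across runs. p-values are printed with 6 significant
#' digits.
#'
#' @param result An `ewas_result` or `dmc_set` tibble.
#' @param path Output path.
#' @param annotation Optional annotation tibble; when supplied, chromosome,
#'   position and gene symbol are joined in.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(result, path, annotation = NULL) {
  df <- as_tibble(result)
  if (!is.null(annotation)) {
    ann <- as_tibble(annotation)[, c("site_id", "chromosome", "position", "gene_symbol")]
    df <- left_join(df, ann, by = "site_id")
  } else {
    if (!"chromosome" %in% names(df)) df$chromosome <- NA_character_
    if (!"position" %in% names(df)) df$position <- NA_real_
    if (!"gene_symbol" %in% names(df)) df$gene_symbol <- NA_character_
  }
  lead <- c("site_id", "chromosome", "position", "gene_symbol",
            "mean_case", "mean_reference", "delta_beta", "coefficient", "se", "p")
  ordered <- c(intersect(lead, names(df)), setdiff(names(df), lead))
  df <- df[, ordered]
  for (col in intersect(c("p", "coefficient", "se", "delta_beta"), names(df))) {
    df[[col]] <- signif(df[[col]], 6)
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble with the written columns.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    chromosome = readr::col_character(),
    gene_symbol = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
}
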