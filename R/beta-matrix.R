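#' Construct a beta matrix
#'
#' A beta matrix holds methylation fractions (beta-values) for CpG sites in
#' rows and samples in columns. Values are unitless fractions in \[0, 1\];
#' missing values are not permitted (the post-QC universe of an array study
#' is complete, and imputation is out of scope).
#'
#' @param values Numeric matrix of beta-values, sites x samples.
#' @param site_ids Character vector of unique CpG identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids Character vector of unique sample identifiers (defaults
#'   to `colnames(values)`).
#'
#' @return A `beta_matrix`: a numeric matrix with class attribute, site ids as
#'   row names and sample ids as column names.
#' @examples
#' bm <- beta_matrix(matrix(runif(6), 3, 2,
#'   dimnames = list(paste0("cg", 1:3), c("s1", "s2"))))
#' dim(bm)
#' @export
beta_matrix <- function(values, site_ids = rownames(values),
                        sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (sites x samples).")
  }
  if (is.null(site_ids) || is.null(sample_ids)) {
    abort("site and sample identifiers are required (row/column names or arguments).")
  }
  site_ids <- as.character(site_ids)
  sample_ids <- as.character(sample_ids)
  if (length(site_ids) != nrow(values)) abort("length(site_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values)) abort("length(sample_ids) != ncol(values)")
  dimnames(values) <- list(site_ids, sample_ids)
  validate_beta_values(values)
  structure(values, class = c("beta_matrix", class(matrix())))
}

validate_beta_values <- function(values) {
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) {
    abort(paste0("duplicate site_id(s): ", paste(head(unique(dup), 5), collapse = ", ")))
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup) > 0) {
    abort(paste0("duplicate sample_id(s): ", paste(head(unique(dup), 5), collapse = ", ")))
  }
  bad <- which(!is.finite(values) | values < 0 | values > 1)
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(values))
    abort(sprintf(
      "beta value out of [0,1] or missing at site '%s', sample '%s' (value: %s); %d offending cell(s) in total",
      rownames(values)[i[1]], colnames(values)[i[2]],
      format(values[bad[1]]), length(bad)
    ))
  }
  invisible(values)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d CpG sites x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf(
    "  beta range: [%.3f, %.3f]  first sites: %s\n",
    min(x), max(x), paste(head(rownames(x), 3), collapse = ", ")
  ))
  invisible(x)
}

#' @describeIn beta_matrix Long-format tibble (site_id, sample_id, beta).
#' @param x A `beta_matrix`.
#' @param ... Unused.
#' @method as_tibble beta_matrix
#' @export
as_tibble.beta_matrix <- function(x, ...) {
  tibble(
    site_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    beta = as.vector(unclass(x))
  )
}

#' @export
`[.beta_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("beta_matrix", class(matrix()))
  out
}

site_ids <- function(x) rownames(x)
sample_ids <- function(x) colnames(x)

#' Validate a sample sheet against a beta matrix
#'
#' A sample sheet is a tibble with one row per sample and columns `sample_id`,
#' `group` (one of `control`, `disease_A`, `disease_B`), `sex` (`F`/`M`),
#' `age` (years, > 0) and `serology` (`positive`/`negative` for `disease_B`
#' samples, `not_applicable` otherwise — the analogue of Ro/SSA / La/SSB
#' autoantibody status).
#'
#' @param sheet A data frame with the columns above.
#' @param beta Optional `beta_matrix`; if supplied, sample sets must match
#'   exactly.
#' @return The validated sheet as a tibble, invisibly usable downstream.
#' @export
validate_sample_sheet <- function(sheet, beta = NULL) {
  required <- c("sample_id", "group", "sex", "age", "serology")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  sheet <- as_tibble(sheet)
  sheet$sample_id <- as.character(sheet$sample_id)
  if (anyDuplicated(sheet$sample_id)) {
    abort(paste0(
      "duplicate sample_id(s) in sheet: ",
      paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", ")
    ))
  }
  bad_group <- setdiff(unique(sheet$group), c("control", "disease_A", "disease_B"))
  if (length(bad_group) > 0) {
    abort(paste0("unknown group label(s): ", paste(bad_group, collapse = ", ")))
  }
  bad_sex <- setdiff(unique(sheet$sex), c("F", "M"))
  if (length(bad_sex) > 0) abort(paste0("unknown sex label(s): ", paste(bad_sex, collapse = ", ")))
  if (!is.numeric(sheet$age) || any(!is.finite(sheet$age)) || any(sheet$age <= 0)) {
    abort("`age` must be finite and > 0 (years)")
  }
  bad_ser <- setdiff(unique(sheet$serology), c("positive", "negative", "not_applicable"))
  if (length(bad_ser) > 0) {
    abort(paste0("unknown serology label(s): ", paste(bad_ser, collapse = ", ")))
  }
  offside <- sheet$group != "disease_B" & sheet$serology != "not_applicable"
  if (any(offside)) {
    abort(paste0(
      "serology must be 'not_applicable' outside disease_B; offending sample(s): ",
      paste(head(sheet$sample_id[offside], 5), collapse = ", ")
    ))
  }
  if (!is.null(beta)) {
    only_beta <- setdiff(sample_ids(beta), sheet$sample_id)
    only_sheet <- setdiff(sheet$sample_id, sample_ids(beta))
    if (length(only_beta) > 0 || length(only_sheet) > 0) {
      abort(sprintf(
        "sample sets differ: %d sample(s) only in beta matrix (%s), %d only in sheet (%s)",
        length(only_beta), paste(head(only_beta, 3), collapse = ", "),
        length(only_sheet), paste(head(only_sheet, 3), collapse = ", ")
      ))
    }
  }
  sheet
}

#' Validate a CpG annotation table
#'
#' Annotation rows carry, per CpG site, the chromosome, the 1-based base-pair
#' position (Illumina-manifest convention), an optional gene symbol, the gene
#' region class and the CpG-island relation class. Only autosomes (chr1-22)
#' are accepted.
#'
#' @param annotation Data frame with columns `site_id`, `chromosome`,
#'   `position`, `gene_symbol`, `gene_region`, `island_relation`.
#' @return The validated annotation as a tibble.
#' @export
validate_cpg_annotation <- function(annotation) {
  required <- c("site_id", "chromosome", "position", "gene_symbol",
                "gene_region", "island_relation")
  missing_cols <- setdiff(required, names(annotation))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  annotation <- as_tibble(annotation)
  if (anyDuplicated(annotation$site_id)) abort("duplicate site_id(s) in annotation")
  autosomes <- paste0("chr", 1:22)
  bad_chr <- setdiff(unique(annotation$chromosome), autosomes)
  if (length(bad_chr) > 0) {
    abort(paste0("non-autosomal or unknown chromosome(s): ", paste(bad_chr, collapse = ", ")))
  }
  if (any(!is.finite(annotation$position)) || any(annotation$position < 1)) {
    abort("`position` must be a 1-based coordinate >= 1")
  }
  bad_region <- setdiff(unique(annotation$gene_region), gene_region_levels())
  if (length(bad_region) > 0) {
    abort(paste0("unknown gene_region class(es): ", paste(bad_region, collapse = ", ")))
  }
  bad_island <- setdiff(unique(annotation$island_relation), island_relation_levels())
  if (length(bad_island) > 0) {
    abort(paste0("unknown island_relation class(es): ", paste(bad_island, collapse = ", ")))
  }
  annotation
}

gene_region_levels <- function() {
  c("TSS1500", "TSS200", "UTR5", "FirstExon", "Body", "UTR3", "intergenic")
}

island_relation_levels <- function() {
  c("Island", "Shore", "Shelf", "OpenSea")
}
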