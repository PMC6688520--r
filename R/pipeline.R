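#' Configuration for a full cross-comparative run
#'
#' Bundles everything one end-to-end run needs: either a
#' [simulation_design()] (the default: a synthetic cohort) or paths to real
#' inputs (beta matrix TSV, sample sheet CSV, annotation TSV, and optionally
#' a reference-profile TSV), the DMC thresholds, the disease anchoring the
#' sharing cutoff, the deconvolution marker count, the CV design, and a
#' global seed that expands into per-stage seeds by fixed offsets (so a
#' single stage can be re-run reproducibly).
#'
#' @param design A [simulation_design()] (ignored when `beta_path` is set).
#' @param beta_path,sheet_path,annotation_path,reference_path Optional input
#'   file paths for a real-data run.
#' @param alpha Family-wise significance level (default 0.05).
#' @param delta_cutoff `|delta_beta|` cutoff for DMC calling.
#' @param reference_disease Disease whose DMC count anchors the sharing
#'   cutoff (`"A"` or `"B"`).
#' @param n_per_type Deconvolution markers per direction per cell type.
#' @param cv A [cv_design()].
#' @param mds_genes Gene symbols defining the signature MDS panel (default:
#'   a ten-gene interferon-regulated module).
#' @param output_dir Directory for stage outputs (created); `NULL` keeps
#'   everything in memory.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(design = simulation_design(),
                       beta_path = NULL, sheet_path = NULL,
                       annotation_path = NULL, reference_path = NULL,
                       alpha = 0.05, delta_cutoff = 0.05,
                       reference_disease = "A",
                       n_per_type = 50,
                       cv = cv_design(),
                       mds_genes = c("IFI44L", "IFIT1", "IFITM1", "IFITM3",
                                     "IRF7", "MX1", "OAS1", "PARP9",
                                     "PLSCR1", "RSAD2"),
                       output_dir = NULL, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (delta_cutoff <= 0 || delta_cutoff >= 1) abort("delta_cutoff must be in (0, 1)")
  seed <- as.integer(seed)
  design$seed <- seed
  cv$seed <- seed + 2000L
  structure(list(
    design = design, beta_path = beta_path, sheet_path = sheet_path,
    annotation_path = annotation_path, reference_path = reference_path,
    alpha = alpha, delta_cutoff = delta_cutoff,
    reference_disease = reference_disease, n_per_type = n_per_type,
    cv = cv, mds_genes = mds_genes, output_dir = output_dir, seed = seed
  ), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Reads a `key: value` YAML file whose top-level keys mirror the
#' [run_config()] arguments, with `design:` and `cv:` as nested blocks of
#' [simulation_design()] resp. [cv_design()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- do.call(simulation_design, y$design %||% list())
  cv <- do.call(cv_design, y$cv %||% list())
  args <- y[setdiff(names(y), c("design", "cv"))]
  do.call(run_config, c(list(design = design, cv = cv), args))
}

#' Run the full cross-comparative pipeline
#'
#' Executes the study workflow in dependency order: cohort simulation (or
#' input loading), reference-based cell-proportion estimation, the two
#' case-control EWASs, the shared/unique cross-comparison and direct
#' case-case comparison, signature MDS with serology stratification,
#' functional-region enrichment of the case-case DMCs, and the four
#' random-forest disease predictions. When `output_dir` is set, each
#' stage's tables are written before the next stage starts and a
#' machine-readable `summary.json` is written last; a rerun with the same
#' configuration and seed reproduces the summary exactly.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return A `run_summary` list (also serialised to JSON when `output_dir`
#'   is set), carrying all stage objects in its `objects` element.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  t_all <- Sys.time()
  log_stage <- function(stage, t0, ...) {
    if (!quiet) {
      message(sprintf("[%s] %s (%.1fs) %s", format(Sys.time(), "%H:%M:%S"),
                      stage, as.numeric(Sys.time() - t0, units = "secs"),
                      paste0(..., collapse = " ")))
    }
  }
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, name, writer = readr::write_tsv) {
    if (!is.null(out_dir)) writer(as_tibble(obj), file.path(out_dir, name))
  }

  # -- inputs: simulate or load ------------------------------------------
  t0 <- Sys.time()
  if (!is.null(config$beta_path)) {
    beta <- read_beta_matrix(config$beta_path)
    sheet <- read_sample_sheet(config$sheet_path)
    annotation <- read_cpg_annotation(config$annotation_path)
    reference <- if (!is.null(config$reference_path)) {
      ref_tbl <- readr::read_tsv(config$reference_path,
                                 col_types = readr::cols(site_id = readr::col_character(),
                                                         .default = readr::col_double()),
                                 progress = FALSE)
      m <- as.matrix(ref_tbl[, -1]); rownames(m) <- ref_tbl$site_id
      structure(m, class = c("reference_profiles", class(matrix())))
    } else {
      abort("a reference-profile table is required for real-data runs")
    }
    truth <- NULL
    log_stage("load", t0, sprintf("%d sites x %d samples", nrow(beta), ncol(beta)))
  } else {
    sim <- simulate_cohort(config$design)
    beta <- sim$beta; sheet <- sim$sheet; annotation <- sim$annotation
    reference <- sim$reference; truth <- sim$truth
    if (!is.null(out_dir)) {
      write_beta_matrix(beta, file.path(out_dir, "beta_matrix.tsv"), digits = 6)
      write_sample_sheet(sheet, file.path(out_dir, "sample_sheet.csv"))
      write_cpg_annotation(annotation, file.path(out_dir, "annotation.tsv"))
      readr::write_tsv(truth, file.path(out_dir, "ground_truth.tsv"))
    }
    log_stage("simulate", t0, sprintf("%d sites x %d samples", nrow(beta), ncol(beta)))
  }

  # -- cell composition ---------------------------------------------------
  t0 <- Sys.time()
  marker_sites <- select_discriminating_sites(reference, config$n_per_type)
  proportions <- estimate_proportions(beta, reference, marker_sites)
  if (!is.null(out_dir)) {
    readr::write_csv(as_tibble(proportions), file.path(out_dir, "cell_proportions.csv"))
  }
  log_stage("deconvolve", t0, sprintf("%d marker sites", length(marker_sites)))

  # -- case-control EWASs -------------------------------------------------
  t0 <- Sys.time()
  ewas_A <- run_ewas(beta, sheet, "disease_A", "control", proportions)
  ewas_B <- run_ewas(beta, sheet, "disease_B", "control", proportions)
  if (!is.null(out_dir)) {
    write_results_table(ewas_A, file.path(out_dir, "ewas_A_vs_control.tsv"), annotation)
    write_results_table(ewas_B, file.path(out_dir, "ewas_B_vs_control.tsv"), annotation)
  }
  log_stage("ewas", t0)

  # -- cross-comparison ---------------------------------------------------
  t0 <- Sys.time()
  p_cutoff <- bonferroni_threshold(config$alpha, nrow(ewas_A))
  cross <- classify_cross_disease(ewas_A, ewas_B, p_cutoff, config$delta_cutoff,
                                  config$alpha, config$reference_disease)
  cc <- case_case_comparison(beta, sheet, proportions,
                             dmcs_A = cross$dmcs_A, dmcs_B = cross$dmcs_B,
                             delta_cutoff = config$delta_cutoff,
                             alpha = config$alpha)
  if (!is.null(out_dir)) {
    write_results_table(cross$dmcs_A, file.path(out_dir, "dmcs_A.tsv"), annotation)
    write_results_table(cross$dmcs_B, file.path(out_dir, "dmcs_B.tsv"), annotation)
  }
  emit(cross$shared, "shared_dmcs.tsv")
  emit(cross$unique_A, "unique_A.tsv"); emit(cross$unique_B, "unique_B.tsv")
  emit(cross$labels_A, "labels_A.tsv"); emit(cross$labels_B, "labels_B.tsv")
  emit(cc$dmcs, "dmcs_case_case.tsv")
  log_stage("crosscompare", t0,
            sprintf("%d/%d DMCs, %d shared, %d/%d unique, %d case-case",
                    nrow(cross$dmcs_A), nrow(cross$dmcs_B), nrow(cross$shared),
                    nrow(cross$unique_A), nrow(cross$unique_B), nrow(cc$dmcs)))

  # -- characterization ---------------------------------------------------
  t0 <- Sys.time()
  panel <- annotation$site_id[annotation$gene_symbol %in% config$mds_genes &
                                annotation$site_id %in% cross$shared$site_id]
  if (length(panel) == 0) {
    panel <- cross$shared |> arrange(.data$p_own) |> head(10) |> pull("site_id")
  }
  mds <- if (length(panel) > 0) mds_embed(beta, panel) else NULL
  enr_region <- if (nrow(cc$dmcs) > 0)
    regional_enrichment(cc$dmcs, annotation, "gene_region") else NULL
  enr_island <- if (nrow(cc$dmcs) > 0)
    regional_enrichment(cc$dmcs, annotation, "island_relation") else NULL
  strat <- if (length(panel) > 0) stratified_group_means(beta, sheet, panel) else NULL
  if (!is.null(mds)) emit(mds, "mds_coordinates.csv", readr::write_csv)
  if (!is.null(enr_region)) emit(enr_region, "enrichment_gene_region.tsv")
  if (!is.null(enr_island)) emit(enr_island, "enrichment_island_relation.tsv")
  if (!is.null(strat)) emit(strat, "stratified_means.tsv")
  log_stage("characterize", t0, sprintf("panel of %d sites", length(panel)))

  # -- classification -----------------------------------------------------
  t0 <- Sys.time()
  preds <- list(
    A_vs_control = crossval_predict(beta, sheet, "disease_A", "control", config$cv),
    B_vs_control = crossval_predict(beta, sheet, "disease_B", "control", config$cv),
    B_seropositive_vs_control = crossval_predict(beta, sheet, "disease_B", "control",
                                                 config$cv, serology_filter = "positive"),
    B_vs_A = crossval_predict(beta, sheet, "disease_B", "disease_A", config$cv)
  )
  if (!is.null(out_dir)) {
    for (nm in names(preds)) {
      readr::write_csv(preds[[nm]]$predictions,
                       file.path(out_dir, paste0("predictions_", nm, ".csv")))
    }
  }
  log_stage("predict", t0,
            paste(names(preds), sprintf("AUC=%.2f", vapply(preds, `[[`, 0, "mean_auc")),
                  collapse = ", "))

  summary <- list(
    seed = config$seed,
    version = as.character(utils::packageVersion("methcross")),
    n_sites = nrow(beta), n_samples = ncol(beta),
    group_sizes = as.list(table(sheet$group)),
    thresholds = list(
      alpha = config$alpha,
      p_cutoff = p_cutoff, p_cutoff_display = format_threshold(p_cutoff),
      delta_cutoff = config$delta_cutoff,
      shared_p_cutoff = cross$shared_p_cutoff,
      shared_p_cutoff_display = format_threshold(cross$shared_p_cutoff)
    ),
    counts = list(
      dmcs_A = nrow(cross$dmcs_A), dmcs_B = nrow(cross$dmcs_B),
      shared_from_A = nrow(cross$shared_from_A),
      shared_from_B = nrow(cross$shared_from_B),
      shared_combined = nrow(cross$shared),
      unique_A = nrow(cross$unique_A), unique_B = nrow(cross$unique_B),
      case_case = nrow(cc$dmcs),
      case_case_in_both = cc$overlap$n_in_both_case_control
    ),
    percentages = list(
      shared_hypo = summarize_directions(cross$shared)$pct_hypo,
      case_case_hypo = summarize_directions(cc$dmcs)$pct_hypo,
      case_case_in_both = cc$overlap$pct_in_both
    ),
    auc = lapply(preds, function(p)
      list(mean = p$mean_auc, pooled = p$pooled_auc,
           by_iteration = p$auc_by_iteration$auc)),
    wall_time_s = as.numeric(Sys.time() - t_all, units = "secs")
  )
  if (!is.null(out_dir)) {
    s <- summary
    s$wall_time_s <- NULL  # keep reruns byte-identical
    jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(c(summary, list(objects = list(
    beta = beta, sheet = sheet, annotation = annotation, truth = truth,
    proportions = proportions, ewas_A = ewas_A, ewas_B = ewas_B,
    cross = cross, case_case = cc, mds = mds, panel = panel,
    enrichment = list(gene_region = enr_region, island_relation = enr_island),
    stratified_means = strat, predictions = preds
  ))), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>\n")
  cat(sprintf("  %d sites x %d samples (seed %d)\n", x$n_sites, x$n_samples, x$seed))
  cat(sprintf("  DMCs: A=%d B=%d | shared=%d (%d from A, %d from B) | unique A=%d B=%d\n",
              x$counts$dmcs_A, x$counts$dmcs_B, x$counts$shared_combined,
              x$counts$shared_from_A, x$counts$shared_from_B,
              x$counts$unique_A, x$counts$unique_B))
  cat(sprintf("  case-case DMCs: %d (%s%% also DMC in both case-control EWASs)\n",
              x$counts$case_case, format(x$percentages$case_case_in_both)))
  for (nm in names(x$auc)) {
    cat(sprintf("  AUC %s: mean %.3f\n", nm, x$auc[[nm]]$mean))
  }
  invisible(x)
}
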