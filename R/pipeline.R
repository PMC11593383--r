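#' Run the full ROH analysis pipeline
#'
#' Executes QC, permissive first-pass detection, per-class allowance
#' calibration, calibrated second-pass detection, F_ROH, per-population
#' incidence scans, island calling, cross-population sharing, optional
#' candidate-gene overlap and summary tables, writing every result as
#' tab-separated text plus a machine-readable run manifest. Any stage error
#' aborts with the stage name and cause.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Recognised top-level keys: \code{input} (\code{prefix},
#'   \code{dialect}, \code{pop_file}), \code{qc} (\code{max_marker_missing},
#'   \code{max_sample_missing}), \code{roh} (arguments of [roh_config()]),
#'   \code{islands} (arguments of [island_config()]), \code{genes}
#'   (annotation table path, optional), \code{genome_length_bp} (optional
#'   fixed F_ROH denominator) and \code{output_dir}.
#' @param output_dir overrides the configured output directory.
#' @return Invisibly, a list with the principal result objects
#'   (\code{qc}, \code{roh}, \code{froh}, \code{islands}, \code{summary})
#'   and \code{output_dir}.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) .stopf("config must be a YAML file path or a list")
  out_dir <- output_dir %||% cfg$output_dir
  if (is.null(out_dir)) .stopf("config must name an output_dir")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  roh_cfg <- stage("configuration",
                   do.call(roh_config, cfg$roh %||% list()))
  isl_cfg <- stage("configuration",
                   do.call(island_config, cfg$islands %||% list()))
  qc_cfg <- cfg$qc %||% list()

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon), add = TRUE)
  say <- function(fmt, ...) writeLines(sprintf(fmt, ...), logcon)
  say("rohscan pipeline")
  say("resolved ROH parameters: min_snp %d, max_gap %d bp, error %.4g, missing %.4g, rounding %s, basis %s",
      roh_cfg$min_snp_count, roh_cfg$max_gap_bp, roh_cfg$genotype_error_rate,
      roh_cfg$missing_rate, roh_cfg$rounding_rule, roh_cfg$calibration_basis)
  say("resolved island parameters: tail %.3g, merge gap %d bp, min SNPs %d",
      isl_cfg$tail_fraction, isl_cfg$merge_gap_bp, isl_cfg$min_island_snps)

  ds <- stage("read", {
    inp <- cfg$input %||% .stopf("config must name an input prefix")
    read_plink(inp$prefix, dialect = inp$dialect %||% "auto",
               pop_file = inp$pop_file)
  })
  say("input: %d samples x %d markers", nrow(ds$samples), nrow(ds$map))

  qc <- stage("qc", apply_qc(ds,
                             qc_cfg$max_marker_missing %||% 0.1,
                             qc_cfg$max_sample_missing %||% 0.1))
  say("qc: markers %d -> %d, samples %d -> %d, genotyping rate %.4f",
      qc$report$markers_before, qc$report$markers_after,
      qc$report$samples_before, qc$report$samples_after,
      qc$report$genotyping_rate)
  write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))

  pass1 <- stage("first_pass", first_pass_roh(qc$dataset, roh_cfg))
  params <- stage("calibration", calibrate_class_params(pass1, roh_cfg))
  say("calibrated allowances: het %s / missing %s",
      paste(params$max_het, collapse = ","),
      paste(params$max_missing, collapse = ","))
  .write_tsv(as.data.frame(params), file.path(out_dir, "class_params.tsv"))

  roh <- stage("second_pass", second_pass_roh(qc$dataset, params, roh_cfg))
  say("second pass: %d segments", nrow(roh))
  write_roh(roh, file.path(out_dir, "roh_segments.tsv"))

  fr <- stage("froh", compute_froh(roh,
                                   genome_length_bp = cfg$genome_length_bp))
  .write_tsv(as.data.frame(fr), file.path(out_dir, "froh.tsv"))
  .write_tsv(summarize_froh(fr), file.path(out_dir, "froh_summary.tsv"))

  isl <- stage("islands", roh_islands(roh, isl_cfg))
  write_islands(isl, out_dir)

  if (!is.null(cfg$genes)) {
    genes <- stage("genes", read_gene_intervals(cfg$genes))
    shared_ann <- stage("genes", overlap_genes(isl$shared, genes))
    .write_tsv(shared_ann, file.path(out_dir, "islands_shared_genes.tsv"))
  }

  bs <- stage("summary", breed_summary(roh))
  .write_tsv(as.data.frame(bs), file.path(out_dir, "breed_summary.tsv"))

  stage("manifest", {
    resolved <- list(qc = qc_cfg, roh = unclass(roh_cfg),
                     islands = unclass(isl_cfg))
    cfg_file <- file.path(out_dir, "resolved_config.yaml")
    yaml::write_yaml(resolved, cfg_file)
    manifest <- list(
      tool = "rohscan",
      version = as.character(utils::packageVersion("rohscan")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config_hash = unname(tools::md5sum(cfg_file)),
      n_samples = nrow(qc$dataset$samples),
      n_markers = nrow(qc$dataset$map),
      n_segments = nrow(roh),
      outputs = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  say("done")
  invisible(list(qc = qc$report, roh = roh, froh = fr, islands = isl,
                 summary = bs, output_dir = out_dir))
}
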