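# End-to-end orchestration: simulate -> design -> normalize -> call ->
# filter -> map -> refine -> scan, with YAML-configurable parameters,
# per-stage TSV outputs and JSON run summaries, and deterministic seeding.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    stages = list(design = TRUE, normalize = TRUE, call = TRUE,
                  filter = TRUE, map = TRUE, refine = TRUE, scan = TRUE),
    input = list(),                      # optional pre-existing input paths
    sim = list(),                        # overrides for sim_config()
    design = list(window_bp = 2000, min_qual = 25, target_tm = 80, ctx = 1e-7),
    normalize = list(spatial_filter = TRUE, radius = 3, k = 5),
    call = list(nc_threshold = 0.6, shrinkage = 0.5),
    filter = list(alpha = 0.05, conf_cutoff = 0.6, het_max = 0.2, hom_min = 0.15),
    map = list(p_cutoff = 1e-10, missing_threshold = 0.15, ril_correction = TRUE,
               min_group_size = 2,
               # recorded for provenance; only min_group_size acts in-repo
               no_map_dist = 15, detect_bad_data = FALSE),
    refine = list(flank = 6, region_len = 12, max_nc_regions = 10),
    scan = list(span = 0.1, window = 5, alpha = 0.05, min_run = 3,
                n_accessions = 4, p_poly = 0.53),
    write_signals = FALSE,
    export_vcf = FALSE
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Pipeline configuration
#'
#' Builds the nested parameter list driving [run_pipeline()], optionally
#' reading a YAML file; explicit arguments override file values, which
#' override the defaults.
#'
#' @param path Optional YAML file.
#' @param ... Named overrides (nested lists merge recursively), e.g.
#'   `sim = list(n_chromosomes = 2), seed = 7`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- c("pipeline_config", class(cfg))
  cfg
}

write_stage_summary <- function(out_dir, stage, info) {
  path <- file.path(out_dir, sprintf("%s_summary.json", stage))
  jsonlite::write_json(c(list(stage = stage), info), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export genotype calls as VCF
#'
#' Minimal VCFv4.2 export: AA/AB/BB map to 0/0, 0/1, 1/1 and NC to `./.`.
#' Simulated markers carry placeholder REF/ALT alleles A and B.
#'
#' @param calls A calls table.
#' @param path Output file.
#' @param ref,alt Allele strings.
#' @return `path`, invisibly.
#' @export
export_vcf_genotypes <- function(calls, path, ref = "A", alt = "B") {
  gt <- calls_matrix(calls)
  code <- c(AA = "0/0", AB = "0/1", BB = "1/1", NC = "./.")
  body <- matrix(code[gt], nrow(gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")
  )
  chrom <- if ("chrom" %in% names(calls)) calls$chrom else "."
  pos <- if ("pos_mb" %in% names(calls)) round(calls$pos_mb * 1e6) else seq_len(nrow(calls))
  lines <- apply(cbind(chrom, pos, calls$marker_id, ref, alt, ".", "PASS",
                       ".", "GT", body), 1, paste, collapse = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes every enabled stage, writing each stage's tables under
#' `out_dir` together with a JSON run summary (inputs, outputs,
#' parameters, seed). With a fixed configuration and seed, outputs are
#' byte-identical between runs. Referenced input paths are validated
#' before any stage runs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list of class `rilmap_run` with the in-memory stage results
#'   (sim, probes, processed, genotypes, filtered, map, refined, scans)
#'   and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("rilmap_run_")) {
  for (p in unlist(config$input)) {
    if (!file.exists(p)) abort(sprintf("input path does not exist: %s", p))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- list(out_dir = out_dir, config = config)

  sim_args <- merge_config(list(seed = config$seed), config$sim)
  sim_cfg <- do.call(sim_config, sim_args)

  # -- simulate ------------------------------------------------------------
  if (!is.null(config$input$calls)) {
    calls_true <- read_rilmap_tsv(config$input$calls)
    sim <- NULL
  } else {
    sim <- simulate_ril_population(sim_cfg)
    calls_true <- sim$calls
  }
  write_rilmap_tsv(calls_true, file.path(out_dir, "genotypes_true.tsv"))
  write_stage_summary(out_dir, "simulate", list(
    seed = config$seed, markers = nrow(calls_true),
    samples = length(sample_cols(calls_true))
  ))
  run$sim <- sim

  # -- design --------------------------------------------------------------
  if (isTRUE(config$stages$design)) {
    pileup <- simulate_read_pileup(sim_cfg)
    write_rilmap_tsv(pileup, file.path(out_dir, "pileup.tsv"))
    sel <- select_window_snps(pileup, window_bp = config$design$window_bp,
                              min_qual = config$design$min_qual)
    flanks <- simulate_flanks(sel, seed = child_seed(config$seed, "flanks"))
    anno <- simulate_annotation(sim_cfg)
    gff <- file.path(out_dir, "annotation.gff3")
    write_annotation_gff3(anno, gff)
    probes <- design_array(
      pileup, flanks,
      window_bp = config$design$window_bp, min_qual = config$design$min_qual,
      params = thermo_params(ctx = config$design$ctx),
      target_tm = config$design$target_tm, annotation = anno
    )
    write_rilmap_tsv(probes, file.path(out_dir, "probes.tsv"))
    write_stage_summary(out_dir, "design", list(
      candidate_sites = nrow(pileup), selected_snps = nrow(sel),
      probes = nrow(probes), target_tm = config$design$target_tm
    ))
    run$probes <- probes
  }

  # -- normalize -----------------------------------------------------------
  signals <- simulate_array_signals(sim %||% calls_true, sim_cfg)
  if (isTRUE(config$write_signals)) {
    write_rilmap_tsv(signals, file.path(out_dir, "signals_raw.tsv"))
  }
  processed <- if (isTRUE(config$stages$normalize)) {
    process_signals(signals,
                    spatial_filter = config$normalize$spatial_filter,
                    radius = config$normalize$radius, k = config$normalize$k)
  } else {
    process_signals(signals, spatial_filter = FALSE)
  }
  write_rilmap_tsv(processed, file.path(out_dir, "signals_summarized.tsv"))
  write_stage_summary(out_dir, "normalize", list(
    probes = 4L * length(unique(signals$snp_id)),
    arrays = length(unique(signals$sample)),
    spatial_filter = isTRUE(config$stages$normalize) &&
      isTRUE(config$normalize$spatial_filter),
    masked_entries = sum(processed$masked)
  ))
  run$processed <- processed

  # -- call ----------------------------------------------------------------
  models <- fit_training_models(processed, lambda = config$call$shrinkage)
  genotypes <- call_genotypes(processed, models,
                              markers = if (!is.null(sim)) sim$markers else NULL,
                              nc_threshold = config$call$nc_threshold)
  write_rilmap_tsv(genotypes$calls, file.path(out_dir, "genotypes_called.tsv"))
  write_rilmap_tsv(genotypes$confidence, file.path(out_dir, "confidence.tsv"))
  model_summary <- models |>
    mutate(min_separation = vapply(.data$model, min_cluster_separation, 0)) |>
    select("snp_id", "gts_status", "miscluster_count", "min_separation")
  write_rilmap_tsv(model_summary, file.path(out_dir, "training_models.tsv"))
  write_stage_summary(out_dir, "call", list(
    snps = nrow(models),
    gts_perfect = sum(models$gts_status == "GTS_perfect"),
    gts_one_off = sum(models$gts_status == "GTS_one_off"),
    rejected = sum(models$gts_status == "rejected"),
    nc_threshold = config$call$nc_threshold
  ))
  run$genotypes <- genotypes

  # -- filter --------------------------------------------------------------
  filtered <- if (isTRUE(config$stages$filter)) {
    filter_markers(genotypes,
                   t = sim_cfg$generations, alpha = config$filter$alpha,
                   conf_cutoff = config$filter$conf_cutoff,
                   het_max = config$filter$het_max,
                   hom_min = config$filter$hom_min)
  } else {
    genotypes$calls
  }
  report <- attr(filtered, "filter_report")
  if (!is.null(report)) {
    write_rilmap_tsv(report, file.path(out_dir, "filter_report.tsv"))
  }
  write_stage_summary(out_dir, "filter", list(
    enabled = isTRUE(config$stages$filter),
    consumed = if (isTRUE(config$stages$filter)) "filtered calls" else "unfiltered calls",
    markers_in = nrow(genotypes$calls), markers_out = nrow(filtered),
    samples_out = length(sample_cols(filtered))
  ))
  run$filtered <- filtered

  # -- map -----------------------------------------------------------------
  map <- NULL
  if (isTRUE(config$stages$map)) {
    map <- build_linkage_map(filtered,
                             p_cutoff = config$map$p_cutoff,
                             missing_threshold = config$map$missing_threshold,
                             min_group_size = config$map$min_group_size,
                             ril_correction = config$map$ril_correction)
    write_rilmap_tsv(as_tibble(map), file.path(out_dir, "linkage_map.tsv"))
    g <- attr(map, "groups")
    write_stage_summary(out_dir, "map", list(
      linkage_groups = nrow(g), markers = nrow(map),
      bins = sum(g$n_bins), total_cm = sum(g$length_cm)
    ))
  }
  run$map <- map

  # -- refine --------------------------------------------------------------
  refined <- NULL
  if (isTRUE(config$stages$refine) && !is.null(map)) {
    refined <- refine_genotypes(filtered, map,
                                flank = config$refine$flank,
                                region_len = config$refine$region_len)
    write_rilmap_tsv(refined$calls, file.path(out_dir, "genotypes_refined.tsv"))
    write_rilmap_tsv(refined$diff, file.path(out_dir, "refinement_diff.tsv"))
    qc2 <- sample_qc(refined$calls, het_max = 1, hom_min = 0,
                     nc_regions = refined$nc_regions,
                     max_nc_regions = config$refine$max_nc_regions)
    dropped <- setdiff(sample_cols(refined$calls), sample_cols(qc2))
    if (length(dropped) > 0) {
      # rebuild the map without the unusable samples
      keep <- filtered[, c(marker_meta_cols(filtered), sample_cols(qc2))]
      attr(keep, "dedup_groups") <- attr(filtered, "dedup_groups")
      map <- build_linkage_map(keep,
                               p_cutoff = config$map$p_cutoff,
                               missing_threshold = config$map$missing_threshold,
                               min_group_size = config$map$min_group_size,
                               ril_correction = config$map$ril_correction)
      write_rilmap_tsv(as_tibble(map), file.path(out_dir, "linkage_map.tsv"))
      refined <- refine_genotypes(keep, map,
                                  flank = config$refine$flank,
                                  region_len = config$refine$region_len)
      write_rilmap_tsv(refined$calls, file.path(out_dir, "genotypes_refined.tsv"))
      write_rilmap_tsv(refined$diff, file.path(out_dir, "refinement_diff.tsv"))
      run$map <- map
    }
    write_stage_summary(out_dir, "refine", list(
      modified_calls = nrow(refined$diff),
      samples_dropped = length(dropped)
    ))
  }
  run$refined <- refined

  if (isTRUE(config$export_vcf)) {
    export_vcf_genotypes((refined %||% list(calls = filtered))$calls,
                         file.path(out_dir, "genotypes.vcf"))
  }

  # -- scan ----------------------------------------------------------------
  if (isTRUE(config$stages$scan) && !is.null(map)) {
    scan_calls <- (if (!is.null(refined)) refined$calls else filtered)
    if (!"pos_mb" %in% names(scan_calls) && !is.null(sim)) {
      scan_calls <- left_join(scan_calls, sim$markers, by = "marker_id")
    }
    profile <- local_recomb_rate(map, span = config$scan$span,
                                 window = config$scan$window)
    distortion <- segregation_scan(scan_calls, alpha = config$scan$alpha,
                                   min_run = config$scan$min_run)
    coll <- collinearity(map)
    panel <- simulate_accession_panel(sim %||% scan_calls,
                                      n_accessions = config$scan$n_accessions,
                                      p_poly = config$scan$p_poly,
                                      seed = child_seed(config$seed, "panel"))
    binpoly <- bin_polymorphism(map, panel)
    write_rilmap_tsv(profile, file.path(out_dir, "recomb_profile.tsv"))
    write_rilmap_tsv(distortion$records, file.path(out_dir, "distortion_records.tsv"))
    write_rilmap_tsv(distortion$intervals, file.path(out_dir, "sdr_intervals.tsv"))
    write_rilmap_tsv(coll, file.path(out_dir, "collinearity.tsv"))
    write_rilmap_tsv(binpoly$bins, file.path(out_dir, "bin_polymorphism.tsv"))
    write_stage_summary(out_dir, "scan", list(
      sdr_intervals = nrow(distortion$intervals),
      mean_r_squared = mean(coll$r_squared, na.rm = TRUE),
      bin_coverage = binpoly$coverage
    ))
    run$scans <- list(profile = profile, distortion = distortion,
                      collinearity = coll, bin_polymorphism = binpoly)
  }

  class(run) <- "rilmap_run"
  run
}

#' @export
print.rilmap_run <- function(x, ...) {
  cat(sprintf("<rilmap_run> artifacts in %s\n", x$out_dir))
  invisible(x)
}

#' Summarize a pipeline run
#'
#' Emits the per-chromosome marker table (counts, genomic contexts when
#' the design stage ran, median marker interval) and the per-linkage-group
#' map summary (lengths, markers, bins, median bin interval), as tibbles;
#' optionally writes them as TSV plus a Markdown digest.
#'
#' @param run A `rilmap_run`.
#' @param write Write report files into the run's output directory?
#' @return List with `chromosomes` and `map` tibbles.
#' @export
pipeline_report <- function(run, write = TRUE) {
  stopifnot(inherits(run, "rilmap_run"))
  calls_true <- read_rilmap_tsv(file.path(run$out_dir, "genotypes_true.tsv"))
  chrom_tbl <- calls_true |>
    group_by(.data$chrom) |>
    summarise(
      n_markers = n(),
      median_interval_mb = median(diff(sort(.data$pos_mb))),
      .groups = "drop"
    )
  if (!is.null(run$probes) && "context" %in% names(run$probes)) {
    ctx <- run$probes |>
      distinct(.data$snp_id, .data$chrom, .data$context) |>
      count(.data$chrom, .data$context) |>
      tidyr::pivot_wider(names_from = "context", values_from = "n",
                         values_fill = 0L, names_prefix = "n_")
    names(ctx)[names(ctx) == "chrom"] <- "design_chrom"
    chrom_tbl <- bind_cols(chrom_tbl,
                           ctx[match(sprintf("chr%d", chrom_tbl$chrom),
                                     ctx$design_chrom), -1])
  }
  map_tbl <- if (!is.null(run$map)) {
    as_tibble(run$map) |>
      group_by(.data$linkage_group) |>
      summarise(
        length_cm = max(.data$cm),
        n_markers = n(),
        n_bins = dplyr::n_distinct(.data$bin),
        median_bin_interval_cm = {
          pos <- sort(unique(.data$cm[!duplicated(.data$bin)]))
          if (length(pos) > 1) median(diff(pos)) else NA_real_
        },
        .groups = "drop"
      )
  } else {
    tibble(linkage_group = integer(), length_cm = numeric(),
           n_markers = integer(), n_bins = integer(),
           median_bin_interval_cm = numeric())
  }
  if (write) {
    write_rilmap_tsv(chrom_tbl, file.path(run$out_dir, "report_chromosomes.tsv"))
    write_rilmap_tsv(map_tbl, file.path(run$out_dir, "report_map.tsv"))
    md <- c(
      "# Run report", "",
      sprintf("- markers simulated: %d", nrow(calls_true)),
      sprintf("- linkage groups: %d", nrow(map_tbl)),
      sprintf("- total map length: %.1f cM", sum(map_tbl$length_cm)),
      sprintf("- bins: %d", sum(map_tbl$n_bins))
    )
    writeLines(md, file.path(run$out_dir, "report.md"))
  }
  list(chromosomes = chrom_tbl, map = map_tbl)
}
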