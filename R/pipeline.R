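#' Validate a pipeline configuration
#'
#' @param config list (parsed JSON) or path to a JSON config file.
#' @return the validated config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  if (!is.list(config)) stopf("config must be a list or a JSON path")
  required <- c("schema_version", "reference", "days", "expression")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stopf("config missing fields: %s", paste(missing, collapse = ", "))
  }
  if (config$schema_version != 1) {
    stopf("unsupported config schema_version %s", config$schema_version)
  }
  for (d in config$days) {
    if (is.null(d$day) || is.null(d$classes)) {
      stopf("each day entry needs 'day' and 'classes'")
    }
    if (sum(unlist(d$classes)) == 0) {
      stopf("day %s: n_molecules = 0", d$day)
    }
  }
  config
}

#' Default pipeline configuration
#'
#' A compact scenario modeled on a hypomethylating-agent time course in a
#' biallelically methylated cell line: a uniformly hypermethylated,
#' TSS-occupied baseline; a reactivated day-5 population with a
#' demethylated fraction and partial TSS eviction; and a day-7 population
#' whose demethylated molecules are all re-occupied at the TSS.
#'
#' @return config list (see [load_config()]).
#' @export
default_config <- function() {
  path <- system.file("extdata", "default_config.json",
                      package = "resilencer")
  load_config(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s': %s", name, conditionMessage(e))
  })
}

#' Run the full simulate / call / classify / quantify / order pipeline
#'
#' Executes every analysis layer end to end from a JSON-style config:
#' generates the reference amplicon and per-day clone populations, pushes
#' them through the simulated NOMe-seq protocol, aligns and calls every
#' clone, classifies molecules and calls footprints, computes
#' delta-delta-Ct expression, detects resilencing onset, orders events by
#' half-recovery day, and writes a report (JSON + TSV + BED + lollipop
#' text) to `outdir`. All randomness derives from `seed`.
#'
#' @param config config list or JSON path (see [load_config()]); default
#'   [default_config()].
#' @param seed master integer seed.
#' @param outdir output directory (created if needed).
#' @return the report, invisibly (also written to
#'   `file.path(outdir, "report.json")`).
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         outdir = tempfile("resilencer_run_")) {
  config <- stage("config", load_config(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  ref <- stage("reference", {
    rc <- config$reference
    generate_reference(rc$length, rc$cpg_density, rc$gpc_density,
                       tss_offset = rc$tss_offset, seed = seed,
                       name = rc$name %||% "promoter_amplicon")
  })
  write_reference(ref, file.path(outdir, "reference.fasta"),
                  file.path(outdir, "reference_sites.bed"))

  ap <- stage("assay_params", {
    do.call(assay_params, config$assay %||% list())
  })

  counts <- list()
  day_summaries <- list()
  for (k in seq_along(config$days)) {
    dcfg <- config$days[[k]]
    day <- dcfg$day
    day_seed <- seed + 1000L * k
    classes <- default_classes()
    occ <- dcfg$tss_occupied_prob %||% list()
    for (cl in names(occ)) classes[[cl]]$tss_occupied_prob <- occ[[cl]]
    pop <- stage("population", {
      spec <- population_spec(n_molecules = sum(unlist(dcfg$classes)),
                              class_mix = unlist(dcfg$classes),
                              classes = classes,
                              nucleosome_width =
                                config$nucleosome_width %||% 147L,
                              seed = day_seed)
      generate_population(ref, spec)
    })
    clones <- stage("assays", {
      apply_assays(pop, ref, ap, seed = day_seed + 1L)
    })
    write_clones(clones, file.path(outdir, sprintf("clones_day%s.fasta", day)))
    write_truth(pop, file.path(outdir, sprintf("truth_day%s.tsv", day)))
    profiles <- stage("calling", call_clones(clones, ref))
    if (!length(profiles)) stopf("stage 'calling': no mappable clones on day %s", day)
    summ <- stage("classification", summarize_population(profiles, ref))
    write_call_matrix(profiles,
                      file.path(outdir, sprintf("calls_day%s_cpg.tsv", day)),
                      track = "cpg")
    write_footprints_bed(profiles, ref,
                         file.path(outdir, sprintf("footprints_day%s.bed", day)))
    writeLines(render_lollipop(profiles, ref, "cpg"),
               file.path(outdir, sprintf("lollipop_day%s_cpg.txt", day)))
    writeLines(render_lollipop(profiles, ref, "gpc"),
               file.path(outdir, sprintf("lollipop_day%s_gpc.txt", day)))
    counts[[as.character(day)]] <- list(
      n_molecules = length(pop), n_clones = length(clones),
      n_profiles = length(profiles), n_classified = summ$n)
    day_summaries[[as.character(day)]] <- list(
      day = day, n = summ$n,
      pct_demethylated = summ$pct_demethylated,
      pct_tss_depleted = summ$pct_tss_depleted,
      joint = as.data.frame(summ$joint))
  }

  expr <- stage("quantification", {
    ec <- config$expression
    q <- unlist(ec$quantities)
    design <- rbind(
      data.frame(assay = "expression", target = ec$target,
                 condition = "sample", day = as.numeric(names(q)),
                 true_quantity = unname(q), stringsAsFactors = FALSE),
      data.frame(assay = "expression", target = ec$ref_gene,
                 condition = "sample", day = as.numeric(names(q)),
                 true_quantity = 1, stringsAsFactors = FALSE))
    ct <- generate_ct_table(design, base_ct = ec$base_ct %||% 25,
                            noise_sd = ec$noise_sd %||% 0.05,
                            seed = seed + 77L)
    write_ct_table(ct, file.path(outdir, "ct_expression.tsv"))
    relative_expression(ct, ec$target, ec$ref_gene,
                        calibrator_day = ec$calibrator_day)
  })
  write.table(expr, file.path(outdir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  tc <- stage("timecourse", {
    tcfg <- config$timecourse %||% list()
    sim <- simulate_timecourse(
      nucleosome_t50 = tcfg$nucleosome_t50 %||% 6,
      methylation_t50 = tcfg$methylation_t50 %||% 11,
      noise_sd = tcfg$noise_sd %||% 4,
      seed = seed + 99L)
    onset <- detect_resilencing_onset(
      setNames(expr$value, expr$day),
      treatment_end_day = config$expression$treatment_end_day %||% 3)
    ord <- event_order(sim$timeline, sim$metrics)
    list(onset_day = if (is.na(onset)) "unreached" else onset,
         half_recovery = as.list(ord$half_recovery),
         event_order = ord$event_order,
         nucleosome_before_methylation = ord$nucleosome_before_methylation,
         timeline = sim$timeline)
  })
  write.table(tc$timeline, file.path(outdir, "timeline.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  report <- list(
    schema_version = 1,
    seed = seed,
    reference = list(name = ref$name, length = ref$length,
                     tss_position = ref$tss_position,
                     n_cpg = length(ref$cpg_sites),
                     n_gpc = length(ref$gpc_sites)),
    stage_counts = counts,
    day_summaries = day_summaries,
    expression = expr,
    onset_day = tc$onset_day,
    half_recovery = tc$half_recovery,
    event_order = tc$event_order,
    nucleosome_before_methylation = tc$nucleosome_before_methylation)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
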