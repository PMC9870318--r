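#' Pipeline run configuration
#'
#' Bundles every tunable of the simulate -> extract -> classify -> cluster ->
#' stats pipeline. All defaults are the canonical study conditions: the
#' three step protocols, the -50 mV exclusion cutoff, 3 mV sag threshold,
#' +30 pA / 1-spike "Others" rule, 5 ms ISI bins, and the three/six
#' clustering parameter sets.
#'
#' @param seed Mandatory integer seed; the whole run is deterministic given
#'   the config.
#' @param n_per_type Cohort counts for Types I, II, III, Others.
#' @param jitter Cohort parameter jitter (lognormal sd).
#' @param noise_sd Current-clamp noise (pA).
#' @param sag_threshold,others_current_threshold,others_max_spikes,rmp_cutoff
#'   Classifier thresholds (see [classify_neurons()], [apply_exclusion()]).
#' @param parameter_set Clustering parameter set, `"three"` or `"six"`.
#' @param k Number of clusters to cut.
#' @param write_traces Also write raw traces (large) into the run directory.
#' @param out_dir Output directory (`NULL`: in-memory run only).
#' @return A `run_config` list.
#' @export
run_config <- function(seed,
                       n_per_type = c(I = 30, II = 30, III = 30, Others = 30),
                       jitter = 0.1, noise_sd = 0,
                       sag_threshold = 3, others_current_threshold = 30,
                       others_max_spikes = 1, rmp_cutoff = -50,
                       parameter_set = "six", k = 3,
                       write_traces = FALSE, out_dir = NULL) {
  if (missing(seed)) abort("`seed` is mandatory")
  structure(list(seed = as.integer(seed), n_per_type = n_per_type,
                 jitter = jitter, noise_sd = noise_sd,
                 sag_threshold = sag_threshold,
                 others_current_threshold = others_current_threshold,
                 others_max_spikes = others_max_spikes,
                 rmp_cutoff = rmp_cutoff,
                 parameter_set = parameter_set, k = k,
                 write_traces = write_traces, out_dir = out_dir),
            class = "run_config")
}

#' Simulate a cohort and extract all features
#'
#' Runs all protocols for every neuron of a cohort and returns the wide
#' feature table plus the long per-step table; traces are processed one
#' neuron at a time and not retained.
#'
#' @param cohort Tibble from [make_cohort()].
#' @param config A [sim_config()].
#' @param protocols Named protocol list.
#' @param keep_traces Also return the raw sweeps (`$sims`); intended for
#'   small cohorts, as traces dominate memory.
#' @return List with `features` (wide, one row per neuron, including
#'   `phenotype` ground truth and `ap_position`) and `step_features` (long);
#'   plus `sims` when `keep_traces = TRUE`.
#' @export
cohort_features <- function(cohort, config = sim_config(),
                            protocols = default_protocols(),
                            keep_traces = FALSE) {
  res <- purrr::map(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    sims <- simulate_neuron(cohort_params(row), config, protocols)
    sims$neuron_id <- row$neuron_id
    out <- extract_one(sims, protocols)
    if (keep_traces) out$sims <- sims
    out
  })
  features <- purrr::list_rbind(purrr::map(res, "wide")) |>
    left_join(cohort |>
                select(dplyr::any_of(c("neuron_id", "phenotype",
                                       "ap_position"))),
              by = "neuron_id") |>
    dplyr::relocate(dplyr::any_of(c("phenotype", "ap_position")),
                    .after = "neuron_id")
  out <- list(features = features,
              step_features = purrr::list_rbind(purrr::map(res, "long")))
  if (keep_traces)
    out$sims <- purrr::list_rbind(purrr::map(res, "sims"))
  out
}

#' Run the full pipeline
#'
#' Simulate a synthetic cohort, extract features, apply exclusion and
#' classification, cluster, and compute the statistical surface; optionally
#' write every artifact into a run directory (config, cohort manifest,
#' feature tables, labels, proportions, linkage, heatmap TSV, agreement,
#' stats, report and a manifest auditing per-stage row counts).
#'
#' @param config A [run_config()].
#' @return The report: a list with `proportions`, `counts`, `features`,
#'   `labels`, `type_summaries`, `agreement`, `linkage`, `anova`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sc <- sim_config(noise_sd = config$noise_sd, seed = config$seed)
  protocols <- default_protocols()

  cohort <- make_cohort(config$n_per_type, config$jitter, config$seed)
  stage_counts <- list(cohort = nrow(cohort))
  if (nrow(cohort) == 0) {
    report <- list(proportions = proportions_by_type(character(0)),
                   counts = tibble(label = .phenotypes, n = 0L),
                   features = tibble(), labels = tibble(),
                   manifest = list(seed = config$seed,
                                   stage_counts = stage_counts))
    if (!is.null(config$out_dir)) write_run(report, config)
    return(report)
  }

  fx <- cohort_features(cohort, sc, protocols,
                        keep_traces = isTRUE(config$write_traces))
  if (isTRUE(config$write_traces) && !is.null(config$out_dir))
    write_traces(fx$sims, file.path(config$out_dir, "traces"), protocols)
  features <- fx$features |>
    apply_exclusion(config$rmp_cutoff) |>
    classify_neurons(config$sag_threshold,
                     config$others_current_threshold,
                     config$others_max_spikes)
  labels <- features[c("neuron_id", "phenotype", "label", "rationale")]
  stage_counts$features <- nrow(features)
  stage_counts$excluded <- sum(features$excluded)

  props <- proportions_by_type(features$label)

  mat <- build_feature_matrix(features, config$parameter_set)
  stage_counts$matrix_rows <- nrow(mat)
  linkage <- NULL; agreement <- NULL; clusters <- NULL
  if (nrow(mat) >= max(2, config$k)) {
    linkage <- ward_linkage(mat, scale = TRUE)
    clusters <- cut_clusters(linkage, config$k)
    agreement <- cluster_agreement(clusters, labels)
  }

  kept <- filter(features, !.data$excluded)
  type_summaries <- purrr::map(
    c("rmp", "capacitance", "input_resistance", "sag_80", "ih_140",
      "mfr", "mfr_step"),
    function(f) {
      summarize_groups(kept, .data[[f]], .data$label) |>
        mutate(feature = f, .before = 1)
    }) |>
    purrr::list_rbind()

  anova <- list()
  ev <- fx$step_features |>
    filter(.data$feature == "evoked_spikes", .data$step > 0) |>
    left_join(labels[c("neuron_id", "label")], by = "neuron_id") |>
    filter(.data$label != "Excluded")
  if (dplyr::n_distinct(ev$label) >= 2)
    anova$evoked_two_way <- tryCatch(
      tidy(two_way_anova(ev, value, label, step)), error = function(e) NULL)
  if (dplyr::n_distinct(kept$label) >= 2) {
    anova$capacitance_one_way <- tryCatch(
      tidy(one_way_anova(kept, capacitance, label)),
      error = function(e) NULL)
    anova$capacitance_tukey <- tryCatch(
      tidy(tukey_hsd(kept, capacitance, label)), error = function(e) NULL)
  }

  rostro <- NULL
  if ("ap_position" %in% names(kept)) {
    rostro <- kept |>
      count(.data$ap_position, .data$label) |>
      arrange(dplyr::desc(.data$ap_position))
  }

  report <- list(
    proportions = props,
    counts = props[c("label", "n")],
    features = features,
    step_features = fx$step_features,
    labels = labels,
    type_summaries = type_summaries,
    clusters = clusters,
    agreement = agreement,
    linkage = linkage,
    anova = anova,
    rostrocaudal = rostro,
    manifest = list(seed = config$seed,
                    package_version = as.character(utils::packageVersion("patchtype")),
                    config_hash = rlang::hash(unclass(config)),
                    stage_counts = stage_counts))
  if (!is.null(config$out_dir)) write_run(report, config, cohort)
  report
}

write_run <- function(report, config, cohort = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  jsonlite::write_json(unclass(config), out("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (!is.null(cohort)) readr::write_csv(cohort, out("cohort.csv"))
  if (nrow(report$features %||% tibble()) > 0) {
    write_feature_table(report$features, out("features.tsv"))
    write_feature_table(report$step_features, out("step_features.tsv"))
    readr::write_tsv(report$labels, out("labels.tsv"))
  }
  jsonlite::write_json(report$proportions, out("proportions.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(report$linkage)) {
    readr::write_tsv(tidy(report$linkage), out("linkage_merges.tsv"))
    export_dendrogram_newick(report$linkage, out("dendrogram.nwk"))
    mat <- build_feature_matrix(report$features, config$parameter_set)
    export_heatmap(standardize(mat), report$linkage, report$labels,
                   out("heatmap.tsv"))
  }
  if (!is.null(report$agreement))
    jsonlite::write_json(
      list(contingency = report$agreement$contingency,
           purity = report$agreement$purity,
           overall = report$agreement$overall),
      out("agreement.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  if (length(report$anova))
    jsonlite::write_json(report$anova, out("stats.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  jsonlite::write_json(report$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' Proportion report from per-type counts
#'
#' Formats per-type counts as the standard proportion report: percentage of
#' the classified total per type, to two decimals.
#'
#' @param counts Numeric vector of four counts (Types I, II, III, Others).
#' @return Tibble `label`, `n`, `pct` with the grand total as
#'   `attr(, "total")`.
#' @examples
#' report_proportions(c(67, 25, 28, 13))
#' @export
report_proportions <- function(counts) {
  if (length(counts) != 4 || any(counts < 0))
    abort("`counts` must be four non-negative counts")
  proportions_by_type(rep(.phenotypes, counts))
}
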