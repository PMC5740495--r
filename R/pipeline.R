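# End-to-end orchestration over synthetic data: simulate -> preprocess ->
# NIP calling -> specificity -> network smoothing -> site analysis ->
# evaluation against the planted truth, with a JSON manifest recording
# stages, parameters, seed and output checksums.

#' Evaluate recovered cargo-bait pairs against the planted truth
#'
#' A (protein, bait) pair counts as called when the specificity flag is
#' significant in at least one fusion sample of that bait (either
#' terminus). Reports pair-level sensitivity, false-discovery proportion,
#' per-bait precision, and - when a NIP result is supplied - the NIP /
#' background confusion counts.
#'
#' @param truth a `ground_truth` from [simulate_truth()].
#' @param spec a `specificity_table` from [specificity_scores()].
#' @param design the study design (maps samples to baits).
#' @param nip optional `nip_result` from [call_nip()].
#' @return List: `summary` (one-row tibble with `sensitivity`, `fdp`,
#'   `tp`, `fp`, `fn`), `per_bait` tibble, and `nip_confusion` tibble (or
#'   `NULL`).
#' @export
evaluate_recovery <- function(truth, spec, design, nip = NULL) {
  bait_of <- dplyr::distinct(design[!design$is_control, c("cell_line", "bait")])
  called <- spec |>
    filter(.data$significant) |>
    inner_join(bait_of, by = c(sample = "cell_line")) |>
    dplyr::distinct(.data$group_id, .data$bait)
  truth_pairs <- dplyr::distinct(truth$cargo[c("protein", "bait")])

  key_called <- paste(called$group_id, called$bait)
  key_truth <- paste(truth_pairs$protein, truth_pairs$bait)
  tp <- sum(key_called %in% key_truth)
  fp <- length(key_called) - tp
  fn <- length(key_truth) - tp
  summary <- tibble(
    sensitivity = if (length(key_truth)) tp / length(key_truth) else NA_real_,
    fdp = if (tp + fp > 0) fp / (tp + fp) else 0,
    tp = tp, fp = fp, fn = fn
  )
  per_bait <- called |>
    mutate(true = key_called %in% key_truth) |>
    group_by(.data$bait) |>
    summarise(n_called = dplyr::n(),
              precision = mean(.data$true), .groups = "drop")

  nip_confusion <- NULL
  if (!is.null(nip)) {
    truth_label <- dplyr::case_when(
      nip$group_id %in% truth$cargo$protein ~ "NIP",
      nip$group_id %in% truth$control_enriched ~ "BACKGROUND",
      .default = "NEITHER"
    )
    nip_confusion <- as_tibble(as.data.frame(table(
      truth = truth_label, called = nip$label
    )))
  }
  list(summary = summary, per_bait = per_bait, nip_confusion = nip_confusion)
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic study and runs every downstream stage, writing
#' each stage's tables plus a JSON manifest (stage names, parameters,
#' seed, md5 checksums) into `outdir`. Re-running with the same
#' configuration and seed reproduces byte-identical outputs.
#'
#' @param config a [sim_config()], or the path to a YAML file whose keys
#'   are `sim_config()` arguments.
#' @param seed master seed; every stage derives its own substream from it.
#' @param outdir output directory (created if needed).
#' @param fraction top fraction for network extraction (default 0.02).
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1,
                         outdir = tempfile("proxiscore_run"), fraction = 0.02) {
  if (is.character(config)) {
    config <- do.call(sim_config, yaml::read_yaml(config))
  }
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config or YAML path")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outdir, f)
  stages <- list()
  note <- function(name, files, params = list()) {
    stages[[length(stages) + 1]] <<- list(
      stage = name, outputs = as.list(basename(files)),
      md5 = as.list(unname(tools::md5sum(files))), params = params)
  }

  # 1. simulate
  design <- simulate_design(config)
  truth <- simulate_truth(config, seed)
  mat <- simulate_intensities(design, truth, config, seed)
  net <- simulate_network(truth, config, seed)
  site_mat <- simulate_sites(design, truth, config, seed)
  readr::write_tsv(design, out("design.tsv"))
  write_intensity_matrix(mat, out("intensities.tsv"))
  readr::write_tsv(as_tibble(net), out("network.tsv"))
  write_intensity_matrix(site_mat, out("sites.tsv"))
  readr::write_tsv(truth$cargo, out("truth_cargo.tsv"))
  note("simulate", out(c("design.tsv", "intensities.tsv", "network.tsv",
                         "sites.tsv", "truth_cargo.tsv")),
       params = list(seed = seed, n_proteins = config$n_proteins,
                     n_ntrs = config$n_ntrs, n_controls = config$n_controls,
                     n_bio = config$n_bio, n_tech = config$n_tech,
                     delta = config$delta))

  # 2. preprocess
  filtered <- filter_identifications(mat, design, min_unique = 2,
                                     min_bio = min(3, config$n_bio))
  merged <- merge_technical(filtered, design)
  write_intensity_matrix(merged, out("merged.tsv"))
  note("preprocess", out("merged.tsv"),
       params = list(min_unique = 2, min_bio = min(3, config$n_bio)))

  # 3. NIP calling
  ctrl <- control_comparisons(filtered, design)
  nip <- call_nip(ctrl, alpha = 0.1)
  readr::write_tsv(nip, out("nip.tsv"))
  note("nip", out("nip.tsv"), params = list(alpha = 0.1))

  # 4. specificity
  spec <- specificity_scores(filtered, design, p_sig = 0.01, alpha = 0.01)
  readr::write_tsv(spec, out("specificity.tsv"))
  note("specificity", out("specificity.tsv"),
       params = list(p_sig = 0.01, alpha = 0.01))

  # 5. network smoothing
  smoothed <- smooth_scores(spec, net, fraction = fraction)
  readr::write_tsv(smoothed, out("netprop.tsv"))
  comps <- smoothed |>
    filter(.data$selected) |>
    group_by(.data$sample) |>
    dplyr::group_modify(~ extract_subnetworks(.x$node, net)) |>
    ungroup()
  readr::write_tsv(comps, out("subnetworks.tsv"))
  note("netprop", out(c("netprop.tsv", "subnetworks.tsv")),
       params = list(alpha = 0.5, iters = 30, fraction = fraction))

  # 6. sites
  kept_sites <- filter_sites(site_mat, design, min_bio = min(2, config$n_bio))
  centered <- normalize_center(kept_sites)
  write_intensity_matrix(centered, out("sites_centered.tsv"))
  note("sites", out("sites_centered.tsv"),
       params = list(min_bio = min(2, config$n_bio)))

  # 7. evaluate
  eval_res <- evaluate_recovery(truth, spec, design, nip = nip)
  readr::write_tsv(eval_res$summary, out("evaluation.tsv"))
  note("evaluate", out("evaluation.tsv"))

  manifest <- list(seed = seed, stages = stages)
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(design = design, truth = truth, matrix = mat, network = net,
                 merged = merged, nip = nip, specificity = spec,
                 smoothed = smoothed, subnetworks = comps, sites = centered,
                 evaluation = eval_res, manifest = manifest, outdir = outdir))
}
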