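#' Configure the end-to-end pipeline
#'
#' Bundles the per-stage settings with a single seed. Input paths are
#' optional: when `pileup_path` or `proteome_path` is `NULL` the
#' corresponding stage runs on data from the synthetic generators.
#'
#' @param seed Integer seed recorded in every output header.
#' @param thresholds Variant acceptance thresholds ([filter_thresholds()]).
#' @param criteria Cargo screen criteria ([cargo_criteria()]).
#' @param reactor Reactor parameters ([reactor_params()]).
#' @param strains Sample-to-strain map for classification.
#' @param emergent_samples Later samples for the `emergent` label.
#' @param n_decoys,cargo Synthetic proteome composition.
#' @param founders,duration Forward reactor simulation settings.
#' @param non_producer_fraction Non-producing fraction for the founder
#'   back-calculation.
#' @param pileup_path,proteome_path Optional real input files (pileup TSV,
#'   protein FASTA) replacing the simulated data.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            thresholds = filter_thresholds(),
                            criteria = cargo_criteria(),
                            reactor = reactor_params(),
                            strains = demo_strains(),
                            emergent_samples = "MO_biofilm",
                            n_decoys = 100,
                            cargo = list(
                              planted_cargo(3038, 4, n_cys = 0),
                              planted_cargo(2414, 3, n_cys = 3)
                            ),
                            founders = 1.6e4, duration = 144,
                            non_producer_fraction = 0.24,
                            pileup_path = NULL, proteome_path = NULL) {
  structure(
    list(
      seed = as.integer(seed), thresholds = thresholds, criteria = criteria,
      reactor = reactor, strains = strains,
      emergent_samples = emergent_samples, n_decoys = n_decoys,
      cargo = cargo, founders = founders, duration = duration,
      non_producer_fraction = non_producer_fraction,
      pileup_path = pileup_path, proteome_path = proteome_path
    ),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Executes simulate -> variant screen -> cargo screen -> founder
#' back-calculation, writes every stage result as a headered TSV under
#' `output_dir`, and emits a run manifest (`manifest.json`) with the tool
#' version, seed, configuration digest, input digests, timestamps and
#' per-stage counts. Data outputs are byte-identical across reruns with the
#' same configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for outputs (created if needed).
#' @param quiet Suppress per-stage progress messages (which go to standard
#'   error).
#' @return Invisibly, a list with the stage tibbles, the founder fit, and
#'   the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$pileup_path, config$proteome_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("Input file not found: ", p))
    }
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  digest <- config_digest(config[setdiff(names(config), "seed")])
  say <- function(...) if (!quiet) message("[straindrift] ", sprintf(...))

  say("stage 1/4: pileup")
  pileup <- if (is.null(config$pileup_path)) {
    simulate_pileup(demo_pileup_plan(seed = config$seed))
  } else {
    read_pileup(config$pileup_path)
  }
  write_pileup(pileup, file.path(output_dir, "pileup.tsv"), config$seed, digest)

  say("stage 2/4: variant screen (%d rows)", nrow(pileup))
  variant_report <- screen_variants(
    pileup, config$thresholds, config$strains, config$emergent_samples
  )
  write_tsv_with_header(
    variant_report, file.path(output_dir, "variant_report.tsv"),
    config$seed, digest
  )

  say("stage 3/4: cargo screen")
  proteome <- if (is.null(config$proteome_path)) {
    simulate_proteome(config$n_decoys, config$cargo,
      seed = config$seed, criteria = config$criteria
    )
  } else {
    read_fasta(config$proteome_path)
  }
  write_fasta(proteome, file.path(output_dir, "proteome.fasta"))
  cargo_report <- screen_proteome(proteome, config$criteria)
  write_tsv_with_header(
    dplyr::select(cargo_report, -"nonamer_hits", -"ca_hits", -"glyala_segments"),
    file.path(output_dir, "cargo_report.tsv"), config$seed, digest
  )

  say("stage 4/4: reactor and founder back-calculation")
  trajectory <- simulate_reactor(
    config$reactor, config$founders, config$duration
  )
  write_trajectory(
    dplyr::select(trajectory, "time_h", "protein_ug_per_cm2", "censored"),
    file.path(output_dir, "trajectory.tsv"), config$seed, digest
  )
  usable <- trajectory[!trajectory$censored & !trajectory$at_capacity &
    trajectory$time_h > 0, ]
  founder_fit <- if (nrow(usable)) {
    back_calculate_founders(
      usable$protein_ug_per_cm2[nrow(usable)], usable$time_h[nrow(usable)],
      config$reactor$generation_time, config$non_producer_fraction,
      config$reactor$geometry, config$reactor$constants
    )
  } else {
    NULL
  }
  if (!is.null(founder_fit)) {
    write_tsv_with_header(
      tidy(founder_fit), file.path(output_dir, "founder_backcalc.tsv"),
      config$seed, digest
    )
  }

  manifest <- list(
    tool = "straindrift",
    version = as.character(packageVersion("straindrift")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_digest = digest,
    inputs = list(
      pileup = config$pileup_path %||% "simulated",
      proteome = config$proteome_path %||% "simulated"
    ),
    counts = list(
      pileup_rows = nrow(pileup),
      variant_keys = nrow(variant_report),
      strain_unique = sum(variant_report$label == "strain_unique"),
      shared_all = sum(variant_report$label == "shared_all"),
      proteins_screened = nrow(cargo_report),
      cargo_candidates = sum(cargo_report$verdict == "candidate"),
      trajectory_points = nrow(trajectory)
    )
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  say("done: %d variant keys, %d cargo candidates",
    nrow(variant_report), sum(cargo_report$verdict == "candidate"))
  invisible(list(
    pileup = pileup, variant_report = variant_report,
    proteome = proteome, cargo_report = cargo_report,
    trajectory = trajectory, founder_fit = founder_fit,
    manifest = manifest
  ))
}
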