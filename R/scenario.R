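# End-to-end scenario workflows with reproducible run manifests:
#   druglike        - GAN -> sample -> generation metrics -> library search
#   target_biased   - conditional GAN -> sample(active) -> search -> rank
#   compound_series - mask from a core pattern -> masked conditional GAN ->
#                     sample -> search -> substructure confirmation -> rank

#' Default scenario configuration
#'
#' Returns the configuration list [scenario_run()] validates against, with
#' every training default pre-filled (pretraining epochs 100, GAN epochs
#' 800, batch 32, learning rates 1e-6/1e-3, similarity bands
#' 0.70/0.75/0.80/0.85) and the synthetic fixture generators as the data
#' source. Any entry can be overridden by the YAML config file passed to
#' [scenario_run()].
#'
#' @return nested named list.
#' @export
scenario_default_config <- function() {
  list(
    config_version = 1L,
    data = list(
      source = "synthetic",
      n_active = 2000L, n_inactive = 2000L, length = 168L,
      signature_bits = 1:20, p_on_active = 0.9, p_on_inactive = 0.1,
      background_p = 0.3,
      library_n = 1000L, library_fraction_with_core = 0.3,
      smiles_file = NULL, labels_file = NULL
    ),
    training = list(
      architecture = "AlexNet",
      d_epochs = 100L, gan_epochs = 800L, batch_size = 32L,
      d_learning_rate = 1e-6, g_learning_rate = 1e-3,
      pretrain_learning_rate = 1e-3, l2_coeff = 1e-4
    ),
    sampling = list(n_samples = 10000L, threshold = 0.5),
    search = list(thresholds = c(0.70, 0.75, 0.80, 0.85), mw_range = NULL,
                  top_n = 10L),
    mcs = list(smarts = default_core_smarts())
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

validate_config <- function(cfg) {
  required <- c("data", "training", "sampling", "search", "mcs")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config is missing sections: ", paste(missing, collapse = ", "))
  }
  if (!cfg$training$architecture %in% architecture_names()) {
    stop("unknown architecture in config: ", cfg$training$architecture)
  }
  invisible(cfg)
}

write_manifest <- function(path, command, cfg, seed, inputs = character(),
                           status = "running") {
  manifest <- list(
    command = command,
    status = status,
    seed = seed,
    config = cfg,
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    package_version = as.character(utils::packageVersion("fpgan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Run an end-to-end generation scenario
#'
#' Executes one of the three workflows against the configured data source
#' (the synthetic fixture generators by default), writing every stage output
#' and a run manifest into `out_dir`:
#' \describe{
#'   \item{druglike}{train an unconditional GAN on the actives, sample,
#'     compute the generation metrics, search the library.}
#'   \item{target_biased}{train a conditional GAN on actives+inactives,
#'     sample with the active label, search, rank by similarity and QED.}
#'   \item{compound_series}{build a mask from the core pattern's fingerprint
#'     bits, train a masked conditional GAN, sample, search, run two-round
#'     substructure confirmation, rank.}
#' }
#'
#' @param name scenario name (`"druglike"`, `"target_biased"`,
#'   `"compound_series"`).
#' @param config path to a YAML config file overriding
#'   [scenario_default_config()], or a config list, or `NULL` for the
#'   defaults.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the whole run.
#' @return (invisibly) a list with the fitted model, the generated
#'   fingerprints, the generation report and the search result.
#' @export
scenario_run <- function(name = c("druglike", "target_biased",
                                  "compound_series"),
                         config = NULL, out_dir = tempfile("fpgan_run_"),
                         seed = 1L) {
  name <- match.arg(name)
  cfg <- scenario_default_config()
  inputs <- character()
  if (is.character(config)) {
    inputs <- config
    config <- yaml::read_yaml(config)
  }
  if (is.list(config)) cfg <- merge_config(cfg, config)
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest_path, paste("scenario", name), cfg, seed, inputs)

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("scenario '", name, "' failed at stage [", what, "]: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  ## data
  dat <- stage("data", {
    dcfg <- cfg$data
    if (!identical(dcfg$source, "synthetic")) {
      rec <- read_molecules(dcfg$smiles_file)
      lab <- utils::read.csv(dcfg$labels_file, stringsAsFactors = FALSE)
      fps <- fp_encode(rec, scheme = "MACCS", length = dcfg$length)
      structure(list(fps = fps,
                     labels = as_binary_labels(
                       lab$label[match(rec$molecule_id, lab$id)],
                       nrow(rec))),
                class = "fp_labeled_set")
    } else {
      make_synthetic_fpset(
        n_active = dcfg$n_active, n_inactive = dcfg$n_inactive,
        length = dcfg$length, signature_bits = dcfg$signature_bits,
        p_on_active = dcfg$p_on_active, p_on_inactive = dcfg$p_on_inactive,
        background_p = dcfg$background_p, seed = seed)
    }
  })
  library <- stage("library", make_synthetic_library(
    n = cfg$data$library_n, planted_core_smarts = cfg$mcs$smarts,
    fraction_with_core = cfg$data$library_fraction_with_core,
    seed = seed + 1L))

  tcfg <- cfg$training
  train_config <- fp_training_config(
    d_epochs = tcfg$d_epochs, gan_epochs = tcfg$gan_epochs,
    batch_size = tcfg$batch_size, d_learning_rate = tcfg$d_learning_rate,
    g_learning_rate = tcfg$g_learning_rate,
    pretrain_learning_rate = tcfg$pretrain_learning_rate,
    l2_coeff = tcfg$l2_coeff, seed = seed)

  mask <- NULL
  if (name == "compound_series") {
    mask <- stage("mask", mcs_mask_from_smiles(
      cfg$mcs$smarts, scheme = "MACCS", length = cfg$data$length))
  }

  ## model
  fit <- stage("train", {
    if (name == "druglike") {
      fp_dcgan(dat, architecture = tcfg$architecture, config = train_config,
               epochs = tcfg$gan_epochs)
    } else {
      fp_cdcgan(dat, architecture = tcfg$architecture, mask = mask,
                config = train_config, epochs = tcfg$gan_epochs)
    }
  })

  write_fpgan_model(fit, file.path(out_dir, "model.rds"))

  ## sampling
  samples <- stage("sample", sample_fingerprints(
    fit, n = cfg$sampling$n_samples, seed = seed + 2L,
    label = if (fit$conditional) "active" else NULL,
    threshold = cfg$sampling$threshold))
  write_fingerprints(samples, file.path(out_dir, "generated_fingerprints.csv"))

  ## metrics
  training_fps <- dat$fps[dat$labels == "active"]
  report <- stage("evaluate", generation_report(samples, training_fps,
                                                seed = seed))
  utils::write.csv(report, file.path(out_dir, "generation_report.csv"),
                   row.names = FALSE)

  ## search
  res <- stage("search", search_library(
    samples, library, thresholds = cfg$search$thresholds,
    mw_range = cfg$search$mw_range))
  utils::write.csv(res$band_counts, file.path(out_dir, "band_counts.csv"),
                   row.names = FALSE)

  ranked <- NULL
  if (name == "compound_series") {
    res <- stage("confirm", mcs_confirm_hits(res, library, cfg$mcs$smarts))
  }
  if (name != "druglike" && nrow(res$hits) > 0L) {
    ranked <- stage("rank", {
      prof <- druglike_profile(
        library[library$molecule_id %in% res$hits$molecule_id, , drop = FALSE])
      rank_candidates(res, prof, top_n = cfg$search$top_n,
                      confirmed_only = name == "compound_series" &&
                        any(res$hits$mcs_confirmed))
    })
    utils::write.csv(ranked, file.path(out_dir, "top_candidates.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(res$hits, file.path(out_dir, "hits.csv"),
                   row.names = FALSE)

  write_manifest(manifest_path, paste("scenario", name), cfg, seed, inputs,
                 status = "completed")
  invisible(list(fit = fit, samples = samples, report = report,
                 search = res, ranked = ranked, out_dir = out_dir))
}
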