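## End-to-end orchestration: synthetic generation (optional) -> featurize ->
## tICA -> k-centers -> MSM -> PCCA+ -> TPT -> MFPT, with per-stage artifact
## files and a provenance manifest.

#' Default pipeline configuration
#'
#' Stage parameters for a full analysis run at desk scale. All values can be
#' overridden via `pipeline_config(...)`.
#'
#' @param ... overrides of the default fields.
#' @return Named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # synthetic generation
    n_traj = 252L, n_frames = 1000L,
    # tICA
    tica_lag_ns = 20, n_components = 4L, ridge = 1e-6,
    # clustering
    k = 90L,
    # MSM
    msm_lag_frames = 300L, reversible = TRUE,
    # lumping / kinetics
    n_macro = 9L, mc_steps = round(1e7 / 30), bootstrap_lists = 0L,
    tpt_source = NULL, tpt_sink = NULL,
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "PipelineConfig"
  cfg
}

.stage_log <- function(run, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(run)) cat(line, "\n", file = file.path(run, "pipeline.log"),
                         append = TRUE)
}

#' Run the full sliding-kinetics pipeline
#'
#' Executes generate (unless feature trajectories are supplied) -> tICA ->
#' k-centers -> MSM -> PCCA+ lumping -> TPT pathway decomposition -> MFPT
#' estimation, writing per-stage artifacts and a provenance manifest
#' (configuration, seed, package version) into the run directory when
#' `config$out_dir` is set. Reruns with an identical configuration and seed
#' reproduce the stochastic stages exactly.
#'
#' @param config a [pipeline_config()].
#' @param ftrajs optional list of [feature_trajectory()] objects; when NULL
#'   the synthetic generator provides them (and the ground-truth model is
#'   attached to the result).
#' @return List with the per-stage results: `model_true` (when synthetic),
#'   `tica`, `clusters`, `dtrajs`, `msm`, `lumping`, `tpt`, `pathways`,
#'   `kinetics_mc`, `kinetics_exact`, and `bootstrap` when requested.
#' @export
run_pipeline <- function(config = pipeline_config(), ftrajs = NULL) {
  run <- config$out_dir
  if (!is.null(run)) dir.create(run, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  stage <- "generate"
  out <- tryCatch({
    if (is.null(ftrajs)) {
      .stage_log(run, stage, sprintf("synthetic dataset %d x %d frames, seed %d",
                                     config$n_traj, config$n_frames, config$seed))
      model_true <- build_sliding_model()
      ds <- generate_dataset(model_true, config$n_traj, config$n_frames,
                             seed = config$seed)
      res$model_true <- model_true
      res$dtrajs_true <- ds$dtrajs
      ftrajs <- ds$ftrajs
    }

    stage <- "tica"
    .stage_log(run, stage, sprintf("lag %.3g ns, %d components",
                                   config$tica_lag_ns, config$n_components))
    tica <- fit_tica(ftrajs, lag = config$tica_lag_ns,
                     n_components = config$n_components, ridge = config$ridge)
    proj <- lapply(ftrajs, function(t) tica_transform(tica, t))
    res$tica <- tica

    stage <- "cluster"
    .stage_log(run, stage, sprintf("k-centers, k = %d", config$k))
    clusters <- kcenters_fit(proj, k = config$k)
    dtrajs <- lapply(proj, function(p) assign_clusters(clusters, p))
    res$clusters <- clusters
    res$dtrajs <- dtrajs

    stage <- "msm"
    .stage_log(run, stage, sprintf("lag %d frames, reversible = %s",
                                   config$msm_lag_frames, config$reversible))
    msm <- build_msm(dtrajs, lag = config$msm_lag_frames,
                     reversible = config$reversible)
    dropped <- config$k - nrow(msm$tpm)
    if (dropped > 0) .stage_log(run, stage, sprintf(
      "warning: %d state(s) outside the ergodic component dropped", dropped))
    res$msm <- msm

    stage <- "lump"
    .stage_log(run, stage, sprintf("PCCA+ into %d macrostates", config$n_macro))
    lumping <- pcca_lump(msm, config$n_macro)
    res$lumping <- lumping

    stage <- "tpt"
    src <- config$tpt_source
    snk <- config$tpt_sink
    if (is.null(src) || is.null(snk)) {
      # default: least- to most-populated macrostate
      src <- which.min(lumping$populations)
      snk <- which.max(lumping$populations)
    }
    .stage_log(run, stage, sprintf("macro %s -> %s", src, snk))
    tpt <- net_flux(msm, which(lumping$assignment %in% src),
                    which(lumping$assignment %in% snk))
    res$tpt <- tpt
    res$pathways <- top_pathways(tpt, n_paths = 10L)

    stage <- "mfpt"
    .stage_log(run, stage, sprintf("MC %d steps", config$mc_steps))
    mc <- mc_trajectory(msm, n_steps = config$mc_steps, seed = config$seed)
    res$kinetics_mc <- mfpt_from_mc(mc, lumping)
    res$kinetics_exact <- mfpt_exact(msm, lumping)
    if (config$bootstrap_lists > 0L) {
      .stage_log(run, stage, sprintf("bootstrap, %d lists",
                                     config$bootstrap_lists))
      res$bootstrap <- bootstrap_kinetics(
        dtrajs, lumping, lag = config$msm_lag_frames,
        n_lists = config$bootstrap_lists, mc_steps = config$mc_steps,
        seed = config$seed)
    }
    res
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(run)) {
    write_dtrajs(out$dtrajs, file.path(run, "dtrajs"))
    write_model(out$msm, file.path(run, "msm.json"))
    utils::write.csv(data.frame(macro = seq_len(out$lumping$n_macro),
                                population = out$lumping$populations),
                     file.path(run, "populations.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(out$kinetics_mc$mfpt_ns),
                     file.path(run, "mfpt_mc_ns.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(out$pathways, function(p)
        list(states = p$states, flux = p$flux, share = p$share)),
      file.path(run, "pathways.json"), auto_unbox = TRUE, digits = NA)
    prov <- list(package = "slidemsm",
                 version = as.character(utils::packageVersion("slidemsm")),
                 seed = config$seed,
                 config = unclass(config)[!vapply(config, is.null, logical(1))],
                 config_hash = sum(utf8ToInt(paste(
                   names(config), vapply(config, function(v)
                     paste(format(v), collapse = ","), character(1)),
                   collapse = ";"))))
    jsonlite::write_json(prov, file.path(run, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
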