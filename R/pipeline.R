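# End-to-end orchestration: simulate (or read) a community, build
# probability matrices, sample webs, census motifs, benchmark against
# Curveball nulls, fit richness trends, and record a run manifest.

#' Default pipeline configuration
#'
#' @param global_seed master seed for every stochastic stage.
#' @param alpha,beta encounter scalars (see [scalar_config()]). The defaults
#'   keep encounter probabilities density-dependent (unsaturated) at the
#'   abundance scale of the default synthetic community while holding
#'   sampled web sizes in the empirically plausible envelope; see the
#'   methods vignette and [calibrate_scalars()] for the generality-targeted
#'   calibration procedure applicable to field data.
#' @param iterations binary webs sampled per probability matrix.
#' @param R null webs per sampled iteration.
#' @param trades_factor Curveball trades per null sample, as a multiple of
#'   the number of consumer rows.
#' @param scenario_strength strength of the diversity-scaled predator-prey
#'   scenario (0 disables it; see [diversity_scaled_scalars()]).
#' @param generator a [generator_config()] for the simulated community, or
#'   NULL when reading data with `data_dir`.
#' @param data_dir directory of community files to read instead of
#'   simulating.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(global_seed = 1L, alpha = 800, beta = 100,
                            iterations = 50L, R = 250L, trades_factor = 5L,
                            scenario_strength = 0,
                            generator = generator_config(global_seed =
                              global_seed),
                            data_dir = NULL) {
  structure(list(global_seed = global_seed, alpha = alpha, beta = beta,
                 iterations = iterations, R = R,
                 trades_factor = trades_factor,
                 scenario_strength = scenario_strength,
                 generator = generator, data_dir = data_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys: `global_seed`, `alpha`, `beta`, `iterations`, `R`,
#' `trades_factor`, `scenario_strength`, `data_dir`, and a nested
#' `generator` block of [generator_config()] arguments. Unknown keys are an
#' error.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "generator")
  bad <- setdiff(names(raw), c(known, "generator"))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  gen_args <- raw$generator %||% list()
  bad <- setdiff(names(gen_args), names(formals(generator_config)))
  if (length(bad))
    stop("unknown generator key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  raw$generator <- NULL
  if (!is.null(raw$global_seed) && is.null(gen_args$global_seed))
    gen_args$global_seed <- raw$global_seed
  args <- c(raw, list(generator = do.call(generator_config, gen_args)))
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Simulate-or-read -> probability webs -> motif/null profiles per
#' plot-period -> richness trends and summaries. All stage seeds derive
#' deterministically from the global seed, so a rerun with the same
#' configuration is bit-identical.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param out_dir optional directory; when given, the community files,
#'   `profiles.tsv`, `trends.tsv`, `summaries_*.tsv` and `manifest.yaml`
#'   are written there.
#' @param verbose print progress messages.
#' @return list with elements `community`, `profiles` (per plot-period x
#'   scope x class), `trends`, `summaries`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()

  comm <- if (!is.null(config$data_dir)) read_community(config$data_dir)
          else generate_community(config$generator)
  base_sc <- scalar_config(config$alpha, config$beta)

  periods <- unique(comm$samples$time_period)
  keys <- expand.grid(plot_id = comm$design$plot_id, time_period = periods,
                      stringsAsFactors = FALSE)
  prof <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    pl <- keys$plot_id[i]; pd <- keys$time_period[i]
    sr <- comm$design$sown_richness[comm$design$plot_id == pl]
    sc <- if (config$scenario_strength > 0)
      diversity_scaled_scalars(base_sc, sr, config$scenario_strength)
      else base_sc
    pweb <- build_probabilistic_web(comm, pl, pd, sc)
    prof[[i]] <- profile_pipeline(pweb, iterations = config$iterations,
                                  R = config$R,
                                  trades_factor = config$trades_factor,
                                  seed = config$global_seed)
    if (verbose && i %% 40 == 0)
      message(sprintf("  profiled %d/%d plot-periods", i, nrow(keys)))
  }
  profiles <- do.call(rbind, prof)
  profiles <- merge(profiles, comm$design, by = "plot_id", sort = FALSE)

  trends <- fit_all_trends(profiles)
  summaries <- summarize_profiles(profiles)

  manifest <- list(
    package_version = as.character(packageVersion("motifweb")),
    global_seed = config$global_seed,
    alpha = config$alpha, beta = config$beta,
    iterations = config$iterations, R = config$R,
    trades_factor = config$trades_factor,
    scenario_strength = config$scenario_strength,
    data_source = if (is.null(config$data_dir)) "simulated"
                  else config$data_dir,
    n_plot_periods = nrow(keys),
    seed_rule = "derive_seed(global_seed, plot_id, time_period, 'profile')",
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- write_community(comm, file.path(out_dir, "data"))
    write.table(profiles, file.path(out_dir, "profiles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(trends, file.path(out_dir, "trends.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summaries$shares, file.path(out_dir, "summaries_shares.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summaries$totals, file.path(out_dir, "summaries_totals.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(paths, file.path(out_dir, c("profiles.tsv", "trends.tsv",
                                           "summaries_shares.tsv",
                                           "summaries_totals.tsv")))
    manifest$file_md5 <- as.list(tools::md5sum(unname(files)))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(community = comm, profiles = profiles, trends = trends,
       summaries = summaries, manifest = manifest)
}
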