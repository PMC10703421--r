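#' Load a simulation configuration file
#'
#' Reads a structured key-value (YAML) configuration and returns fully
#' validated simulation objects.  Unset fields take the calibrated
#' defaults; unknown keys are rejected with the offending key named.  The
#' shipped default file (`system.file("extdata", "default-config.yaml",
#' package = "mitosim")`) reproduces the calibrated parameter set with the
#' aggregate-expression evaluation laws and biased fission on.
#'
#' @param path Path to a YAML configuration file.
#' @return List with elements `params` ([sim_params()]), `config`
#'   ([sim_config()]), `seeding` ([seeding_spec()]) and `run` (list of run
#'   controls: `n_reps`, `base_seed`, `snapshot_dt`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("parameters", "profiles", "configuration", "seeding", "run")
  check_keys(raw, known_top, "top level")

  p <- raw$parameters
  check_keys(p, c("unit_mito_volume", "mother_cell_volume",
                  "total_mito_volume", "bud_mito_volume", "dump_occupancy",
                  "dt_sim", "dt_expt", "t_equil", "t_eval", "prob_model",
                  "diffusion_floor"), "parameters")
  profiles <- default_profiles()
  if (!is.null(raw$profiles)) {
    check_keys(raw$profiles, c("wt", "dump_neg", "dump_pos"), "profiles")
    for (nm in names(raw$profiles)) {
      blk <- raw$profiles[[nm]]
      check_keys(blk, c("fission", "fusion", "diffusion"),
                 paste0("profiles.", nm))
      for (law in names(blk)) {
        check_keys(blk[[law]], c("slope", "intercept"),
                   paste0("profiles.", nm, ".", law))
        field <- paste0(law, "_law")
        profiles[[nm]][[field]] <- rate_law(blk[[law]]$slope,
                                            blk[[law]]$intercept)
      }
    }
  }
  params <- do.call(sim_params, c(p, list(profiles = profiles)))

  cc <- raw$configuration
  check_keys(cc, c("fission_fusion", "diffusion", "placement_mode",
                   "biased_fraction"), "configuration")
  bias <- bias_config(
    placement_mode = cc[["placement_mode"]] %||% "biased",
    biased_fraction = cc[["biased_fraction"]] %||%
      if ((cc[["placement_mode"]] %||% "biased") == "random") 0 else 1)
  config <- sim_config(fission_fusion = cc[["fission_fusion"]] %||% "mitofluc",
                       diffusion = cc[["diffusion"]] %||% "mitofluc",
                       bias = bias)

  ss <- raw$seeding
  check_keys(ss, c("mode", "cluster_count", "cluster_count_distribution",
                   "total_marked"), "seeding")
  seeding <- seeding_spec(
    mode = ss[["mode"]] %||% "clustered",
    cluster_count = ss[["cluster_count"]],
    cluster_count_distribution =
      if (!is.null(ss[["cluster_count_distribution"]]))
        as.numeric(unlist(ss[["cluster_count_distribution"]])),
    total_marked = ss[["total_marked"]])

  rr <- raw$run
  check_keys(rr, c("n_reps", "base_seed", "snapshot_dt"), "run")
  run <- list(n_reps = rr[["n_reps"]] %||% 1L,
              base_seed = rr[["base_seed"]] %||% 1L,
              snapshot_dt = rr[["snapshot_dt"]] %||% params$dt_expt)
  stopifnot(run$n_reps >= 1)

  list(params = params, config = config, seeding = seeding, run = run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(block, known, where) {
  if (is.null(block)) return(invisible())
  bad <- setdiff(names(block), known)
  if (length(bad) > 0)
    stop("unknown configuration key at ", where, ": ",
         paste(bad, collapse = ", "))
  invisible()
}

#' Write a run record to a directory
#'
#' Persists a [run_simulation()] record as plain-text artifacts: the event
#' log and snapshots as CSV and the run metadata (seed, parameter hash,
#' configuration label, seeding spec, seed-time edge set) as JSON.
#'
#' @param record A [run_simulation()] record.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(record$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(record$snapshots, file.path(dir, "snapshots.csv"),
                   row.names = FALSE)
  meta <- c(record$meta, list(
    seed_time = record$seed_time,
    edges_at_seed = record$edges_at_seed,
    final_time = record$final_state$time,
    config = list(fission_fusion = record$config$fission_fusion,
                  diffusion = record$config$diffusion,
                  placement_mode = record$config$bias$placement_mode,
                  biased_fraction = record$config$bias$biased_fraction),
    seeding = list(mode = record$seeding$mode,
                   cluster_count = record$seeding$cluster_count,
                   cluster_count_distribution =
                     record$seeding$cluster_count_distribution,
                   total_marked = record$seeding$total_marked),
    parameters = list(
      unit_mito_volume = record$params$unit_mito_volume,
      mother_cell_volume = record$params$mother_cell_volume,
      total_mito_volume = record$params$total_mito_volume,
      bud_mito_volume = record$params$bud_mito_volume,
      dump_occupancy = record$params$dump_occupancy,
      dt_sim = record$params$dt_sim, dt_expt = record$params$dt_expt,
      t_equil = record$params$t_equil, t_eval = record$params$t_eval,
      prob_model = record$params$prob_model,
      diffusion_floor = record$params$diffusion_floor)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a run record written by [write_record()]
#'
#' @param dir Directory containing `events.csv`, `snapshots.csv` and
#'   `meta.json`.
#' @return A `sim_record` equivalent to the one written (law profiles are
#'   taken from [default_profiles()] unless supplied).
#' @param profiles Optional condition profiles for the rebuilt parameter
#'   set.
#' @export
read_record <- function(dir, profiles = default_profiles()) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pm <- meta$parameters
  params <- sim_params(
    unit_mito_volume = pm$unit_mito_volume,
    mother_cell_volume = pm$mother_cell_volume,
    total_mito_volume = pm$total_mito_volume,
    bud_mito_volume = pm$bud_mito_volume,
    dump_occupancy = pm$dump_occupancy,
    dt_sim = pm$dt_sim, dt_expt = pm$dt_expt,
    t_equil = pm$t_equil, t_eval = pm$t_eval,
    profiles = profiles, prob_model = pm$prob_model,
    diffusion_floor = pm$diffusion_floor)
  config <- sim_config(
    fission_fusion = meta$config$fission_fusion,
    diffusion = meta$config$diffusion,
    bias = bias_config(meta$config$placement_mode,
                       meta$config$biased_fraction))
  nz <- function(x) if (length(x) == 0) NULL else x   # JSON null -> NULL
  seeding <- seeding_spec(
    mode = meta$seeding$mode,
    cluster_count = nz(meta$seeding$cluster_count),
    cluster_count_distribution =
      nz(as.numeric(unlist(meta$seeding$cluster_count_distribution))),
    total_marked = nz(meta$seeding$total_marked))
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  for (col in setdiff(names(events), "event_type"))
    events[[col]] <- as.numeric(events[[col]])
  snaps <- utils::read.csv(file.path(dir, "snapshots.csv"))
  rec <- structure(list(
    meta = list(seed = meta$seed, config_label = meta$config_label,
                seeding_mode = meta$seeding_mode,
                n_clusters = meta$n_clusters,
                events_recorded = isTRUE(meta$events_recorded),
                parameter_hash = meta$parameter_hash),
    params = params, config = config, seeding = seeding,
    events = events, snapshots = snaps,
    edges_at_seed = matrix(as.integer(meta$edges_at_seed), ncol = 2),
    seed_time = meta$seed_time,
    final_state = NULL), class = "sim_record")
  rec$final_state <- state_at(rec, meta$final_time)
  rec
}
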