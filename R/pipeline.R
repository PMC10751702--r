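# Reproducible end-to-end runs: configuration, presets, fixture generation.

#' Run configuration
#'
#' Assembles and validates the full configuration of an end-to-end run.  Two
#' presets are shipped: `"desk"` (1 straight 200-bp target, 1e5 histories,
#' 3 repeats -- the default; the whole pipeline runs in minutes) and
#' `"paper"` (6 condensed 1122-bp targets, 1e7 histories, 10 repeats -- the
#' full-scale study protocol, long-running and opt-in).
#'
#' @param preset `"desk"` or `"paper"`.
#' @param ... overrides of individual fields: `energies` (eV), `n_histories`,
#'   `n_repeats`, `master_seed`, `n_targets`, `n_bp`, `mode`, `spacing`,
#'   `world_edge` (nm), `source_distance` (nm), `cutoff` (eV), `cell_size`
#'   (nm), `output_dir`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    energies = c(4, 6, 10, 15, 20, 30, 50, 100, 200, 500),
    n_histories = if (preset == "desk") 1e5 else 1e7,
    n_repeats = if (preset == "desk") 3L else 10L,
    master_seed = 1L,
    n_targets = if (preset == "desk") 1L else 6L,
    n_bp = if (preset == "desk") 200L else 1122L,
    mode = if (preset == "desk") "straight" else "condensed",
    spacing = 40,
    world_edge = 400,
    source_distance = 40,
    cutoff = 1.0,
    cell_size = 1.0,
    output_dir = "dnatrackmc-run")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(all(cfg$energies > 0), cfg$n_histories >= 0,
            cfg$n_repeats >= 1, cfg$n_bp >= 1, cfg$n_targets >= 1,
            cfg$world_edge > 0, cfg$source_distance > 0, cfg$cutoff > 0,
            cfg$cell_size > 0, cfg$mode %in% c("straight", "condensed"))
  # the world box must enclose the geometry and the source stand-off
  geom_extent <- (cfg$n_bp - 1) * BDNA_RISE_NM
  if (cfg$mode == "condensed") geom_extent <- min(geom_extent, 40)
  need <- geom_extent + 2 * (cfg$source_distance + 5)
  if (cfg$world_edge < min(need, geom_extent + 10))
    stop("world box too small for the geometry")
  structure(cfg, class = "run_config")
}

#' Execute a full configured run
#'
#' Builds the scene and tracking context once, then simulates every beam
#' energy for every repeat, scores damage and writes: a per-repeat results
#' table (TSV, one row per energy x repeat), an aggregated mean/sd table
#' (TSV), and the resolved configuration with the master seed (YAML).  Rerun
#' with the same configuration and seed, the outputs are byte-identical.
#'
#' @param config a `run_config`.
#' @param quiet suppress per-energy progress messages.
#' @param dry_run validate the configuration and build the geometry, but do
#'   not simulate.
#' @return Invisibly, a list with `per_repeat`, `aggregate`, `model` and the
#'   output file paths.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE,
                         dry_run = FALSE) {
  config <- validate_run_config(config)
  model <- build_scene(n_targets = config$n_targets, n_bp = config$n_bp,
                       mode = config$mode, spacing = config$spacing,
                       seed = config$master_seed)
  if (dry_run) {
    if (!quiet) message("dry run: configuration and geometry are valid")
    return(invisible(list(config = config, model = model)))
  }
  ctx <- tracking_context(model, world_edge = config$world_edge,
                          cell_size = config$cell_size,
                          cutoff = config$cutoff)
  rules <- damage_rules()
  rows <- list()
  for (e in config$energies) {
    if (!quiet) message(sprintf("energy %g eV ...", e))
    for (r in seq_len(config$n_repeats)) {
      src <- source_for_model(model, e, distance = config$source_distance,
                              n_histories = config$n_histories)
      seed_er <- derive_seed(config$master_seed,
                             match(e, config$energies) * 1e7 + r * 1e4)
      sim <- run_simulation(ctx, src, seed = seed_er)
      row <- summarize_run(sim, model, rules)
      row[, repeat_index := r]
      rows[[length(rows) + 1L]] <- row
      if (!quiet) {
        imb <- ledger_imbalance(sim)
        message(sprintf("  repeat %d: %d events, ledger imbalance %.2e",
                        r, nrow(sim$events), imb))
      }
    }
  }
  per_repeat <- rbindlist(rows)
  agg <- per_repeat[, .(mean = sapply(.SD, mean), sd = sapply(.SD, sd),
                        quantity = names(.SD)),
                    by = energy_ev,
                    .SDcols = setdiff(names(per_repeat),
                                      c("energy_ev", "seed", "repeat_index"))]
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  f_rep <- file.path(config$output_dir, "results_per_repeat.tsv")
  f_agg <- file.path(config$output_dir, "results_aggregate.tsv")
  f_cfg <- file.path(config$output_dir, "config.yaml")
  fwrite(per_repeat, f_rep, sep = "\t")
  fwrite(agg[, .(energy_ev, quantity, mean, sd)], f_agg, sep = "\t")
  yaml::write_yaml(unclass(config), f_cfg)
  invisible(list(per_repeat = per_repeat, aggregate = agg, model = model,
                 files = c(per_repeat = f_rep, aggregate = f_agg,
                           config = f_cfg)))
}

#' Generate deterministic fixtures
#'
#' Writes, depending on `kind`: a PDB geometry fixture (`"geometry"`), the
#' cross-section table set (`"xsec"`), or a synthetic event-stream TSV
#' (`"events"`) for damage-module-only testing.  Same seed, same bytes.
#'
#' @param kind `"geometry"`, `"xsec"` or `"events"`.
#' @param params list of parameters: for geometry `n_bp`, `mode`; for xsec
#'   the [xsec_fixture_params()] list; for events `n_events`, `n_bp`,
#'   `channel`, `kind_hit`, `deposit_ev`.
#' @param seed integer seed.
#' @param path output file (geometry/events) or directory (xsec).
#' @return `path`, invisibly.
#' @export
generate_fixtures <- function(kind = c("geometry", "xsec", "events"),
                              params = list(), seed = 1L, path) {
  kind <- match.arg(kind)
  switch(kind,
    geometry = {
      model <- build_bdna(params$n_bp %||% 10L,
                          mode = params$mode %||% "straight", seed = seed)
      write_pdb(model, path)
    },
    xsec = {
      lib <- build_fixture_library(params = if (length(params)) params
                                   else xsec_fixture_params(), seed = seed)
      export_xsec(lib, path)
    },
    events = {
      n <- params$n_events %||% 10L
      n_bp <- params$n_bp %||% 200L
      ev <- with_local_seed(seed, data.table(
        history_id = seq_len(n),
        lineage = "primary",
        channel = params$channel %||% "dea",
        kind = params$kind_hit %||% "phosphate",
        group = molecule_group(params$kind_hit %||% "phosphate"),
        strand = sample(1:2, n, replace = TRUE),
        bp_index = sample.int(n_bp, n, replace = TRUE),
        target = 1L,
        molecule_id = seq_len(n),
        x = 0, y = 0, z = 0,
        deposit_ev = params$deposit_ev %||% 7,
        element = "P"))
      fwrite(ev, path, sep = "\t")
    })
  invisible(path)
}
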