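#' Default run configuration
#'
#' All stage parameters with their canonical defaults: pulling at 200 nm/s,
#' the 60 pN constant-force clamp, 25 ms low-pass window, 1-60 pN rupture
#' peak bounds, 0.5 pN compaction reference force, 2 pN unzip interaction
#' threshold, 80% breakage cutoff, 30 s Savitzky-Golay constant, 0.2-turn
#' dwell bins, 2 s dwell threshold, 0.4-turn assignment radius, 0.5-turn rate
#' bins, 30-turn censoring, 0.22 pN holding force, 2 nm capture distance,
#' 45 nm persistence length, 1e5/1.5e6 MC steps and 50-degree pivots.
#'
#' @param seed integer seed recorded in (and used by) every stage.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    elasticity = list(persistence_length_nm = 45, stretch_modulus_pN = 1200,
                      rise_per_bp_nm = 0.338, temperature_K = 296.15),
    stretch = list(velocity_nm_s = 200, clamp_force_pN = 60,
                   filter_window_s = 0.025, target_rate_hz = 1000,
                   min_peak_pN = 1, max_peak_pN = 60,
                   compaction_force_pN = 0.5, escape_force_pN = 110,
                   template_bp = 12688),
    unzip = list(velocity_nm_s = 400, threshold_pN = 2,
                 breakage_cutoff_fraction = 0.8, filter_window_s = 0.025),
    twist = list(sg_constant_s = 30, turn_bin = 0.2, dwell_threshold_s = 2,
                 assign_radius_turns = 0.4, rate_bin_turns = 0.5,
                 censor_turns = 30, force_pN = 0.22, initial_turns = 40,
                 rate_hz = 10),
    loop_mc = list(n_equil = 1e5, n_prod = 1.5e6, pivot_max_angle_deg = 50,
                   r_capture_nm = 2, segment_bp = 5)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else keeps its canonical value.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  structure(modifyList(unclass(cfg), user), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration (seed", x$seed, "):\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

# stable hash of a config for run logs: short digest of its serialization
.config_hash <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %%
            .Machine$integer.max)
}

#' Run a generate-then-analyze pipeline
#'
#' Executes the configured stage sequence over seeded synthetic data and
#' returns a summary; per-trace failures are caught, logged and skipped so
#' partial results survive. Currently wired stages: `"stretch"`
#' (constant-velocity generation, rupture detection, loop sizing,
#' compaction) and `"twist"` (relaxation generation, pause pipeline).
#'
#' @param config a [default_run_config()] (or [read_run_config()]) object.
#' @param stages character vector, subset of `c("stretch", "twist")`.
#' @param n_traces traces per stage (default 5).
#' @param out optional directory; when given, the summary is written to
#'   `summary.json` and per-trace event tables to TSV files inside it.
#' @return list with one entry per stage plus `config_hash`, `seed` and
#'   `errors` (character vector of per-trace failure messages).
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("stretch", "twist"), n_traces = 5,
                         out = NULL) {
  stages <- match.arg(stages, c("stretch", "twist"), several.ok = TRUE)
  el <- ds_dna_elasticity(config$elasticity$persistence_length_nm,
                          config$elasticity$stretch_modulus_pN,
                          config$elasticity$rise_per_bp_nm,
                          config$elasticity$temperature_K)
  errors <- character(0)
  result <- list(config_hash = .config_hash(config), seed = config$seed)

  if ("stretch" %in% stages) {
    per_trace <- list()
    for (i in seq_len(n_traces)) {
      res <- tryCatch({
        seed_i <- config$seed * 1000 + i
        set.seed(seed_i)
        nl <- 1 + rbinom(1, 2, 0.5)
        forces <- sort(runif(nl, 10, 45))
        while (nl > 1 && min(diff(forces)) < 3) forces <- sort(runif(nl, 10, 45))
        loops <- data.frame(
          loop_bp = round(runif(nl, 200, 500)),
          rupture_force_pN = forces
        )
        sc <- stretch_scenario(template_bp = config$stretch$template_bp,
                               loops = loops,
                               velocity = config$stretch$velocity_nm_s,
                               rate = 10 * config$stretch$target_rate_hz,
                               seed = seed_i)
        tr <- gen_stretch_trace(sc, el)
        fl <- decimate_and_filter(tr, config$stretch$target_rate_hz,
                                  config$stretch$filter_window_s)
        ev <- detect_ruptures(fl, config$stretch$min_peak_pN,
                              config$stretch$max_peak_pN)
        sizes <- vapply(seq_len(nrow(ev)), function(k) {
          loop_size_of_event(fl, ev[k, ], el)$released_bp
        }, numeric(1))
        list(trace = i, n_loops_true = nl, events = ev,
             released_bp = sizes,
             extension_at_ref =
               extension_at_reference_force(fl,
                                            config$stretch$compaction_force_pN))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, sprintf("stretch trace %d: %s", i,
                                    conditionMessage(res)))
      } else {
        per_trace[[length(per_trace) + 1]] <- res
      }
    }
    result$stretch <- list(
      traces = per_trace,
      loops_per_trace = vapply(per_trace, function(p) nrow(p$events),
                               numeric(1)),
      mean_rupture_force = mean(unlist(lapply(per_trace, function(p) {
        p$events$peak_force
      })))
    )
  }

  if ("twist" %in% stages) {
    hat <- hat_curve(0, 3600, 10, 4, 4)
    per_trace <- list()
    for (i in seq_len(n_traces)) {
      res <- tryCatch({
        sc <- twist_scenario(hat = hat,
                             initial_turns = config$twist$initial_turns,
                             rate = config$twist$rate_hz,
                             seed = config$seed * 1000 + i)
        tr <- gen_twist_trace(sc)
        a <- analyze_twist_trace(tr, hat, sc$branch,
                                 config$twist$initial_turns,
                                 config$twist$sg_constant_s)
        list(trace = i, pause_free_rate = a$pause_free_rate,
             mean_rate = a$mean_rate, n_pauses = nrow(a$pauses),
             first_pause_turns = a$first_pause_turns)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, sprintf("twist trace %d: %s", i,
                                    conditionMessage(res)))
      } else {
        per_trace[[length(per_trace) + 1]] <- res
      }
    }
    fp <- vapply(per_trace, function(p) p$first_pause_turns, numeric(1))
    result$twist <- list(
      traces = per_trace,
      median_pause_free_rate =
        median(vapply(per_trace, function(p) p$pause_free_rate, numeric(1)),
               na.rm = TRUE),
      pause_frequency = if (length(fp) >= 10) {
        pause_frequency(fp, config$twist$censor_turns)$frequency
      } else NA_real_
    )
  }

  result$errors <- errors
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    slim <- result
    if (!is.null(slim$stretch)) slim$stretch$traces <- NULL
    if (!is.null(slim$twist)) slim$twist$traces <- NULL
    jsonlite::write_json(slim, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(result$stretch)) {
      for (p in result$stretch$traces) {
        write.table(p$events,
                    file.path(out, sprintf("stretch_events_%03d.tsv",
                                           p$trace)),
                    sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
  }
  result
}
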