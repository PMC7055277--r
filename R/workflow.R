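# Pipeline orchestration: runs the analysis stages in order, writing each
# stage's artifacts and a JSON report (parameters, seed, config hash, counts,
# wall time) so reruns are reproducible and auditable.

#' Pipeline stage names, in execution order
#' @export
PIPELINE_STAGES <- c("simulate", "grid", "build-od", "fit-degrees",
                     "fit-kernel", "odrank", "model-sim", "compare")

#' Read a pipeline configuration file
#'
#' @param path YAML file mirroring the per-stage parameter lists (see the
#'   package vignette for the schema).
#' @return a named list with class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config)[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

cfg_get <- function(config, stage, key, default = NULL) {
  v <- config[[stage]][[key]]
  if (is.null(v)) default else v
}

write_report <- function(out_dir, stage, config, seed, t0, extra = list()) {
  report <- c(list(stage = stage, seed = seed,
                   config_hash = config_hash(config),
                   elapsed_s = round(as.numeric(Sys.time()) - t0, 3)),
              extra)
  path <- file.path(out_dir, sprintf("report_%s.json", gsub("-", "_", stage)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  report
}

read_zoneset <- function(out_dir) {
  zs <- utils::read.csv(file.path(out_dir, "zoneset.csv"))
  class(zs) <- c("zone_set", "data.frame")
  zs
}

read_distances <- function(out_dir) {
  as.matrix(utils::read.csv(file.path(out_dir, "distances.csv"),
                            header = FALSE))
}

require_artifact <- function(out_dir, file, stage) {
  path <- file.path(out_dir, file)
  if (!file.exists(path)) {
    stop(sprintf("missing upstream artifact '%s'; run stage providing it before '%s'",
                 file, stage), call. = FALSE)
  }
  path
}

#' Run one pipeline stage
#'
#' Stages (run in this order by [run_pipeline()]):
#' `simulate` (synthetic trips), `grid` (endpoint binning + high-demand zone
#' selection + distances), `build-od` (OD matrix and degrees), `fit-degrees`
#' (degree-distribution model selection), `fit-kernel` (distance-kernel
#' estimation), `odrank` (spectrum + stationary distribution + mean-field q),
#' `model-sim` (Monte Carlo trips from the fitted kernel), `compare`
#' (empirical vs model displacement densities). Identical config + seed gives
#' identical outputs.
#'
#' @param stage stage name.
#' @param config a `pipeline_config` (or plain list).
#' @param out_dir output directory (created if missing); also where upstream
#'   artifacts are looked up.
#' @return the stage report (list), invisibly.
#' @export
run_stage <- function(stage, config, out_dir = config$out_dir %||% ".") {
  if (!stage %in% PIPELINE_STAGES) {
    stop(sprintf("unknown stage '%s'; available: %s", stage,
                 paste(PIPELINE_STAGES, collapse = ", ")), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  t0 <- as.numeric(Sys.time())
  log_msg <- function(...) message(sprintf("[odflow:%s] ", stage), sprintf(...))

  report <- switch(stage,
    "simulate" = {
      n_zones <- cfg_get(config, "simulate", "n_zones", 10)
      extent <- unlist(cfg_get(config, "simulate", "extent", c(2, 2)))
      layout <- make_zone_layout(cfg_get(config, "simulate", "layout_kind",
                                         "uniform-random"),
                                 n_zones, extent, seed = seed)
      att <- cfg_get(config, "simulate", "attractiveness", list(model = "uniform"))
      weights <- if (identical(att$model, "uniform")) {
        rep(1, n_zones)
      } else {
        sample_degree_values(att$model,
                             list(beta = att$beta, lambda = att$lambda,
                                  gamma = att$gamma),
                             k_min = att$k_min %||% 1000, n = n_zones,
                             seed = seed + 1L)
      }
      if (isTRUE(cfg_get(config, "simulate", "lonlat", FALSE))) {
        layout <- layout_to_lonlat(layout)
      }
      trips <- generate_trips(layout, weights,
                              kernel_R = cfg_get(config, "simulate", "kernel_R", 1.8),
                              kernel_beta = cfg_get(config, "simulate", "kernel_beta", 0.15),
                              n_trips = cfg_get(config, "simulate", "n_trips", 1000),
                              seed = seed + 2L,
                              jitter = isTRUE(cfg_get(config, "simulate", "jitter", TRUE)))
      write_trips(trips, file.path(out_dir, "trips.csv"))
      utils::write.csv(as.data.frame(layout), file.path(out_dir, "zones.csv"),
                       row.names = FALSE)
      log_msg("%d trips over %d zones", nrow(trips), n_zones)
      write_report(out_dir, stage, config, seed, t0,
                   list(n_trips = nrow(trips), n_zones = n_zones))
    },
    "grid" = {
      require_artifact(out_dir, "trips.csv", stage)
      trips <- read_trips(file.path(out_dir, "trips.csv"))
      cell <- cfg_get(config, "grid", "cell_side", 100)
      if (attr_mode(trips) == "lonlat") {
        lon <- c(trips$pickup_longitude, trips$dropoff_longitude)
        lat <- c(trips$pickup_latitude, trips$dropoff_latitude)
        ref <- cfg_get(config, "grid", "reference_latitude", 40.7)
        origin <- c(min(lon), min(lat))
        span <- project_point(cbind(max(lon), max(lat)),
                              grid_spec(cell, 1, 1, origin, ref, "lonlat"))
        grid <- grid_spec(cell, ceiling(span[1] / cell) + 1,
                          ceiling(span[2] / cell) + 1, origin, ref, "lonlat")
      } else {
        x <- c(trips$pickup_x, trips$dropoff_x)
        y <- c(trips$pickup_y, trips$dropoff_y)
        grid <- grid_spec(cell, ceiling(max(x) / cell) + 1,
                          ceiling(max(y) / cell) + 1, c(0, 0), mode = "planar")
      }
      counts <- count_endpoints(trips, grid)
      M <- cfg_get(config, "grid", "M", 1000)
      zs <- select_high_demand(counts, grid, M)
      res <- restrict_trips(trips, zs)
      utils::write.csv(as.data.frame(zs), file.path(out_dir, "zoneset.csv"),
                       row.names = FALSE)
      write_trips(res$trips, file.path(out_dir, "trips_restricted.csv"))
      D <- zone_distances(zs)
      utils::write.table(D, file.path(out_dir, "distances.csv"), sep = ",",
                         row.names = FALSE, col.names = FALSE)
      log_msg("%d high-demand zones (M = %d), retained %.2f%% of in-bounds trips",
              nrow(zs), M, 100 * res$fraction)
      write_report(out_dir, stage, config, seed, t0,
                   list(n_zones = nrow(zs), M = M,
                        retained_fraction = res$fraction,
                        n_excluded = counts$n_excluded))
    },
    "build-od" = {
      require_artifact(out_dir, "trips_restricted.csv", stage)
      trips <- read_trips(file.path(out_dir, "trips_restricted.csv"))
      zs <- read_zoneset(out_dir)
      od <- build_od(trips, n_zones = nrow(zs))
      Matrix::writeMM(od$T, file.path(out_dir, "od.mtx"))
      utils::write.csv(data.frame(zone_id = zs$zone_id, k_in = od$k_in,
                                  k_out = od$k_out),
                       file.path(out_dir, "degrees.csv"), row.names = FALSE)
      stats <- displacement_stats(trips)
      jsonlite::write_json(
        list(mean_km = stats$mean_km, max_km = stats$max_km,
             fractions = as.list(stats$fractions), n = stats$n),
        file.path(out_dir, "displacements.json"), auto_unbox = TRUE,
        digits = NA)
      log_msg("OD matrix %d x %d, %d trips", nrow(od$T), ncol(od$T),
              as.integer(od$total))
      write_report(out_dir, stage, config, seed, t0,
                   list(n_zones = nrow(od$T), total_trips = od$total))
    },
    "fit-degrees" = {
      require_artifact(out_dir, "degrees.csv", stage)
      deg <- utils::read.csv(file.path(out_dir, "degrees.csv"))
      k_min <- cfg_get(config, "fit_degrees", "k_min", 1000)
      out <- lapply(c(in_degree = "k_in", out_degree = "k_out"), function(col) {
        k <- deg[[col]][deg[[col]] >= k_min]
        if (length(k) < 50) return(list(skipped = "fewer than 50 degrees >= k_min"))
        sel <- select_best(k, k_min)
        list(best = sel$table$model[1],
             table = sel$table,
             params = lapply(sel$fits, function(f) as.list(f$params)))
      })
      jsonlite::write_json(out, file.path(out_dir, "degree_fits.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_report(out_dir, stage, config, seed, t0,
                   list(k_min = k_min,
                        best_in = out$in_degree$best %||% NA,
                        best_out = out$out_degree$best %||% NA))
    },
    "fit-kernel" = {
      require_artifact(out_dir, "od.mtx", stage)
      od_T <- methods::as(Matrix::readMM(file.path(out_dir, "od.mtx")),
                          "CsparseMatrix")
      D <- read_distances(out_dir)
      od <- list(T = od_T, k_out = Matrix::rowSums(od_T),
                 k_in = Matrix::colSums(od_T), total = sum(od_T))
      class(od) <- "od_matrix"
      W <- transition_matrix(od)
      pairs <- kernel_pairs(W, D,
                            d_min = cfg_get(config, "fit_kernel", "d_min", 0.1),
                            d_max = cfg_get(config, "fit_kernel", "d_max", 11))
      utils::write.csv(pairs, file.path(out_dir, "kernel_pairs.csv"),
                       row.names = FALSE)
      Rg <- cfg_get(config, "fit_kernel", "R_grid", c(0.5, 5, 0.1))
      scan <- select_R(pairs, seq(Rg[1], Rg[2], by = Rg[3]))
      jsonlite::write_json(
        list(R = scan$R, c = scan$fit$c, beta = scan$fit$beta,
             n_pairs = nrow(pairs),
             window = c(cfg_get(config, "fit_kernel", "d_min", 0.1),
                        cfg_get(config, "fit_kernel", "d_max", 11))),
        file.path(out_dir, "kernel.json"), auto_unbox = TRUE, digits = NA)
      log_msg("kernel fit: R = %.2f km, c = %.3f, beta = %.4f /km",
              scan$R, scan$fit$c, scan$fit$beta)
      write_report(out_dir, stage, config, seed, t0,
                   list(R = scan$R, c = scan$fit$c, beta = scan$fit$beta,
                        n_pairs = nrow(pairs)))
    },
    "odrank" = {
      require_artifact(out_dir, "od.mtx", stage)
      od_T <- methods::as(Matrix::readMM(file.path(out_dir, "od.mtx")),
                          "CsparseMatrix")
      od <- list(T = od_T, k_out = Matrix::rowSums(od_T),
                 k_in = Matrix::colSums(od_T), total = sum(od_T))
      class(od) <- "od_matrix"
      W <- transition_matrix(od)
      spec <- od_spectrum(W)
      utils::write.csv(data.frame(re = Re(spec$values), im = Im(spec$values)),
                       file.path(out_dir, "spectrum.csv"), row.names = FALSE)
      p_inf <- stationary_dist(W)
      oq <- optimal_q(p_inf, od$k_in, od$total)
      utils::write.csv(
        data.frame(zone_id = seq_along(p_inf), P_inf = p_inf, k_in = od$k_in,
                   meanfield_at_qstar = meanfield_rank(od$k_in, od$total,
                                                       min(max(oq$q_star, 0), 1))),
        file.path(out_dir, "odrank.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(q_star = oq$q_star, S_qstar = oq$S_qstar,
             unit_multiplicity = spec$unit_multiplicity,
             strongly_connected = spec$strongly_connected),
        file.path(out_dir, "odrank.json"), auto_unbox = TRUE, digits = NA)
      log_msg("q* = %.4f, unit multiplicity %d", oq$q_star,
              spec$unit_multiplicity)
      write_report(out_dir, stage, config, seed, t0,
                   list(q_star = oq$q_star,
                        unit_multiplicity = spec$unit_multiplicity))
    },
    "model-sim" = {
      require_artifact(out_dir, "kernel.json", stage)
      require_artifact(out_dir, "degrees.csv", stage)
      kern <- jsonlite::read_json(file.path(out_dir, "kernel.json"),
                                  simplifyVector = TRUE)
      deg <- utils::read.csv(file.path(out_dir, "degrees.csv"))
      D <- read_distances(out_dir)
      beta_sim <- max(kern$beta, 0)  # noisy fits on tiny inputs can dip below 0
      if (beta_sim != kern$beta) log_msg("clamping fitted beta %.4g to 0", kern$beta)
      Wm <- model_transition_matrix(D, kern$R, beta_sim)
      n <- cfg_get(config, "model_sim", "n_trips",
                   as.integer(sum(deg$k_out)))
      sim <- simulate_trips(Wm, deg$k_out, n, seed = seed + 3L, D = D)
      utils::write.csv(sim, file.path(out_dir, "model_trips.csv"),
                       row.names = FALSE)
      write_report(out_dir, stage, config, seed, t0,
                   list(n_trips = n, R = kern$R, beta = kern$beta))
    },
    "compare" = {
      require_artifact(out_dir, "model_trips.csv", stage)
      require_artifact(out_dir, "trips_restricted.csv", stage)
      sim <- utils::read.csv(file.path(out_dir, "model_trips.csv"))
      trips <- read_trips(file.path(out_dir, "trips_restricted.csv"))
      window <- unlist(cfg_get(config, "compare", "window", c(0.1, 40)))
      cmp <- compare_displacements(trip_distances(trips), sim$d_km,
                                   window = window)
      jsonlite::write_json(cmp, file.path(out_dir, "compare.json"),
                           auto_unbox = TRUE, digits = NA)
      log_msg("displacement densities: KS = %.4f, TV = %.4f", cmp$ks, cmp$tv)
      write_report(out_dir, stage, config, seed, t0, cmp)
    })
  invisible(report)
}

#' Run the full pipeline (or a subset of stages)
#'
#' @param config a `pipeline_config` or plain list; `config$seed` seeds every
#'   stochastic stage, `config$out_dir` receives all artifacts.
#' @param stages stage names in execution order (default: all).
#' @param out_dir output directory override.
#' @return named list of stage reports, invisibly.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES,
                         out_dir = config$out_dir %||% ".") {
  reports <- lapply(stages, run_stage, config = config, out_dir = out_dir)
  names(reports) <- stages
  invisible(reports)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
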