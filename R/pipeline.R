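# End-to-end orchestration: synthesise -> fit -> simulate -> report.
# The package functions are the primary interface; run_pipeline() wires
# them together for a reproducible demo cohort with provenance.

.config_schema <- function() {
  list(
    seed = "integer",
    out_dir = "character",
    stages = "character", # subset of cohort, tube, droplet, shape
    cohort = list(n_per_group = "numeric", beta_hindbrain_mean = "numeric",
                  beta_spinalcord_mean = "numeric", sd = "numeric",
                  noise_sd = "numeric"),
    tube = list(duration_h = "numeric", schedule = "character",
                n_segments = "numeric"),
    droplet = list(duration_h = "numeric", n_frames = "numeric",
                   gamma_N_m = "numeric", noise_sd = "numeric",
                   n_boot = "numeric"),
    shape = list(n_sections = "numeric", n_samples = "numeric",
                 window_um = "numeric")
  )
}

.validate_config <- function(config, schema = .config_schema(),
                             path = "config") {
  if (!is.list(config)) stop(path, " must be a list", call. = FALSE)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, "$", unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(config)) {
    want <- schema[[nm]]
    got <- config[[nm]]
    if (is.list(want)) {
      .validate_config(got, want, paste0(path, "$", nm))
    } else if (want == "numeric" || want == "integer") {
      if (!is.numeric(got)) stop(path, "$", nm, " must be numeric",
                                 call. = FALSE)
    } else if (want == "character" && !is.character(got)) {
      stop(path, "$", nm, " must be character", call. = FALSE)
    }
  }
  # domain bounds that must hold before any computation
  ch <- config$cohort
  if (!is.null(ch)) {
    for (k in intersect(c("beta_hindbrain_mean", "beta_spinalcord_mean"),
                        names(ch))) {
      if (ch[[k]] < 0 || ch[[k]] > 1) {
        stop("config$cohort$", k, " must lie in [0, 1]", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving every stochastic stage.
#' @return A validated config list for [run_pipeline()].
#' @export
default_config <- function(out_dir = tempfile("ntrun"), seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("cohort", "tube", "droplet", "shape"),
    cohort = list(n_per_group = 4, beta_hindbrain_mean = 0.35,
                  beta_spinalcord_mean = 0.15, sd = 0.05,
                  noise_sd = 0.05),
    tube = list(duration_h = 20, schedule = "onset_to_late",
                n_segments = 24),
    droplet = list(duration_h = 10, n_frames = 9,
                   gamma_N_m = nt_defaults()$droplet$gamma_N_m,
                   noise_sd = 0.2, n_boot = 0),
    shape = list(n_sections = 3, n_samples = 80, window_um = 100)
  )
}

#' Run the full synthetic-embryo analysis pipeline
#'
#' Executes the requested stages in dependency order on synthetic data
#' with known ground truth: `cohort` (paired creep experiments,
#' two-stage AFM fits, paired group statistics), `tube` (hindbrain vs
#' spinal-cord pressurized-tube simulation), `droplet` (forward droplet
#' rounding plus viscosity inversion) and `shape` (cross-sections,
#' thickness profiles, roof metrics). Every run writes tidy CSV/JSON
#' outputs plus a provenance record (config hash, seed, package version).
#' A stage failure aborts the run naming the stage; outputs already
#' written are retained and listed as partial in the provenance file.
#'
#' @param config A config list, see [default_config()]. Validated against
#'   the schema (unknown keys rejected) before any computation.
#' @return Invisibly, a run report list: per-stage outputs and file paths.
#' @export
run_pipeline <- function(config = default_config()) {
  .validate_config(config)
  config <- modifyList(default_config(out_dir = config$out_dir %||%
                                        tempfile("ntrun"),
                                      seed = config$seed %||% 1L),
                       config)
  .validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config, outputs = list(), stages_done = character())
  prov_path <- file.path(config$out_dir, "provenance.json")
  write_prov <- function(status) {
    cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    jsonlite::write_json(list(
      status = status, stages_done = report$stages_done,
      config_md5 = unname(tools::md5sum(tmp)), seed = config$seed,
      package_version = as.character(utils::packageVersion("neurotube")),
      files = unlist(report$outputs, use.names = FALSE)),
      prov_path, auto_unbox = TRUE)
    unlink(tmp)
  }
  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    message("stage: ", name)
    res <- tryCatch(fun(), error = function(e) {
      write_prov(sprintf("failed at stage '%s': %s", name,
                         conditionMessage(e)))
      stop(sprintf("pipeline aborted in stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    report$stages_done <<- c(report$stages_done, name)
    res
  }

  report$cohort <- run_stage("cohort", function() {
    ch <- config$cohort
    coh <- gen_cohort(ch$n_per_group,
                      effects = list(beta_hindbrain_mean = ch$beta_hindbrain_mean,
                                     beta_spinalcord_mean = ch$beta_spinalcord_mean,
                                     sd = ch$sd),
                      seed = config$seed,
                      gt_base = ground_truth(noise_sd = ch$noise_sd))
    fits <- lapply(coh$records, function(emb) {
      lapply(emb, function(rec) {
        rf <- fit_force_ramp(rec)
        fit_creep_powerlaw(rec, rf)
      })
    })
    beta_hat <- data.frame(
      embryo = rep(seq_along(fits), each = 2L),
      region = rep(c("hindbrain", "spinal_cord"), length(fits)),
      beta_hat = unlist(lapply(fits, function(e)
        c(e$hindbrain$beta, e$spinal_cord$beta))))
    stats <- paired_group_compare(
      beta_hat$beta_hat[beta_hat$region == "hindbrain"],
      beta_hat$beta_hat[beta_hat$region == "spinal_cord"], paired = TRUE)
    f1 <- file.path(config$out_dir, "cohort_beta_fits.csv")
    write.csv(merge(beta_hat, coh$beta_true), f1, row.names = FALSE)
    f2 <- file.path(config$out_dir, "cohort_stats.json")
    write_fit_json(stats, f2)
    report$outputs$cohort <<- c(f1, f2)
    list(fits = beta_hat, stats = stats)
  })

  report$tube <- run_stage("tube", function() {
    tb <- config$tube
    sched <- pressure_schedule_preset(tb$schedule,
                                      duration_h = tb$duration_h)
    mat <- material_params()
    trajs <- lapply(c("hindbrain", "spinal_cord"), function(rg) {
      simulate_tube(tube_preset(rg, n_segments = tb$n_segments), mat,
                    sched, tb$duration_h)
    })
    names(trajs) <- c("hindbrain", "spinal_cord")
    long <- do.call(rbind, lapply(names(trajs), function(rg) {
      cbind(region = rg, trajs[[rg]]$series)
    }))
    f <- file.path(config$out_dir, "tube_trajectories.csv")
    write.csv(long, f, row.names = FALSE)
    report$outputs$tube <<- f
    trajs
  })

  report$droplet <- run_stage("droplet", function() {
    dp <- config$droplet
    vols <- nt_defaults()$droplet$volume_nl
    res <- lapply(c("hindbrain", "spinal_cord"), function(rg) {
      st <- tube_preset(rg, stage = "droplet_site")
      gt <- ground_truth(noise_sd = dp$noise_sd, seed = config$seed)
      ser <- gen_droplet_series(gt, st,
                                droplet = list(volume_nl = vols[[rg]],
                                               gamma_N_m = dp$gamma_N_m),
                                duration_h = dp$duration_h,
                                n_frames = dp$n_frames)
      est <- estimate_viscosity_from_droplet(
        ser, st, material_params(),
        droplet = list(volume_nl = vols[[rg]], gamma_N_m = dp$gamma_N_m),
        n_boot = dp$n_boot)
      list(series = ser, estimate = est)
    })
    names(res) <- c("hindbrain", "spinal_cord")
    f <- file.path(config$out_dir, "droplet_estimates.json")
    write_fit_json(lapply(res, function(x) x$estimate), f)
    report$outputs$droplet <<- f
    res
  })

  report$shape <- run_stage("shape", function() {
    sh <- config$shape
    mk <- function(rg, i) {
      thin <- if (rg == "hindbrain") c(8, 40) else c(30, 40)
      gen_cross_section(list(kind = "dorsally_thinned", R_inner = 60,
                             thickness_dorsal = thin[1L],
                             thickness_ventral = thin[2L],
                             n_points = 240L),
                        metadata = list(embryo_id = i, region = rg))
    }
    metrics <- do.call(rbind, lapply(c("hindbrain", "spinal_cord"),
                                     function(rg) {
      do.call(rbind, lapply(seq_len(sh$n_sections), function(i) {
        pr <- thickness_profile(mk(rg, i), n_samples = sh$n_samples)
        rm <- roof_metrics(pr, window = sh$window_um)
        data.frame(region = rg, embryo = i,
                   mean_roof_thickness = rm$mean_roof_thickness,
                   roof_length = rm$roof_length)
      }))
    }))
    stats <- two_group_test(
      metrics$mean_roof_thickness[metrics$region == "hindbrain"],
      metrics$mean_roof_thickness[metrics$region == "spinal_cord"])
    f1 <- file.path(config$out_dir, "shape_metrics.csv")
    write.csv(metrics, f1, row.names = FALSE)
    f2 <- file.path(config$out_dir, "shape_stats.json")
    write_fit_json(stats, f2)
    report$outputs$shape <<- c(f1, f2)
    list(metrics = metrics, stats = stats)
  })

  write_prov("complete")
  report$outputs$provenance <- prov_path
  invisible(report)
}
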