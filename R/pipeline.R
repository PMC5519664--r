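#' Run the full analysis pipeline from a JSON config
#'
#' Executes the requested stages in fixed order -- phantom, degrade,
#' segment, wss, el, flowrate, compare -- and writes every output plus a
#' run manifest (package version, R version, full config, seed, file list)
#' into the output directory, so any result file can be traced back to the
#' exact config and seed that produced it.
#'
#' Config keys (all stages optional except an input): `seed`,
#' `output_dir`; `input` (path of a velocity volume) or `phantom` (a
#' [phantom_spec()] as a named list); `degrade`
#' ([degradation_spec()] fields); `segment` (`frame`, `threshold`,
#' `seed_voxel`, `connectivity`, `boundary_threshold`,
#' `smooth_iterations`, `smooth_lambda`, optional `edits_file` CSV with
#' columns i,j,k,value); `wss` (`depth_m` optional); `el` (`closure`,
#' optional `mu`, `rho`, `k_file`, `epsilon_file`); `flowrate` (`plane`
#' with `origin`/`normal`); `compare` (`planes`, compares the degraded
#' field against the clean phantom field).
#'
#' @param config path to a JSON config file, or an equivalent named list.
#' @param output_dir overrides the config's `output_dir`.
#' @return Invisibly, the manifest as a named list. Errors carry the name
#'   of the failing stage.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    config
  }
  missing_keys <- character(0)
  if (is.null(cfg$phantom) && is.null(cfg$input))
    missing_keys <- c(missing_keys, "phantom or input")
  out_dir <- output_dir %||% cfg$output_dir
  if (is.null(out_dir)) missing_keys <- c(missing_keys, "output_dir")
  if (!is.null(cfg$segment)) {
    for (k in c("threshold", "seed_voxel"))
      if (is.null(cfg$segment[[k]]))
        missing_keys <- c(missing_keys, paste0("segment.", k))
  }
  if (!is.null(cfg$flowrate) && is.null(cfg$flowrate$plane))
    missing_keys <- c(missing_keys, "flowrate.plane")
  if (!is.null(cfg$el) && identical(cfg$el$closure, "rng_k_epsilon") &&
      (is.null(cfg$el$k_file) || is.null(cfg$el$epsilon_file)))
    missing_keys <- c(missing_keys, "el.k_file", "el.epsilon_file")
  if (length(missing_keys) > 0)
    stop_flow4d(paste0("config is missing required keys: ",
                       paste(unique(missing_keys), collapse = ", ")),
                "flow4d_validation_error")
  seed <- as.integer(cfg$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop_flow4d(sprintf("pipeline stage '%s' failed: %s", name,
                          conditionMessage(e)), "flow4d_stage_error")
    })
  }
  props <- fluid_properties(mu = cfg$mu %||% 0.004, rho = cfg$rho %||% 1060)

  phantom <- NULL
  if (!is.null(cfg$phantom)) {
    field <- stage("phantom", {
      pc <- cfg$phantom
      spec <- phantom_spec(kind = pc$kind %||% "poiseuille",
                           radius = pc$radius,
                           length = pc$length %||% 100,
                           flow_rate_lpm = pc$flow_rate_lpm %||% 5,
                           spacing = pc$spacing %||% c(0.885, 0.885, 1),
                           alpha = pc$alpha %||% 13,
                           frames = pc$frames %||% 16L,
                           flow_split = pc$flow_split,
                           seed = seed)
      phantom <- gen_phantom(spec, props)
      p <- file.path(out_dir, "phantom_velocity.nii")
      write_velocity_volume(phantom$field, p)
      write_scalar_volume(phantom$mask, file.path(out_dir, "phantom_mask.nii"))
      jsonlite::write_json(phantom$truth, file.path(out_dir, "phantom_truth.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      outputs <- c(outputs, p, file.path(out_dir, "phantom_mask.nii"),
                    file.path(out_dir, "phantom_truth.json"))
      phantom$field
    })
  } else {
    field <- stage("input", read_velocity_volume(cfg$input))
  }

  if (!is.null(cfg$degrade)) {
    field <- stage("degrade", {
      dspec <- degradation_spec(
        target_spacing = cfg$degrade$target_spacing %||% c(1.25, 1.25, 2),
        noise_sd = cfg$degrade$noise_sd %||% 0,
        venc = cfg$degrade$venc %||% Inf,
        seed = seed)
      dg <- degrade_pcmri(field, if (!is.null(phantom)) phantom$mask else NULL,
                          dspec)
      p <- file.path(out_dir, "degraded_velocity.nii")
      write_velocity_volume(dg, p)
      outputs <- c(outputs, p)
      dg
    })
  }

  mask <- NULL
  mesh <- NULL
  if (!is.null(cfg$segment)) {
    sc <- cfg$segment
    frame <- as.integer(sc$frame %||% 1L)
    stage("segment", {
      sp <- speed_volume(field, frame)
      m <- threshold_segment(sp, sc$threshold)
      m <- region_grow(m, as.integer(unlist(sc$seed_voxel)),
                       connectivity = as.integer(sc$connectivity %||% 26L))
      if (!is.null(sc$boundary_threshold) && sc$boundary_threshold > 0)
        m <- refine_boundary(m, sp, sc$boundary_threshold)
      if (!is.null(sc$edits_file)) {
        ed <- utils::read.csv(sc$edits_file)
        m <- edit_mask(m, ed)
      }
      mask <- m
      mesh <- smooth_laplacian(extract_surface(m),
                                iterations = as.integer(sc$smooth_iterations %||% 10L),
                                lambda = sc$smooth_lambda %||% 0.5)
      pm <- file.path(out_dir, "lumen_mask.nii")
      ps <- file.path(out_dir, "lumen_surface.stl")
      write_scalar_volume(m, pm)
      write_mesh(mesh, ps)
      outputs <- c(outputs, pm, ps)
    })
  } else if (!is.null(phantom)) {
    mask <- phantom$mask
  }

  if (!is.null(cfg$wss)) {
    stage("wss", {
      if (is.null(mesh)) mesh <- extract_surface(mask)
      w <- compute_wss(mesh, field, frame = as.integer(cfg$wss$frame %||% 1L),
                       props = props, depth = cfg$wss$depth_m)
      p <- file.path(out_dir, "wss.vtp")
      write_mesh(mesh, p, cell_data = list(
        wss_magnitude_Pa = ifelse(w$valid, w$wss_magnitude, NA_real_)))
      js <- file.path(out_dir, "wss_summary.json")
      jsonlite::write_json(list(area_averaged_wss_Pa = mean_wss(w),
                                valid_faces = sum(w$valid),
                                total_faces = length(w$valid),
                                depth_m = w$depth),
                           js, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, p, js)
    })
  }

  if (!is.null(cfg$el)) {
    stage("el", {
      closure <- cfg$el$closure %||% "laminar"
      model <- closure_model(closure)
      mu_t <- NULL
      if (closure == "rng_k_epsilon") {
        kvol <- read_scalar_volume(cfg$el$k_file, unit = "m^2/s^2")
        evol <- read_scalar_volume(cfg$el$epsilon_file, unit = "m^2/s^3")
        mu_t <- eddy_viscosity_rng(kvol, evol, props, model)
      }
      el <- compute_el(field, frame = as.integer(cfg$el$frame %||% 1L),
                       mask = mask, props = props, model = model, mu_t = mu_t)
      p <- file.path(out_dir, "energy_loss.json")
      write_report(el, p)
      outputs <- c(outputs, p)
    })
  }

  if (!is.null(cfg$flowrate)) {
    stage("flowrate", {
      pl <- cfg$flowrate$plane
      q <- flow_rate(field, frame = as.integer(cfg$flowrate$frame %||% 1L),
                     mask = mask,
                     plane = list(origin = as.numeric(unlist(pl$origin)),
                                  normal = as.numeric(unlist(pl$normal))),
                     props = props)
      p <- file.path(out_dir, "flow_rate.json")
      jsonlite::write_json(list(volume_flow_m3_per_s = q$volume_flow,
                                mass_flow_kg_per_s = q$mass_flow,
                                n_samples = q$n_samples, area_m2 = q$area),
                           p, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, p)
    })
  }

  if (!is.null(cfg$compare)) {
    stage("compare", {
      if (is.null(phantom))
        stop("compare stage needs a phantom reference")
      ref <- resample_to_grid(phantom$field, field$geometry, mask)
      pls <- cfg$compare$planes
      part <- partition_regions(mask,
        plane1 = list(origin = as.numeric(unlist(pls[[1]]$origin)),
                      normal = as.numeric(unlist(pls[[1]]$normal))),
        plane2 = list(origin = as.numeric(unlist(pls[[2]]$origin)),
                      normal = as.numeric(unlist(pls[[2]]$normal))))
      rep <- compare_fields(field, ref, part)
      pc <- file.path(out_dir, "comparison.csv")
      pj <- file.path(out_dir, "comparison.json")
      write_report(rep, pc)
      write_report(rep, pj)
      outputs <- c(outputs, pc, pj)
    })
  }

  manifest <- list(package = "flow4d",
                   version = as.character(utils::packageVersion("flow4d")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = seed,
                   config = cfg,
                   outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline from a config), `phantom`, `degrade`,
#' `segment`, `wss`, `el`, `flowrate`, `compare` -- each a thin wrapper
#' that builds a one-stage config. Invoke via the installed `exec/flow4d`
#' script or `Rscript -e 'flow4d::flow4d_main()' ...`.
#'
#' @param args character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status, invisibly (0 on success).
#' @export
flow4d_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: flow4d <command> --config <file.json> [--out <dir>] [--seed <int>]",
    "commands: run phantom degrade segment wss el flowrate compare",
    sep = "\n")
  if (length(args) < 1L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) {
      message("missing value for --", key)
      return(invisible(1L))
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  if (is.null(opts$config)) {
    message(usage)
    return(invisible(1L))
  }
  status <- tryCatch({
    cfg <- jsonlite::read_json(opts$config, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (cmd != "run") {
      keep <- c("seed", "output_dir", "input", "phantom", "mu", "rho",
                switch(cmd, phantom = NULL, degrade = "degrade",
                       segment = "segment", wss = c("segment", "wss"),
                       el = c("segment", "el"),
                       flowrate = c("segment", "flowrate"),
                       compare = c("degrade", "segment", "compare"),
                       stop_flow4d(paste("unknown command", cmd),
                                   "flow4d_parameter_error")))
      cfg <- cfg[intersect(names(cfg), keep)]
    }
    run_pipeline(cfg, output_dir = opts$out)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
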