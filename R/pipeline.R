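# Pipeline configuration and orchestration ------------------------------------

PIPELINE_STAGES <- c("synthetic", "gait", "shape", "fe", "remodel")

#' Validate a pipeline configuration
#'
#' Configurations are plain lists (typically from a YAML file) with fields:
#' `archetype` ("NF"/"HB"/"FB"), `seed`, `out_dir`, `stages` (subset of
#' synthetic, gait, shape, fe, remodel, in order), and optional per-stage
#' parameter blocks `gait:`, `fe:`, `remodel:`, `synthetic:`. Unknown keys
#' are rejected.
#'
#' @param config list or path to a YAML file.
#' @return the validated config (with defaults filled in).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_validation("config must be a list or YAML path")
  allowed <- c("archetype", "seed", "out_dir", "stages",
               "synthetic", "gait", "fe", "remodel", "shape")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop_validation("unknown config key(s): ", paste(unknown, collapse = ", "))
  config$archetype <- match.arg(config$archetype %||% "NF",
                                c("NF", "HB", "FB"))
  config$seed <- as.integer(config$seed %||% 0L)
  config$out_dir <- config$out_dir %||% tempfile("footform_run_")
  config$stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad))
    stop_validation("unknown stage(s): ", paste(bad, collapse = ", "))
  config$stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% config$stages]
  syn <- config$synthetic %||% list()
  syn$n_frames <- syn$n_frames %||% 51L
  syn$target_edge <- syn$target_edge %||% 9
  config$synthetic <- syn
  gt <- config$gait %||% list()
  gt$n_trials <- gt$n_trials %||% 3L
  gt$alpha <- gt$alpha %||% 0.05
  config$gait <- gt
  rm_ <- config$remodel %||% list()
  rm_$n_days <- rm_$n_days %||% 60
  rm_$rho0 <- rm_$rho0 %||% 0.8
  rm_$resolve_every <- rm_$resolve_every %||% 1L
  config$remodel <- rm_
  config
}

#' Run the full synthetic-foot analysis pipeline
#'
#' Executes the requested stages in order for one archetype: synthetic data
#' generation (bones, FE mesh, pressure trials), gait analytics (regional
#' stats, GRF, normalised CoP), shape comparison against the NF reference
#' (correspondence, error maps, Hausdorff, SSM), the quasi-static FE solve
#' under mean stance pressures, and the remodelling simulation. Writes STL,
#' .inp, CSV and VTK artefacts plus a machine-readable `summary.json` and a
#' `run.log` with the package version, seed and config hash into `out_dir`.
#' Deterministic stages reproduce bitwise for a fixed config and seed.
#'
#' @param config list or YAML path accepted by [pipeline_config()].
#' @return (invisibly) the output directory; the parsed summary is attached
#'   as attribute `"summary"`.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log <- c(sprintf("footform %s", as.character(utils::packageVersion("footform"))),
           sprintf("seed: %d", cfg$seed),
           sprintf("archetype: %s", cfg$archetype),
           sprintf("config hash: %s", config_hash(cfg)),
           sprintf("stages: %s", paste(cfg$stages, collapse = ", ")))
  summary <- list(archetype = cfg$archetype, seed = cfg$seed)
  params <- default_archetype(cfg$archetype, seed = cfg$seed)
  bones <- NULL; mesh <- NULL; series <- NULL; stats <- NULL; lc <- NULL
  stage_time <- function(nm, expr) {
    st <- Sys.time()
    r <- force(expr)  # expr evaluates in the run_pipeline frame
    log <<- c(log, sprintf("stage %s: %.2f s", nm,
                           as.numeric(difftime(Sys.time(), st,
                                               units = "secs"))))
    r
  }
  for (stage in cfg$stages) {
    if (stage == "synthetic") {
      stage_time("synthetic", {
        bones <- generate_foot_bones(params)
        for (nm in names(bones$meshes))
          write_stl(bones$meshes[[nm]],
                    file.path(cfg$out_dir, paste0(nm, ".stl")))
        mesh <- generate_foot_model(bones,
                                     target_edge = cfg$synthetic$target_edge)
        write_inp(mesh, file.path(cfg$out_dir, "foot_model.inp"))
        series <- generate_pressure_series(params,
                                            n_frames = cfg$synthetic$n_frames)
        write_pressure_csv(series, file.path(cfg$out_dir, "pressure.csv"))
        summary$synthetic <- list(
          n_bones = length(bones$meshes),
          bbox_length_mm = diff(range(do.call(rbind,
            lapply(bones$meshes, `[[`, "vertices"))[, 2])),
          n_tets = nrow(mesh$tets), n_nodes = nrow(mesh$nodes),
          min_scaled_jacobian = min(scaled_jacobian(mesh)))
      })
    } else if (stage == "gait") {
      stage_time("gait", {
        if (is.null(series)) series <- generate_pressure_series(params)
        rmap <- region_map(dim(series$frames)[2:3], cfg$archetype)
        stats <- regional_stats(series, rmap)
        write.csv(stats, file.path(cfg$out_dir, "regional_stats.csv"),
                  row.names = FALSE)
        traj <- cop_trajectory(series)
        ncop <- normalize_cop(traj, params$foot_length, params$foot_width)
        write.csv(ncop, file.path(cfg$out_dir, "cop_trajectory.csv"),
                  row.names = FALSE)
        grf <- compute_grf(series)
        summary$gait <- list(
          peak_grf_n = max(grf),
          peak_grf_bw = max(grf) / (params$body_mass * 9.81),
          cop_ml_range_pct = diff(range(ncop$x_pct)),
          cop_ap_range_pct = diff(range(ncop$y_pct)),
          regional = setNames(as.list(stats$mean_kpa), stats$region))
      })
    } else if (stage == "shape") {
      stage_time("shape", {
        if (is.null(bones)) bones <- generate_foot_bones(params)
        ref <- generate_foot_bones(default_archetype("NF", seed = cfg$seed))
        shp <- list()
        for (bn in c("calcaneus", "talus", "metatarsal_1")) {
          fit <- icp_align(bones$meshes[[bn]], ref$meshes[[bn]])
          cor <- correspond(ref$meshes[[bn]], fit$aligned)
          em <- error_map(ref$meshes[[bn]], cor)
          hd <- hausdorff(fit$aligned, ref$meshes[[bn]])
          write_error_map_csv(em, file.path(cfg$out_dir,
                                            paste0("errormap_", bn, ".csv")))
          write_ply(ref$meshes[[bn]],
                    file.path(cfg$out_dir, paste0("errormap_", bn, ".ply")),
                    scalar = em)
          shp[[bn]] <- list(icp_rms_mm = fit$rms,
                            hausdorff_mm = hd$hausdorff,
                            mean_signed_mm = mean(em),
                            dist_mean_mm = hd$gaussian_mean,
                            dist_sd_mm = hd$gaussian_sd)
        }
        summary$shape <- shp
      })
    } else if (stage == "fe") {
      stage_time("fe", {
        if (is.null(mesh)) mesh <- generate_foot_model(params,
          target_edge = cfg$synthetic$target_edge)
        if (is.null(stats)) {
          if (is.null(series)) series <- generate_pressure_series(params)
          rmap <- region_map(dim(series$frames)[2:3], cfg$archetype)
          stats <- regional_stats(series, rmap)
        }
        mp <- setNames(stats$mean_kpa, stats$region)
        bw <- params$body_mass * 9.81
        lc <- foot_load_case(mesh, mp, bw)
        asm <- assemble_stiffness(mesh, default_materials())
        K <- add_connectors(asm$K, mesh, lc$connector_pairs, lc$connector_k)
        sol <- fe_solve(K, lc$f, lc$fixed_nodes, mesh, asm$cache,
                        asm$E, asm$nu)
        en <- strain_energy(sol, asm$cache)
        bone_sets <- grep("^bone_", names(mesh$element_sets), value = TRUE)
        peaks <- lapply(bone_sets, function(bs)
          max(sol$von_mises[mesh$element_sets[[bs]]]))
        names(peaks) <- sub("^bone_", "", bone_sets)
        write_vtk(mesh, file.path(cfg$out_dir, "fe_solution.vtk"),
                  cell_data = list(von_mises = sol$von_mises),
                  point_data = list(displacement = sol$displacements))
        summary$fe <- list(peak_von_mises_mpa = peaks,
                            residual = sol$residual,
                            rearfoot_energy_share =
                              rearfoot_energy_share(mesh, en))
      })
    } else if (stage == "remodel") {
      stage_time("remodel", {
        if (is.null(lc)) stop_input("remodel stage requires the fe stage")
        pr <- remodel_params(n_days = cfg$remodel$n_days)
        hist <- run_remodelling(mesh, lc, cfg$remodel$rho0, pr,
                                resolve_every = cfg$remodel$resolve_every)
        rho_fin <- tail(hist$density, 1)[1, ]
        write_vtk(mesh, file.path(cfg$out_dir, "remodel_density.vtk"),
                  cell_data = list(density = {
                    d <- rep(NA_real_, nrow(mesh$tets))
                    d[hist$bone_elements] <- rho_fin
                    d[is.na(d)] <- 0
                    d
                  }))
        regs <- calcaneal_regions(mesh)
        gain <- rho_fin - hist$density[1, ]
        reg_gain <- lapply(regs, function(ids) {
          sel <- match(ids, hist$bone_elements)
          sel <- sel[!is.na(sel)]
          if (length(sel)) mean(gain[sel]) else NA_real_
        })
        summary$remodel <- list(
          converged = hist$converged,
          bone_mass_initial_g = hist$mass_g[1],
          bone_mass_final_g = tail(hist$mass_g, 1),
          mean_density_gain = mean(gain),
          region_density_gain = reg_gain)
      })
    }
  }
  log <- c(log, sprintf("total: %.2f s",
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log, file.path(cfg$out_dir, "run.log"))
  out <- cfg$out_dir
  attr(out, "summary") <- summary
  invisible(out)
}

# share of total strain energy carried by rearfoot elements (posterior 31%
# of foot length, bone and soft alike)
rearfoot_energy_share <- function(mesh, energy) {
  L <- mesh$provenance$foot_length
  yc <- (mesh$nodes[mesh$tets[, 1], 2] + mesh$nodes[mesh$tets[, 2], 2] +
         mesh$nodes[mesh$tets[, 3], 2] + mesh$nodes[mesh$tets[, 4], 2]) / 4
  rear <- yc < BAND_REAR * L
  sum(energy[rear]) / sum(energy)
}

#' Anatomical element regions of the calcaneus
#'
#' Element regions used in remodelling reports: `achilles_insertion` (patch
#' around the Achilles node set), `talar_articulation` (patch around the
#' talus-calcaneus interface), `inferior` (heel-pad side), `shell` (elements
#' owning a boundary face) and `core` (the rest).
#'
#' @param mesh a `tet_mesh` from [generate_foot_model()].
#' @param radius patch radius (mm); defaults to 1.6 lattice edges.
#' @return named list of element id vectors (calcaneal elements).
#' @export
calcaneal_regions <- function(mesh, radius = NULL) {
  cal <- mesh$element_sets$bone_calcaneus %||% integer(0)
  if (!length(cal)) return(list())
  if (is.null(radius))
    radius <- 1.6 * (mesh$provenance$target_edge %||% 9)
  cen <- (mesh$nodes[mesh$tets[cal, 1], , drop = FALSE] +
          mesh$nodes[mesh$tets[cal, 2], , drop = FALSE] +
          mesh$nodes[mesh$tets[cal, 3], , drop = FALSE] +
          mesh$nodes[mesh$tets[cal, 4], , drop = FALSE]) / 4
  cc <- colMeans(cen)
  bf <- boundary_faces(mesh)
  shell_all <- unique(bf[, "element"])
  near <- function(pt) cal[row_norms(sweep(cen, 2, pt)) <= radius]
  ach_pt <- colMeans(mesh$nodes[mesh$node_sets$achilles, , drop = FALSE])
  tal_nodes <- unique(as.vector(
    mesh$tets[mesh$element_sets$bone_talus %||% integer(0), ]))
  cal_nodes <- unique(as.vector(mesh$tets[cal, ]))
  iface <- intersect(tal_nodes, cal_nodes)
  tal_pt <- if (length(iface))
    colMeans(mesh$nodes[iface, , drop = FALSE])
  else cc + c(0, 0, radius)
  achilles <- near(ach_pt)
  talar <- setdiff(near(tal_pt), achilles)
  rest <- setdiff(cal, c(achilles, talar))
  inferior <- rest[cen[match(rest, cal), 3] <= cc[3]]
  # shell/core describe the remaining calcaneus away from the two patches
  list(achilles_insertion = achilles,
       talar_articulation = talar,
       inferior = inferior,
       shell = intersect(rest, shell_all),
       core = setdiff(rest, shell_all))
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[sort(names(cfg))]), collapse = "")
  # small stable FNV-1a hash; provenance only
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
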