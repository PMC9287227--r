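# Orchestration of the tonometry parameter sweeps: build the eye model once,
# sweep probe x IOP x depth, tabulate forces and field summaries, fit the
# linear force relations, and write all outputs.

#' Sweep configuration
#'
#' Defaults reproduce the study grid: plunging depths 0.3-0.7 mm in steps of
#' 0.1 mm, IOP 10/15/20 mmHg, the standard 1.7 mm probe, reference mesh
#' resolution.
#'
#' @param depths depth grid in mm (strictly increasing, > 0)
#' @param iops IOP grid in mmHg (strictly increasing)
#' @param probes list of [probe_spec()] objects
#' @param geometry an [ocular_geometry_params()]
#' @param materials region-to-material map, see [eye_materials()]
#' @param mesh_preset "coarse", "reference" or "fine" (see [mesh_preset()]), or a
#'   list with n_azimuth/n_meridian/n_thickness
#' @param constraint_mode see [apply_remote_displacement_zero()]
#' @param n_increments displacement increments per solve
#' @param formulation element formulation
#' @param stress_stiffening linearize the probe phase about the pressurized
#'   state (default TRUE)
#' @param outdir optional output directory for [write_outputs()]
#' @return an object of class `sweep_config`
#' @export
sweep_config <- function(depths = seq(0.3, 0.7, by = 0.1),
                         iops = c(10, 15, 20),
                         probes = list(probe_spec()),
                         geometry = ocular_geometry_params(),
                         materials = eye_materials(),
                         mesh_preset = "reference",
                         constraint_mode = "remote-rigid-body",
                         n_increments = 10,
                         formulation = "incompatible",
                         stress_stiffening = TRUE,
                         outdir = NULL) {
  if (!length(depths) || any(diff(depths) <= 0) || any(depths <= 0))
    stop("depths must be a nonempty strictly increasing grid of positive values")
  if (!length(iops) || any(diff(iops) <= 0) || any(iops < 0))
    stop("iops must be a nonempty strictly increasing grid")
  if (inherits(probes, "probe_spec")) probes <- list(probes)
  stopifnot(all(vapply(probes, inherits, TRUE, "probe_spec")))
  if (is.character(mesh_preset)) mesh_preset <- mesh_preset(mesh_preset)
  cfg <- list(depths = depths, iops = iops, probes = probes,
              geometry = geometry, materials = materials,
              mesh = mesh_preset, constraint_mode = constraint_mode,
              n_increments = as.integer(n_increments),
              formulation = formulation,
              stress_stiffening = isTRUE(stress_stiffening),
              outdir = outdir)
  class(cfg) <- "sweep_config"
  cfg
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf("<sweep_config> %d depths x %d IOPs x %d probe(s) = %d grid points\n",
              length(x$depths), length(x$iops), length(x$probes),
              length(x$depths) * length(x$iops) * length(x$probes)))
  invisible(x)
}

#' Build the eye model (shell, mesh, assembled system)
#'
#' Convenience constructor shared by the sweep pipeline, the acceptance
#' script and the CLI: lofts the four meridian profiles, sweeps the mesh at
#' the requested resolution and returns the pieces plus a cache environment
#' reused across solves.
#'
#' @param geometry an [ocular_geometry_params()]
#' @param materials region-to-material map
#' @param resolution a [mesh_preset()] name or list
#' @return list with `shell`, `mesh`, `materials`, `cache`
#' @export
build_eye_model <- function(geometry = ocular_geometry_params(),
                            materials = eye_materials(),
                            resolution = "reference") {
  if (is.character(resolution)) resolution <- mesh_preset(resolution)
  profiles <- lapply(QUADRANTS, function(q)
    build_meridian_profile(geometry, q))
  shell <- loft_eye_surface(profiles)
  mesh <- sweep_shell_mesh(shell, resolution$n_azimuth,
                           resolution$n_meridian, resolution$n_thickness)
  list(shell = shell, mesh = mesh, materials = materials,
       geometry = geometry, cache = new.env(parent = emptyenv()))
}

#' Run the force-depth-IOP sweep
#'
#' Solves every grid point of the configuration independently (sharing the
#' assembled stiffness, constraint factorization and probe flexibility
#' across points) and tabulates force, maximum total deformation and
#' maximum von Mises stress per point. A non-converged point is recorded
#' with `converged = FALSE` and the sweep continues. The pipeline contains
#' no randomness: identical configurations give identical tables.
#'
#' @param config a [sweep_config()]
#' @param model optionally a prebuilt [build_eye_model()] (must match the
#'   configuration's geometry/materials)
#' @param keep_fields return the full `solve_result` per grid point in
#'   attribute "fields" (memory-heavy; default FALSE)
#' @return a data.frame of class `sweep_table` with one row per grid point:
#'   probe_diameter_mm, iop_mmhg, depth_mm, force_n,
#'   max_total_deformation_mm, max_von_mises_mpa, max_stress_region,
#'   converged
#' @export
run_sweep <- function(config, model = NULL, keep_fields = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  if (is.null(model))
    model <- build_eye_model(config$geometry, config$materials, config$mesh)
  rows <- list()
  fields <- list()
  for (probe in config$probes) {
    for (iop in config$iops) {
      for (depth in config$depths) {
        lc <- load_case(iop = iop, probe = probe, target_depth = depth,
                        n_increments = config$n_increments,
                        constraint_mode = config$constraint_mode)
        res <- tryCatch(
          solve_indentation(model$mesh, model$materials, lc,
                            formulation = config$formulation,
                            stress_stiffening = config$stress_stiffening,
                            model = model$cache),
          error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            probe_diameter_mm = probe$diameter, iop_mmhg = iop,
            depth_mm = depth, force_n = NA_real_,
            max_total_deformation_mm = NA_real_,
            max_von_mises_mpa = NA_real_,
            max_stress_region = NA_character_, converged = FALSE,
            stringsAsFactors = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          probe_diameter_mm = probe$diameter, iop_mmhg = iop,
          depth_mm = depth, force_n = res$reaction_force,
          max_total_deformation_mm = res$max_total_deformation,
          max_von_mises_mpa = res$max_von_mises,
          max_stress_region = res$max_stress_region,
          converged = res$converged, stringsAsFactors = FALSE)
        if (keep_fields)
          fields[[sprintf("probe%g_iop%g_depth%g", probe$diameter, iop,
                          depth)]] <- res
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$probe_diameter_mm, tab$iop_mmhg, tab$depth_mm), ]
  rownames(tab) <- NULL
  class(tab) <- c("sweep_table", "data.frame")
  attr(tab, "config") <- config
  if (keep_fields) attr(tab, "fields") <- fields
  tab
}

#' Fit the linear force relations of a sweep table
#'
#' Per IOP level (and probe), an ordinary least-squares line
#' force = alpha + beta * depth; the IOP sensitivity dF/dIOP is computed by
#' finite differences across the IOP grid at each depth and averaged over
#' the depth grid, and reported per 5 mmHg.
#'
#' @param table a `sweep_table` (>= 2 depths and >= 2 IOPs)
#' @return an object of class `force_relations`: `per_iop` (data.frame with
#'   probe_diameter_mm, iop_mmhg, intercept_n, slope_n_per_mm, r_squared)
#'   and `iop_sensitivity` (probe_diameter_mm, dforce_diop_n_per_mmhg,
#'   slope_n_per_5mmhg)
#' @export
fit_force_relations <- function(table) {
  stopifnot(inherits(table, "data.frame"))
  tab <- table[table$converged & !is.na(table$force_n), ]
  if (length(unique(tab$depth_mm)) < 2L || length(unique(tab$iop_mmhg)) < 2L)
    stop("force relations need at least 2 depths and 2 IOP levels")
  per <- list(); sens <- list()
  for (pd in unique(tab$probe_diameter_mm)) {
    sub <- tab[tab$probe_diameter_mm == pd, ]
    for (iop in unique(sub$iop_mmhg)) {
      s2 <- sub[sub$iop_mmhg == iop, ]
      fit <- stats::lm(force_n ~ depth_mm, data = s2)
      ss_tot <- sum((s2$force_n - mean(s2$force_n))^2)
      r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
      per[[length(per) + 1L]] <- data.frame(
        probe_diameter_mm = pd, iop_mmhg = iop,
        intercept_n = unname(stats::coef(fit)[1]),
        slope_n_per_mm = unname(stats::coef(fit)[2]),
        r_squared = r2)
    }
    # finite-difference IOP sensitivity averaged over the depth grid
    dd <- numeric(0)
    for (depth in unique(sub$depth_mm)) {
      s3 <- sub[sub$depth_mm == depth, ]
      s3 <- s3[order(s3$iop_mmhg), ]
      if (nrow(s3) >= 2L)
        dd <- c(dd, diff(s3$force_n) / diff(s3$iop_mmhg))
    }
    sens[[length(sens) + 1L]] <- data.frame(
      probe_diameter_mm = pd,
      dforce_diop_n_per_mmhg = mean(dd),
      slope_n_per_5mmhg = 5 * mean(dd))
  }
  out <- list(per_iop = do.call(rbind, per),
              iop_sensitivity = do.call(rbind, sens))
  class(out) <- "force_relations"
  out
}

#' @export
print.force_relations <- function(x, ...) {
  cat("<force_relations>\n  per-IOP linear fits (force = a + b*depth):\n")
  print(x$per_iop, row.names = FALSE)
  cat("  IOP sensitivity:\n")
  print(x$iop_sensitivity, row.names = FALSE)
  invisible(x)
}

#' Summarize the fields of a converged indentation solve
#'
#' @param result a `solve_result`
#' @return list with the maximum total deformation (mm) and its node and
#'   location, and the maximum element von Mises stress (MPa) with its
#'   element and region tag
#' @export
summarize_fields <- function(result) {
  stopifnot(inherits(result, "solve_result"))
  list(max_total_deformation_mm = result$max_total_deformation,
       max_deformation_node = result$max_deformation_node,
       max_deformation_location = result$max_deformation_location,
       max_von_mises_mpa = result$max_von_mises,
       max_stress_element = result$max_stress_element,
       max_stress_region = result$max_stress_region)
}

#' Write sweep outputs to a directory
#'
#' Writes `sweep.csv` (the sweep table, with a commented header documenting
#' columns and units), `relations.json`, `metadata.json` (configuration,
#' package version, unit conventions), optional per-point VTU field files,
#' and `run.log`. Outputs are deterministic: an identical re-run reproduces
#' byte-identical CSV/JSON.
#'
#' @param table a `sweep_table`
#' @param relations a `force_relations` (or NULL)
#' @param fields named list of `solve_result` objects to export as VTU
#'   (or NULL)
#' @param outdir output directory (created if missing)
#' @return invisible character vector of the files written
#' @export
write_outputs <- function(table, relations = NULL, fields = NULL, outdir) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stop(sprintf("cannot create output directory '%s'", outdir))
  written <- character(0)

  csv <- file.path(outdir, "sweep.csv")
  con <- file(csv, "w")
  writeLines(c(
    "# tonometry sweep table (units: mm, mmHg, N, MPa)",
    "# probe_diameter_mm: probe diameter; iop_mmhg: intraocular pressure",
    "# depth_mm: plunging depth; force_n: applanation reaction force",
    "# max_total_deformation_mm: max |u| over nodes",
    "# max_von_mises_mpa: max element von Mises stress; max_stress_region: its region tag"),
    con)
  utils::write.table(as.data.frame(table), con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  close(con)
  written <- c(written, csv)

  if (!is.null(relations)) {
    rj <- file.path(outdir, "relations.json")
    jsonlite::write_json(list(per_iop = relations$per_iop,
                              iop_sensitivity = relations$iop_sensitivity),
                         rj, digits = NA, dataframe = "rows")
    written <- c(written, rj)
  }

  cfg <- attr(table, "config")
  meta <- list(
    package = "tonofem",
    version = as.character(utils::packageVersion("tonofem")),
    units = list(length = "mm", force = "N", stress = "MPa",
                 pressure_input = "mmHg",
                 mmhg_to_mpa = 1.333224e-4),
    config = if (!is.null(cfg)) list(
      depths = cfg$depths, iops = cfg$iops,
      probe_diameters = vapply(cfg$probes, function(p) p$diameter, 0),
      mesh = cfg$mesh, constraint_mode = cfg$constraint_mode,
      n_increments = cfg$n_increments, formulation = cfg$formulation,
      stress_stiffening = cfg$stress_stiffening) else NULL)
  mj <- file.path(outdir, "metadata.json")
  jsonlite::write_json(meta, mj, digits = NA, auto_unbox = TRUE)
  written <- c(written, mj)

  if (!is.null(fields))
    for (nm in names(fields)) {
      res <- fields[[nm]]
      vt <- file.path(outdir, paste0(nm, ".vtu"))
      write_vtu(res$mesh, vt,
                point_data = list(displacement = res$u,
                                  total_deformation = res$total_deformation,
                                  contact_status = res$contact_status),
                cell_data = list(von_mises = res$von_mises,
                                 region_id = as.integer(factor(res$mesh$region))))
      written <- c(written, vt)
    }

  log <- file.path(outdir, "run.log")
  nconv <- sum(table$converged)
  writeLines(c(sprintf("tonofem sweep: %d grid points, %d converged",
                       nrow(table), nconv),
               if (nconv < nrow(table))
                 paste("non-converged points:",
                       paste(which(!table$converged), collapse = ", "))
               else "all points converged",
               sprintf("force range: %.6g - %.6g N",
                       min(table$force_n, na.rm = TRUE),
                       max(table$force_n, na.rm = TRUE))),
             log)
  written <- c(written, log)
  invisible(written)
}

#' Read a sweep configuration from a YAML file
#'
#' Sections `geometry`, `materials`, `probe`, `sweep`, `solver`; every field
#' is optional and defaults to the study configuration. `probe$diameters`
#' is a vector of probe diameters in mm.
#'
#' @param path YAML file path
#' @return a [sweep_config()]
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  geo <- do.call(ocular_geometry_params, as.list(y$geometry %||% list()))
  mat <- if (!is.null(y$materials)) {
    mk <- function(d, fallback) if (is.null(d)) fallback
      else isotropic_material(d$young_modulus, d$poisson_ratio,
                              d$density %||% NA_real_)
    eye_materials(cornea = mk(y$materials$cornea, cornea_material()),
                  sclera = mk(y$materials$sclera, sclera_material()))
  } else eye_materials()
  probes <- if (!is.null(y$probe$diameters))
    lapply(y$probe$diameters, function(d) probe_spec(diameter = d))
  else list(probe_spec(diameter = y$probe$diameter %||% 1.7,
                       edge_fillet_radius = y$probe$edge_fillet_radius %||% 0))
  sw <- y$sweep %||% list()
  so <- y$solver %||% list()
  sweep_config(
    depths = sw$depths %||% seq(0.3, 0.7, by = 0.1),
    iops = sw$iops %||% c(10, 15, 20),
    probes = probes,
    geometry = geo, materials = mat,
    mesh_preset = so$mesh_preset %||% "reference",
    constraint_mode = so$constraint_mode %||% "remote-rigid-body",
    n_increments = so$n_increments %||% 10,
    formulation = so$formulation %||% "incompatible",
    stress_stiffening = so$stress_stiffening %||% TRUE,
    outdir = y$outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
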