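#' Read and write device-style velocity traces
#'
#' Traces are exchanged as delimited text: comment lines starting with `#`
#' (optionally carrying `# t_applanation: <ms>`), then two or three columns
#' `time` (ms), `velocity` (mm/ms) and optionally `displacement` (mm).
#'
#' @param path file path.
#' @return `read_velocity_trace()`: a [velocity_trace()];
#'   `write_velocity_trace()`: the path, invisibly.
#' @export
read_velocity_trace <- function(path) {
  header <- readLines(path, n = 20L)
  header <- header[startsWith(header, "#")]
  t_app <- NULL
  m <- grep("t_applanation:", header, value = TRUE)
  if (length(m))
    t_app <- as.numeric(sub(".*t_applanation:\\s*", "", m[1L]))
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (!all(c("time", "velocity") %in% names(df)))
    stop_wiop("trace file must have 'time' and 'velocity' columns")
  velocity_trace(df$time, df$velocity,
                 displacement = df$displacement,
                 provenance = "clinical-style",
                 t_applanation = t_app)
}

#' @rdname read_velocity_trace
#' @param trace a [velocity_trace()].
#' @export
write_velocity_trace <- function(trace, path) {
  stopifnot(inherits(trace, "velocity_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# apex velocity trace [time ms, velocity mm/ms]",
               if (!is.null(attr(trace, "t_applanation")))
                 sprintf("# t_applanation: %.6g", attr(trace, "t_applanation"))),
             con)
  utils::write.table(as.data.frame(trace), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a work ledger as delimited text
#'
#' @param ledger a [work_ledger()].
#' @param path file path.
#' @export
write_work_ledger <- function(ledger, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# work/energy ledger [time ms; works and energies mJ; pressure mmHg; apex mm]",
               sprintf("# scenario: %s; load_onset: %.6g ms; initial_work: %.6g mJ",
                       attr(ledger, "scenario"), attr(ledger, "load_onset"),
                       attr(ledger, "initial_work"))),
             con)
  utils::write.table(as.data.frame(ledger), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the eye geometry configuration as YAML
#'
#' @param path file path.
#' @return `read_eye_config()`: an [eye_geometry_config()].
#' @export
read_eye_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(eye_geometry_config))
  do.call(eye_geometry_config, vals[intersect(names(vals), known)])
}

#' @rdname read_eye_config
#' @param config an [eye_geometry_config()].
#' @export
write_eye_config <- function(config, path) {
  stopifnot(inherits(config, "eye_geometry_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a kinematic-events file
#'
#' Records the detected first-applanation time, maximum-velocity time and
#' their difference as a small delimited text file.
#'
#' @param comparison an [compare_with_applanation()] result (or a
#'   `wiop_estimate`).
#' @param path file path.
#' @export
write_events <- function(comparison, path) {
  stopifnot(inherits(comparison, c("applanation_comparison",
                                   "wiop_estimate")))
  t_app <- comparison$t_applanation
  t_mv <- comparison$t_maxvel
  df <- data.frame(t_applanation1 = t_app, t_maxvel = t_mv,
                   difference = t_mv - t_app)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# kinematic events [ms]", con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sweep/material design table
#'
#' Delimited text mirroring the sweep design columns (`C10`, `k1`, `k2`,
#' `IOP`, `CCT`, optionally `simulation`).
#'
#' @param path file path.
#' @return data frame suitable for [run_sweep()].
#' @export
read_material_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  need <- c("C10", "k1", "k2", "IOP", "CCT")
  if (!all(need %in% names(df)))
    stop_wiop("material table must have columns ",
              paste(need, collapse = ", "))
  df
}

#' Save and load a calibration as JSON
#'
#' @param fit a `calibration_fit`.
#' @param path file path.
#' @export
write_calibration <- function(fit, path) {
  stopifnot(inherits(fit, "calibration_fit"))
  pack <- function(q) list(coefficients = unname(q$coefficients),
                           r_squared = q$r_squared, n = q$n)
  obj <- list(work_to_iop = pack(fit$work_to_iop),
              time_to_work = pack(fit$time_to_work),
              quartic = unname(unclass(fit$quartic)),
              time_range = fit$time_range,
              source = fit$source)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::fromJSON(path)
  mk <- function(q, n) structure(
    list(coefficients = c(quadratic = q$coefficients[1L],
                          linear = q$coefficients[2L],
                          constant = q$coefficients[3L]),
         r_squared = q$r_squared, n = q$n),
    class = "quad_fit")
  structure(list(work_to_iop = mk(obj$work_to_iop),
                 time_to_work = mk(obj$time_to_work),
                 quartic = structure(stats::setNames(
                   obj$quartic, c("t4", "t3", "t2", "t1", "t0")),
                   class = "wiop_quartic"),
                 time_range = obj$time_range,
                 source = obj$source),
            class = "calibration_fit")
}

#' Export the revolved eye surface as a legacy VTK file
#'
#' Revolves the meridian into a quadrilateral surface mesh (ASCII legacy
#' VTK) for inspection in standard viewers.
#'
#' @param mesh an [build_eye_mesh()] mesh.
#' @param path file path.
#' @param coords optional current nodal coordinates (n x 2).
#' @param n_theta number of circumferential divisions.
#' @export
write_vtk_mesh <- function(mesh, path, coords = NULL, n_theta = mesh$n_theta) {
  stopifnot(inherits(mesh, "eye_mesh"))
  if (is.null(coords)) coords <- mesh$nodes
  r <- coords[, 1L]; y <- coords[, 2L]
  n <- length(r)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  pts <- do.call(rbind, lapply(seq_along(th), function(j)
    cbind(r * cos(th[j]), y, r * sin(th[j]))))
  cells <- list()
  for (j in seq_len(n_theta)) {
    jn <- if (j == n_theta) 1L else j + 1L
    o1 <- (j - 1L) * n; o2 <- (jn - 1L) * n
    for (e in seq_len(n - 1L))
      cells[[length(cells) + 1L]] <-
        c(4L, o1 + e - 1L, o1 + e, o2 + e, o2 + e - 1L)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric eye surface", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(pts))), con)
  utils::write.table(format(pts, digits = 7), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", length(cells), 5L * length(cells)), con)
  utils::write.table(do.call(rbind, cells), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", length(cells)), con)
  writeLines(as.character(rep(9L, length(cells))), con)
  invisible(path)
}

#' Checkpoint a pressurised state to JSON text
#'
#' Sweeps reuse the (expensive) pressurisation phase through checkpoints.
#' Everything needed to resume -- geometry configuration, regional material
#' constants, the zero-pressure reference nodes, the current kinematic state
#' and the recorded pressurisation history -- is serialised as plain JSON.
#'
#' @param state an [pressurize()] / `eye_state`.
#' @param path file path.
#' @export
write_state_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "eye_state"))
  sim <- state$sim
  obj <- list(config = unclass(state$mesh$config),
              reference_nodes = state$mesh$nodes,
              r = sim$r, y = sim$y, vr = sim$vr, vy = sim$vy, t = sim$t,
              cavity = sim$cavity[c("mode", "P0", "V0", "Kf")],
              iop = state$iop,
              ke_fraction = state$ke_fraction,
              blocks = lapply(state$blocks, function(b)
                b[c("time", "apex_y", "apex_vy", "cavity_mmHg", "pos_r",
                    "pos_y", "energies")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_checkpoint
#' @param materials regional material list used when the state was created.
#' @export
read_state_checkpoint <- function(path, materials) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  config <- do.call(eye_geometry_config, obj$config)
  mesh <- build_eye_mesh(config)
  ref <- as.matrix(obj$reference_nodes)
  colnames(ref) <- c("r", "y")
  mesh <- remesh_nodes(mesh, ref)
  sim <- new_sim(mesh, materials)
  sim$r <- obj$r; sim$y <- obj$y; sim$vr <- obj$vr; sim$vy <- obj$vy
  sim$t <- obj$t
  sim$cavity <- list(mode = obj$cavity$mode, P0 = obj$cavity$P0,
                     V0 = obj$cavity$V0, Kf = obj$cavity$Kf)
  blocks <- apply_checkpoint_blocks(obj$blocks)
  traj <- make_trajectory(blocks, sim, scenario = "pressurization",
                          load_onset = sim$t, dt_out = NA_real_)
  structure(list(sim = sim, blocks = blocks, trajectory = traj,
                 mesh = mesh, iop = obj$iop,
                 cavity = cavity_state(obj$cavity$V0, obj$iop,
                                       obj$cavity$Kf),
                 ke_fraction = obj$ke_fraction),
            class = "eye_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild recorded blocks from their JSON form
apply_checkpoint_blocks <- function(blocks) {
  lapply(blocks, function(b) {
    en <- as.matrix(b$energies)
    colnames(en) <- c("strain", "cornea_strain", "cavity", "contact",
                      "kinetic")
    list(time = b$time, apex_y = b$apex_y, apex_vy = b$apex_vy,
         cavity_mmHg = b$cavity_mmHg,
         pos_r = as.matrix(b$pos_r), pos_y = as.matrix(b$pos_y),
         air_p = NULL, mass_y = NULL, mass_v = NULL,
         energies = en)
  })
}
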