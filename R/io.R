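# File formats and run configuration: sweep datasets as commented CSV, fit
# reports as JSON, JSON run configs with schema validation, and legacy-ASCII
# VTK export of meshes and fields for external inspection.

pkg_version <- function() {
  as.character(utils::packageVersion("pillartrap"))
}

# small FNV-1a hash for config provenance stamps (hex string); the running
# state is kept in doubles (exact below 2^53), xor-ing only the low byte
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime (403 + 2^24), kept exact in
    # doubles: the 2^24 part only sees the low byte of h modulo 2^32
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

output_header <- function(seed = NULL, config = NULL) {
  c(sprintf("# pillartrap %s", pkg_version()),
    sprintf("# config_hash: %s",
            if (is.null(config)) "none" else
              fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE))),
    sprintf("# seed: %s", if (is.null(seed)) "none" else seed))
}

#' Read and write sweep-record datasets
#'
#' Sweep datasets are CSV files with columns `E_pa`, `nu`, `diameter_um`,
#' `gap_um`, `pc_pa` (and optionally `failed`). Files written by
#' [write_sweep_csv()] start with `#` comment lines recording the package
#' version, a config hash and the seed.
#'
#' @param records A data frame of sweep records (see
#'   [sweep_critical_pressure()]).
#' @param path File path.
#' @param seed,config Optional provenance recorded in the header.
#'
#' @return `read_sweep_csv()` returns a tibble; `write_sweep_csv()` its
#'   input, invisibly.
#' @export
write_sweep_csv <- function(records, path, seed = NULL, config = NULL) {
  records <- normalize_records(records)
  writeLines(c(output_header(seed, config),
               readr::format_csv(records)), path)
  invisible(records)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  normalize_records(readr::read_csv(path, comment = "#",
                                    show_col_types = FALSE))
}

#' Read and write power-law fit reports
#'
#' Fit reports are JSON files with the fitted coefficient and exponent,
#' goodness of fit (pressure-scale R-squared), residual standard errors on
#' both scales, and the number of points.
#'
#' @param fit A `pc_fit` from [fit_power_law()].
#' @param path File path.
#' @param seed,config Optional provenance.
#' @return `read_fit_json()` returns a named list; `write_fit_json()` the
#'   report list, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL, config = NULL) {
  stopifnot(inherits(fit, "pc_fit"))
  report <- list(
    coefficient = fit$model$coefficient,
    exponent = fit$model$exponent,
    r_squared = fit$r_squared,
    se_log = fit$se_log,
    se_pa = fit$se_pa,
    n_points = fit$n_points,
    exponent_mode = fit$exponent_mode,
    method = fit$method,
    tool_version = pkg_version(),
    config_hash = if (is.null(config)) "none" else
      fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE)),
    seed = if (is.null(seed)) "none" else seed)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::fromJSON(path)
}

# ---- run configuration ----------------------------------------------------

#' Read and validate a run configuration
#'
#' Run configurations are JSON objects with a `schema_version` (currently
#' 1), a `command`, and command-specific fields. Validation happens before
#' any computation; a missing or malformed field raises a classed config
#' error naming the field path.
#'
#' @param path Path to a JSON config file (or a list already parsed).
#' @param command Optional command the config must declare.
#'
#' @return The validated config as a named list.
#' @export
read_run_config <- function(path, command = NULL) {
  config <- if (is.character(path)) {
    tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
             error = function(e) {
               pt_abort(sprintf("Cannot parse config '%s': %s", path,
                                conditionMessage(e)), "config")
             })
  } else if (is.list(path)) {
    path
  } else {
    pt_abort("`path` must be a file path or a list.", "config")
  }
  if (is.null(config$schema_version) || config$schema_version != 1) {
    pt_abort("Config field `schema_version` missing or unsupported (expect 1).",
             "config")
  }
  if (is.null(config$command)) {
    pt_abort("Config field `command` is missing.", "config")
  }
  if (!is.null(command) && !identical(config$command, command)) {
    pt_abort(sprintf("Config declares command '%s', expected '%s'.",
                     config$command, command), "config")
  }
  config
}

config_require <- function(config, fields) {
  for (f in fields) {
    parts <- strsplit(f, ".", fixed = TRUE)[[1]]
    node <- config
    for (p in parts) {
      node <- node[[p]]
      if (is.null(node)) {
        pt_abort(sprintf("Config field `%s` is missing.", f), "config")
      }
    }
  }
  invisible(config)
}

# ---- VTK export -----------------------------------------------------------

#' Export meshes and fields as legacy-ASCII VTK
#'
#' Writes an unstructured grid that ParaView and similar tools read
#' directly. `write_vtk_cell_mesh()` exports a (possibly deformed)
#' tetrahedral cell mesh, `write_vtk_surface()` the pillar facets, and
#' `write_vtk_flow()` the 2D flow solution with velocity and pressure point
#' data.
#'
#' @param mesh A [cell_mesh()].
#' @param path Output file path.
#' @param nodes Optional deformed node positions (defaults to the reference
#'   mesh nodes).
#' @return The path, invisibly.
#' @export
write_vtk_cell_mesh <- function(mesh, path, nodes = NULL) {
  stopifnot(inherits(mesh, "cell_mesh"))
  nodes <- nodes %||% mesh$nodes
  write_vtk_unstructured(path, nodes, mesh$tets - 1L, cell_type = 10L)
}

#' @rdname write_vtk_cell_mesh
#' @param surface A `rigid_surface` from [build_pillar_surface()].
#' @export
write_vtk_surface <- function(surface, path) {
  stopifnot(inherits(surface, "rigid_surface"))
  tr <- surface$triangles
  pts <- rbind(tr[, 1:3], tr[, 4:6], tr[, 7:9])
  n <- nrow(tr)
  conn <- cbind(seq_len(n) - 1L, seq_len(n) + n - 1L, seq_len(n) + 2L * n - 1L)
  write_vtk_unstructured(path, pts, conn, cell_type = 5L)
}

#' @rdname write_vtk_cell_mesh
#' @param solution A `flow_solution` from [solve_flow()].
#' @export
write_vtk_flow <- function(solution, path) {
  stopifnot(inherits(solution, "flow_solution"))
  dom <- solution$domain
  pts <- cbind(dom$nodes, 0)
  write_vtk_unstructured(
    path, pts, dom$triangles - 1L, cell_type = 5L,
    point_data = list(u_um_s = solution$u, v_um_s = solution$v,
                      p_pa = solution$p))
}

write_vtk_unstructured <- function(path, points, conn0, cell_type,
                                   point_data = list()) {
  if (ncol(points) == 2) points <- cbind(points, 0)
  npt <- nrow(points)
  ncell <- nrow(conn0)
  k <- ncol(conn0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("pillartrap %s", pkg_version()),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", npt)), con)
  utils::write.table(format(points, scientific = TRUE, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ncell, ncell * (k + 1)), con)
  utils::write.table(cbind(k, conn0), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(as.character(rep(cell_type, ncell)), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", npt), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], scientific = TRUE, digits = 8),
                 con)
    }
  }
  invisible(path)
}
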