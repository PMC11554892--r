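# On-disk formats. Clinical units throughout (mm, s, mmHg, ml); CSV is
# comma-separated UTF-8 with '.' decimal and a mandatory header; structured
# artifacts (vein trees, calibrations, reports) are JSON; meshes with their
# nodal/cell fields are legacy ASCII VTK unstructured grids (hexahedra).

#' Read patient summary records
#'
#' CSV with columns `patient_id, fibrotic, esv, edv, sv, ef, p_d, p_s, hr`
#' (optional `nyha_class`). Printed values are preserved; internal
#' consistency (SV vs EDV-ESV within 1 ml, EF vs 100 SV/EDV within 0.3
#' points) is checked with warnings, never silent fixes, and a validation
#' report is attached.
#'
#' @param path CSV file path.
#' @return Data.frame of class `patient_record` with attribute `validation`.
#' @export
read_patient_records <- function(path) {
  if (!file.exists(path)) stop("patient record file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_patient_records(df)
}

#' Validate patient summary records
#' @param df data.frame of records.
#' @return The records, classed, with a `validation` attribute (one row per
#'   flagged issue).
#' @export
validate_patient_records <- function(df) {
  mandatory <- c("patient_id", "fibrotic", "esv", "edv", "sv", "ef", "p_d", "p_s", "hr")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("patient record format error: missing column(s) ",
         paste(missing, collapse = ", "))
  for (col in setdiff(mandatory, c("patient_id", "fibrotic"))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("patient record parse error: non-numeric '%s' in row %d",
                   col, bad[1]))
    df[[col]] <- v
  }
  df$fibrotic <- as.logical(df$fibrotic)

  issues <- list()
  flag <- function(row, what, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, patient_id = df$patient_id[row], issue = what, detail = detail)
  }
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!(r$edv > r$esv && r$esv > 0)) {
      flag(i, "volumes", sprintf("EDV %.0f must exceed ESV %.0f > 0", r$edv, r$esv))
      warning(sprintf("record %s: EDV/ESV ordering violated", r$patient_id))
    }
    if (!(r$ef > 0 && r$ef < 100)) flag(i, "ef-range", sprintf("EF %.1f", r$ef))
    if (!(r$p_s > r$p_d && r$p_d > 0)) flag(i, "pressures", sprintf("%.0f/%.0f", r$p_d, r$p_s))
    if (!(r$hr > 0)) flag(i, "hr", sprintf("%.0f", r$hr))
    dsv <- r$sv - (r$edv - r$esv)
    if (abs(dsv) > 1e-9)
      flag(i, "sv-consistency", sprintf("SV %.1f vs EDV-ESV %.1f", r$sv, r$edv - r$esv))
    if (abs(dsv) > 1)
      warning(sprintf("record %s: SV inconsistent with EDV-ESV by %.1f ml",
                      r$patient_id, dsv))
    def <- r$ef - 100 * r$sv / r$edv
    if (abs(def) > 1e-9)
      flag(i, "ef-consistency", sprintf("EF %.1f vs 100 SV/EDV %.2f", r$ef, 100 * r$sv / r$edv))
    if (abs(def) > 0.3)
      warning(sprintf("record %s: EF inconsistent with SV/EDV by %.2f points",
                      r$patient_id, def))
  }
  attr(df, "validation") <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(0), patient_id = character(0),
               issue = character(0), detail = character(0))
  class(df) <- c("patient_record", "data.frame")
  df
}

#' Write patient summary records
#' @param df records data.frame.
#' @param path output CSV path.
#' @export
write_patient_records <- function(df, path) {
  utils::write.csv(as.data.frame(df)[, c("patient_id", "fibrotic",
                                         intersect("nyha_class", names(df)),
                                         "esv", "edv", "sv", "ef", "p_d", "p_s", "hr")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- VTK legacy ASCII unstructured grid -------------------------------------

#' Write an LV mesh (with optional fields) as legacy ASCII VTK
#'
#' @param mesh an `lv_mesh`.
#' @param path output `.vtk` path.
#' @param point_data named list of per-node scalar vectors (e.g. `psi`).
#' @param cell_data named list of per-element fields: scalars or 3-column
#'   matrices (vectors, e.g. fibre directions).
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("LV mesh")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  n <- nrow(mesh$nodes)
  wl("POINTS %d double", n)
  writeLines(apply(format(mesh$nodes, digits = 17, trim = TRUE, scientific = TRUE),
                   1, paste, collapse = " "), con)
  m <- nrow(mesh$elems)
  wl("CELLS %d %d", m, 9L * m)
  writeLines(paste(8L, apply(mesh$elems - 1L, 1, paste, collapse = " ")), con)
  wl("CELL_TYPES %d", m)
  writeLines(as.character(rep(12L, m)), con)
  if (length(point_data)) {
    wl("POINT_DATA %d", n)
    for (nm in names(point_data)) {
      wl("SCALARS %s double 1", nm)
      wl("LOOKUP_TABLE default")
      writeLines(format(point_data[[nm]], digits = 17, trim = TRUE, scientific = TRUE), con)
    }
  }
  if (length(cell_data)) {
    wl("CELL_DATA %d", m)
    for (nm in names(cell_data)) {
      fd <- cell_data[[nm]]
      if (is.matrix(fd) && ncol(fd) == 3) {
        wl("VECTORS %s double", nm)
        writeLines(apply(format(fd, digits = 17, trim = TRUE, scientific = TRUE),
                         1, paste, collapse = " "), con)
      } else {
        wl("SCALARS %s double 1", nm)
        wl("LOOKUP_TABLE default")
        writeLines(format(fd, digits = 17, trim = TRUE, scientific = TRUE), con)
      }
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid of hexahedra
#'
#' @param path `.vtk` path written by [write_mesh_vtk()] (or compatible).
#' @return List: `nodes`, `elems`, `point_data`, `cell_data`.
#' @export
read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(toks(ln[ip])[2])
  pts <- scan(text = paste(ln[(ip + 1):(ip + n)], collapse = "\n"),
              quiet = TRUE, n = 3 * n)
  nodes <- matrix(pts, n, 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  m <- as.integer(toks(ln[ic])[2])
  cell_lines <- ln[(ic + 1):(ic + m)]
  if (any(sub("\\s.*", "", trimws(cell_lines)) != "8"))
    stop("unsupported format: non-hexahedral cells in VTK file")
  cl <- matrix(scan(text = paste(cell_lines, collapse = "\n"), quiet = TRUE),
               m, 9, byrow = TRUE)
  itype <- grep("^CELL_TYPES", ln)[1]
  ct <- scan(text = paste(ln[(itype + 1):(itype + m)], collapse = "\n"), quiet = TRUE)
  if (any(ct != 12)) stop("unsupported format: non-hexahedral cell types in VTK file")
  elems <- cl[, -1, drop = FALSE] + 1
  mode(elems) <- "integer"

  read_fields <- function(start, count) {
    out <- list()
    i <- start
    while (i <= length(ln)) {
      if (grepl("^(POINT_DATA|CELL_DATA)", ln[i])) break
      if (grepl("^SCALARS", ln[i])) {
        nm <- toks(ln[i])[2]
        vals <- scan(text = paste(ln[(i + 2):length(ln)], collapse = "\n"),
                     quiet = TRUE, n = count)
        out[[nm]] <- vals
        i <- i + 2 + count
      } else if (grepl("^VECTORS", ln[i])) {
        nm <- toks(ln[i])[2]
        vals <- scan(text = paste(ln[(i + 1):length(ln)], collapse = "\n"),
                     quiet = TRUE, n = 3 * count)
        out[[nm]] <- matrix(vals, count, 3, byrow = TRUE)
        i <- i + 1 + count
      } else i <- i + 1
    }
    out
  }
  pd <- list(); cd <- list()
  ipd <- grep("^POINT_DATA", ln)
  if (length(ipd)) pd <- read_fields(ipd[1] + 1, n)
  icd <- grep("^CELL_DATA", ln)
  if (length(icd)) cd <- read_fields(icd[1] + 1, m)
  list(nodes = nodes, elems = elems, point_data = pd, cell_data = cd)
}

# ---- EAMS CSV ---------------------------------------------------------------

#' Write an EAMS cloud as CSV
#' @param cloud an `eams_cloud`.
#' @param path output path (columns x_mm, y_mm, z_mm, at_s, region).
#' @export
write_eams <- function(cloud, path) {
  df <- data.frame(x_mm = cloud$points[, 1], y_mm = cloud$points[, 2],
                   z_mm = cloud$points[, 3], at_s = cloud$at,
                   region = cloud$region)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EAMS cloud from CSV
#' @param path CSV with columns x_mm, y_mm, z_mm, at_s, region.
#' @return An `eams_cloud`.
#' @export
read_eams <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_mm", "y_mm", "z_mm", "at_s", "region")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("EAMS format error: missing column(s) ",
                            paste(missing, collapse = ", "))
  eams_cloud(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
             as.numeric(df$at_s), trimws(df$region))
}

# ---- vein tree / results JSON ----------------------------------------------

#' Write a vein tree as JSON
#' @param veins a `vein_tree`.
#' @param path output path.
#' @export
write_veins <- function(veins, path) {
  obj <- list(step = veins$step, seed = veins$seed,
              branch_names = veins$branch_names,
              branches = lapply(veins$branches, function(b)
                unname(apply(b, 1, as.numeric, simplify = FALSE))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vein tree from JSON
#' @param path JSON written by [write_veins()].
#' @return A `vein_tree`.
#' @export
read_veins <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  branches <- lapply(obj$branches, function(b) {
    if (is.list(b)) do.call(rbind, b) else matrix(b, ncol = 3, byrow = FALSE)
  })
  acc <- do.call(rbind, lapply(seq_along(branches), function(bi) {
    pl <- branches[[bi]]
    arc <- c(0, cumsum(rownorm(diff(pl))))
    data.frame(branch = bi, arc = arc, x = pl[, 1], y = pl[, 2], z = pl[, 3])
  }))
  structure(list(branches = branches, branch_names = obj$branch_names,
                 accessible = acc, step = obj$step, seed = obj$seed),
            class = "vein_tree")
}

#' Write a scenario report (JSON + CSV twin)
#' @param report a `scenario_report`.
#' @param path output path; `.json` written there, `.csv` alongside.
#' @param meta optional metadata list (config hash, seed, notes).
#' @export
write_report <- function(report, path, meta = list()) {
  jsonlite::write_json(list(meta = meta, report = as.data.frame(report)),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(as.data.frame(report), sub("\\.json$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Read a scenario report written by [write_report()]
#' @param path JSON path.
#' @return List with `meta` and the report data.frame.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$report <- structure(obj$report, class = c("scenario_report", "data.frame"))
  obj
}
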