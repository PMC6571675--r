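# File formats: profile CSV with '#'-comment metadata, machine-library JSON
# (schema shipped under inst/extdata), and raw+sidecar dose grids. All writes
# are atomic (temp file + rename); all parsers reject NaN/Inf.

.atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}

.num9 <- function(x) formatC(x, digits = 9, format = "g")

#' Write a lateral profile as CSV
#'
#' Format: optional `# depth_mm=<z>` / `# energy_MeV=<E>` comment lines, a
#' `r_mm,dose,sigma` header (sigma column present only when the profile has
#' uncertainties), then one row per point at 9 significant digits — enough
#' for a lossless write/read round trip at that precision.
#'
#' @param profile a [lateral_profile()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "lateral_profile"))
  .atomic_write(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    hdr <- character()
    if (is.finite(profile$depth))
      hdr <- c(hdr, sprintf("# depth_mm=%s", .num9(profile$depth)))
    if (is.finite(profile$energy))
      hdr <- c(hdr, sprintf("# energy_MeV=%s", .num9(profile$energy)))
    has_sigma <- !is.null(profile$sigma)
    hdr <- c(hdr, if (has_sigma) "r_mm,dose,sigma" else "r_mm,dose")
    rows <- if (has_sigma)
      paste(.num9(profile$radii), .num9(profile$dose), .num9(profile$sigma),
            sep = ",")
    else paste(.num9(profile$radii), .num9(profile$dose), sep = ",")
    writeLines(c(hdr, rows), con, sep = "\n")
  })
}

#' Read a lateral profile CSV
#'
#' Inverse of [write_profile()]. Malformed rows are reported with their file
#' row number; radii must be strictly increasing; NaN/Inf are rejected.
#'
#' @param path CSV file path.
#' @return A [lateral_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  meta <- list(depth = NA_real_, energy = NA_real_)
  is_comment <- startsWith(trimws(lines), "#")
  for (cm in lines[is_comment]) {
    kv <- regmatches(cm, regexec("#\\s*([A-Za-z_]+)\\s*=\\s*([-0-9.eE+]+)", cm))[[1]]
    if (length(kv) == 3L) {
      if (kv[2] == "depth_mm") meta$depth <- as.numeric(kv[3])
      if (kv[2] == "energy_MeV") meta$energy <- as.numeric(kv[3])
    }
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) < 2L) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(trimws(lines[body_idx[1]]), ",")[[1]]
  if (header[1] != "r_mm" || header[2] != "dose")
    stop("expected header 'r_mm,dose[,sigma]' in ", path, call. = FALSE)
  has_sigma <- length(header) >= 3L && header[3] == "sigma"
  ncol_exp <- if (has_sigma) 3L else 2L
  rows <- body_idx[-1]
  vals <- matrix(NA_real_, nrow = length(rows), ncol = ncol_exp)
  for (k in seq_along(rows)) {
    parts <- strsplit(trimws(lines[rows[k]]), ",")[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (length(v) != ncol_exp || any(is.na(v)) || any(!is.finite(v)))
      stop(sprintf("malformed row %d in %s: '%s'", rows[k], path,
                   lines[rows[k]]), call. = FALSE)
    vals[k, ] <- v
  }
  bad <- which(diff(vals[, 1]) <= 0)
  if (length(bad))
    stop(sprintf("radii not strictly increasing at row %d in %s",
                 rows[bad[1] + 1L], path), call. = FALSE)
  lateral_profile(vals[, 1], vals[, 2],
                  sigma = if (has_sigma) vals[, 3],
                  depth = meta$depth, energy = meta$energy)
}

# ---- machine JSON --------------------------------------------------------

.rm_to_list <- function(rm) {
  if (is.null(rm)) return(NULL)
  if (rm$mode == "power_law") list(mode = "power_law", a = rm$a, p = rm$p)
  else list(mode = "table",
            table = lapply(seq_len(nrow(rm$table)), function(i)
              list(energy_MeV = rm$table$energy_MeV[i],
                   range_mm = rm$table$range_mm[i])))
}

.rm_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  if (identical(x$mode, "power_law")) {
    range_model("power_law", a = x$a, p = x$p)
  } else if (identical(x$mode, "table")) {
    tab <- x$table
    if (is.data.frame(tab)) {
      range_model("table", table = tab[, c("energy_MeV", "range_mm")])
    } else {
      range_model("table", table = data.frame(
        energy_MeV = vapply(tab, `[[`, numeric(1), "energy_MeV"),
        range_mm = vapply(tab, `[[`, numeric(1), "range_mm")))
    }
  } else stop("range_model.mode must be 'power_law' or 'table'", call. = FALSE)
}

#' Write a machine library as JSON
#'
#' Serializes medium, range model and per-energy depth curves following the
#' schema shipped as `system.file("extdata", "machine-schema.json",
#' package = "stabledose")`. Numbers are written at full (repr-level)
#' precision.
#'
#' @param machine a [machine_library()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_machine <- function(machine, path) {
  stopifnot(inherits(machine, "machine_library"))
  beams <- lapply(machine$beams, function(b)
    list(energy_MeV = b$energy, range_mm = b$range,
         depths = lapply(seq_along(b$depths), function(i)
           list(z_mm = b$depths[i], alpha = b$alpha_z[i],
                gamma_mm = b$gamma_z[i], integral_dose = b$integral_dose[i]))))
  obj <- list(medium = machine$medium,
              range_model = .rm_to_list(machine$range_model),
              beams = beams)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  .atomic_write(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
}

.check_num <- function(x, what, where) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("machine JSON: %s missing or non-finite at %s", what, where),
         call. = FALSE)
  x
}

#' Read a machine library from JSON
#'
#' Validates the structure field by field with element-precise messages.
#' Entries with `alpha <= 1` are rejected at load time: the 2D shell
#' normalization (the first absolute moment of the stable law) diverges
#' there. Unknown extra keys produce a warning, not an error.
#'
#' @param path JSON file path.
#' @return A [machine_library()].
#' @export
read_machine <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  known <- c("medium", "range_model", "beams")
  extra <- setdiff(names(x), known)
  if (length(extra))
    warning("machine JSON: ignoring unknown key(s): ",
            paste(extra, collapse = ", "))
  if (is.null(x$beams) || !length(x$beams))
    stop("machine JSON: no beams", call. = FALSE)
  beams <- lapply(seq_along(x$beams), function(bi) {
    b <- x$beams[[bi]]
    where <- sprintf("beams[%d]", bi)
    e <- .check_num(b$energy_MeV, "energy_MeV", where)
    rg <- .check_num(b$range_mm, "range_mm", where)
    if (is.null(b$depths) || length(b$depths) < 3L)
      stop(sprintf("machine JSON: %s needs >= 3 depth entries", where),
           call. = FALSE)
    z <- a <- g <- id <- numeric(length(b$depths))
    for (di in seq_along(b$depths)) {
      d <- b$depths[[di]]
      w2 <- sprintf("%s.depths[%d]", where, di)
      z[di] <- .check_num(d$z_mm, "z_mm", w2)
      a[di] <- .check_num(d$alpha, "alpha", w2)
      g[di] <- .check_num(d$gamma_mm, "gamma_mm", w2)
      id[di] <- .check_num(d$integral_dose, "integral_dose", w2)
      if (a[di] <= 1)
        stop(sprintf(
          "machine JSON: alpha = %g <= 1 at %s: rejected, the 2D shell normalization diverges for alpha <= 1",
          a[di], w2), call. = FALSE)
    }
    depth_parameterization(e, z, a, g, id, rg)
  })
  machine_library(beams,
                  medium = if (is.null(x$medium)) "water" else x$medium,
                  range_model = .rm_from_list(x$range_model))
}

# ---- dose grids ----------------------------------------------------------

#' Write a dose grid (raw float32 + JSON sidecar)
#'
#' The 3D array is written as little-endian 32-bit floats, x-fastest, to
#' `path`; a JSON sidecar `<path>.json` records `{shape, spacing_mm,
#' origin_mm, units}`. With `mhd = TRUE` a MetaImage-style text header
#' `<path>.mhd` is also written for viewer compatibility.
#'
#' @param dg a [dose_grid()].
#' @param path output path for the raw buffer.
#' @param units dose unit label for the sidecar.
#' @param mhd also write a MetaImage header (default `FALSE`).
#' @return The path, invisibly.
#' @export
write_dose_grid <- function(dg, path, units = "arb", mhd = FALSE) {
  stopifnot(inherits(dg, "dose_grid"))
  .atomic_write(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    writeBin(as.numeric(dg$values), con, size = 4L, endian = "little")
  })
  sidecar <- list(shape = dim(dg$values), spacing_mm = dg$spacing,
                  origin_mm = dg$origin, units = units)
  .atomic_write(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(sidecar, tmp, digits = NA, pretty = TRUE))
  if (mhd) {
    d <- dim(dg$values)
    .atomic_write(paste0(sub("\\.raw$", "", path), ".mhd"), function(tmp)
      writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
                   "BinaryDataByteOrderMSB = False",
                   sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
                   sprintf("ElementSpacing = %g %g %g", dg$spacing[1],
                           dg$spacing[2], dg$spacing[3]),
                   sprintf("Offset = %g %g %g", dg$origin[1], dg$origin[2],
                           dg$origin[3]),
                   "ElementType = MET_FLOAT",
                   sprintf("ElementDataFile = %s", basename(path))), tmp))
  }
  invisible(path)
}

#' Read a dose grid written by [write_dose_grid()]
#'
#' @param path path to the raw buffer (sidecar `<path>.json` must exist).
#' @return A [dose_grid()].
#' @export
read_dose_grid <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar))
    stop("raw + sidecar pair not found at ", path, call. = FALSE)
  meta <- jsonlite::fromJSON(sidecar)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  if (length(v) != n)
    stop("raw buffer holds ", length(v), " values, sidecar promises ", n,
         call. = FALSE)
  dose_grid(array(v, dim = shape), spacing = as.numeric(meta$spacing_mm),
            origin = as.numeric(meta$origin_mm))
}
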