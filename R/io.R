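# File formats: MetaImage and NIfTI volumes, a documented projection
# container, collimator spec files and run configurations.

#' Write a voxel volume
#'
#' MetaImage (`.mhd` + `.raw`, double precision, little endian, x fastest)
#' preserves data, pitch and origin losslessly; NIfTI (`.nii`, via RNifti)
#' preserves data and pitch.
#'
#' @param vol a `voxel_volume`.
#' @param path output path ending in `.mhd` or `.nii`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (grepl("\\.mhd$", path)) {
    raw_path <- sub("\\.mhd$", ".raw", path)
    d <- dim(vol$data)
    hdr <- c(
      "ObjectType = Image",
      "NDims = 3",
      "BinaryData = True",
      "BinaryDataByteOrderMSB = False",
      sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
      sprintf("ElementSpacing = %.10g %.10g %.10g",
              vol$voxel_mm, vol$voxel_mm, vol$voxel_mm),
      sprintf("Offset = %.10g %.10g %.10g",
              vol$origin[1], vol$origin[2], vol$origin[3]),
      sprintf("Semantics = %s", vol$semantics),
      "ElementType = MET_DOUBLE",
      sprintf("ElementDataFile = %s", basename(raw_path)))
    writeLines(hdr, path)
    con <- file(raw_path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- rep(vol$voxel_mm, 3)
    RNifti::writeNifti(img, path)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' Read a voxel volume written by [write_volume()]
#' @param path `.mhd` or `.nii` path.
#' @param semantics value semantics for NIfTI files (MetaImage stores it).
#' @export
read_volume <- function(path, semantics = "activity_Bq") {
  if (grepl("\\.mhd$", path)) {
    lines <- readLines(path)
    kv <- strsplit(lines, " = ")
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, `[`, "", 2)
    get <- function(k) vals[match(k, keys)]
    d <- as.integer(strsplit(get("DimSize"), " ")[[1]])
    sp <- as.numeric(strsplit(get("ElementSpacing"), " ")[[1]])
    if (max(abs(diff(sp))) > 1e-9) stop("anisotropic voxels not supported")
    off <- as.numeric(strsplit(get("Offset"), " ")[[1]])
    sem <- get("Semantics")
    if (is.na(sem)) sem <- semantics
    raw_path <- file.path(dirname(path), get("ElementDataFile"))
    con <- file(raw_path, "rb")
    on.exit(close(con))
    dat <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
    voxel_volume(array(dat, d), sp[1], off, sem)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1]
    voxel_volume(array(as.numeric(img), dim(img)), sp, semantics = semantics)
  } else stop("unsupported volume format: ", path)
}

#' Write a projection set
#'
#' Documented grouped container: a directory holding `manifest.json`
#' (dimensions, windows, kind, pitch, orbit table, collimator spec, seeds)
#' and one raw little-endian float64 array per energy window
#' (`window_<name>.raw`, order `(u, v, view)`, u fastest).  The round trip
#' is bit exact.
#'
#' @param ps a `projection_set`.
#' @param dir output directory (created).
#' @export
write_projections <- function(ps, dir) {
  stopifnot(inherits(ps, "projection_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    kind = ps$kind, pitch_mm = ps$pitch,
    dim = dim(ps$windows[[1]]), windows = names(ps$windows),
    orbit = list(views = ps$orbit$views, center = ps$orbit$center),
    spec = unclass(ps$spec), meta = ps$meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (w in names(ps$windows)) {
    con <- file(file.path(dir, paste0("window_", w, ".raw")), "wb")
    writeBin(as.numeric(ps$windows[[w]]), con, size = 8, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' Read a projection set written by [write_projections()]
#' @param dir container directory.
#' @export
read_projections <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  d <- as.integer(man$dim)
  windows <- lapply(man$windows, function(w) {
    con <- file(file.path(dir, paste0("window_", w, ".raw")), "rb")
    on.exit(close(con))
    array(readBin(con, "double", n = prod(d), size = 8, endian = "little"), d)
  })
  names(windows) <- man$windows
  spec <- man$spec
  class(spec) <- "collimator_spec"
  orbit <- structure(list(views = as.data.frame(man$orbit$views),
                          center = as.numeric(man$orbit$center),
                          n_views = d[3]),
                     class = "detector_orbit")
  structure(list(windows = windows, kind = man$kind, orbit = orbit,
                 spec = spec, pitch = man$pitch_mm, components = NULL,
                 meta = man$meta),
            class = "projection_set")
}

#' Write / read a collimator spec as a key-value text file
#' @param spec a `collimator_spec`.
#' @param path file path.
#' @export
write_collimator <- function(spec, path) {
  flat <- unclass(spec)
  lines <- vapply(names(flat), function(k)
    paste0(k, " = ", paste(format(flat[[k]], digits = 12), collapse = " ")),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_collimator
#' @export
read_collimator <- function(path) {
  kv <- strsplit(readLines(path), " = ")
  out <- list()
  for (p in kv) {
    v <- strsplit(p[2], " ")[[1]]
    num <- suppressWarnings(as.numeric(v))
    out[[p[1]]] <- if (all(!is.na(num))) num else v
  }
  class(out) <- "collimator_spec"
  out
}

#' Write / read a run configuration (YAML)
#' @param config a named list.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
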