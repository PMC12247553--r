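# File formats: pulse-train JSON schema, minimal NIfTI-1 map I/O with JSON
# sidecars, and acquisition-geometry helpers.
#
# All stored quantities use base units (rad, s, 1/s); any display conversion
# is the caller's job. This removes the five-orders-of-magnitude ms-vs-us
# trap between TR and T2s.

#' Write / read a pulse train (JSON schema)
#'
#' Schema: `{tr_s, cycle_time_s, inversion: {trf_s}, pulses: [{alpha_rad,
#' trf_s}, ...]}`. Reading validates the schema and the train invariants and
#' enumerates offending pulse indices.
#'
#' @param train A `qmt_train`.
#' @param path File path (`.json`).
#' @return `read_train` returns a validated `qmt_train`.
#' @export
write_train <- function(train, path) {
  stopifnot(inherits(train, "qmt_train"))
  obj <- list(tr_s = train$tr, cycle_time_s = train$cycle_time,
              inversion = list(trf_s = train$trf_inv),
              pulses = data.frame(alpha_rad = train$alpha,
                                  trf_s = train$trf))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_train
#' @export
read_train <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("tr_s", "cycle_time_s", "inversion", "pulses")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("read_train: missing fields: ", paste(miss, collapse = ", "))
  p <- obj$pulses
  if (is.null(p$alpha_rad) || is.null(p$trf_s))
    stop("read_train: pulses must have alpha_rad and trf_s")
  pulse_train(p$alpha_rad, p$trf_s, tr = obj$tr_s,
              cycle_time = obj$cycle_time_s,
              trf_inv = obj$inversion$trf_s)
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 I/O (.nii, single file, little-endian, float32/float64).
# No NIfTI package exists in the supported dependency set, so the fixed
# 348-byte header is written directly.
# ---------------------------------------------------------------------------

#' Write / read a 3-D or 4-D array as NIfTI-1
#'
#' Single-file `.nii`, little-endian, `float32` (default) or `float64`,
#' sform affine. A JSON sidecar (same path, `.json`) records metadata such
#' as parameter units.
#'
#' @param path Path ending in `.nii`.
#' @param arr 3-D or 4-D numeric array.
#' @param pixdim Voxel sizes (mm), length 3.
#' @param affine 4x4 voxel-to-world matrix; default `diag(pixdim)`.
#' @param datatype `"float32"` or `"float64"`.
#' @param sidecar Named list written as JSON sidecar (or `NULL`).
#' @return `read_nifti` returns a list `data`, `pixdim`, `affine`,
#'   `sidecar`.
#' @export
write_nifti <- function(path, arr, pixdim = c(1, 1, 1), affine = NULL,
                        datatype = c("float32", "float64"), sidecar = NULL) {
  datatype <- match.arg(datatype)
  nd <- length(dim(arr))
  if (!nd %in% c(3, 4)) stop("write_nifti: arr must be 3-D or 4-D")
  if (is.null(affine)) {
    affine <- diag(c(pixdim, 1))
  }
  stopifnot(identical(dim(affine), c(4L, 4L)))
  dims <- c(nd, dim(arr), rep(1L, 7 - nd))
  dt_code <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L
  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wI(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # unused
  wI(dims, 2)                                  # dim[8]
  wF(c(0, 0, 0)); wI(c(0, 0), 2)               # intent_p*, intent_code+datatype placeholder
  seek(con, 70); wI(dt_code, 2); wI(bitpix, 2) # datatype, bitpix
  wI(0, 2)                                     # slice_start
  wF(c(1, pixdim, rep(1, 4)))                  # pixdim[8] (qfac = 1)
  wF(352)                                      # vox_offset
  wF(1); wF(0)                                 # scl_slope, scl_inter
  wI(0, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wF(c(0, 0, 0, 0))                            # cal_max/min, slice_dur, toffset
  wI(c(0, 0), 4)                               # glmax, glmin
  writeBin(raw(104), con)                      # descrip + aux_file
  wI(c(0, 1), 2)                               # qform_code=0, sform_code=1
  wF(rep(0, 6))                                # quatern b,c,d + qoffset x,y,z
  wF(t(affine[1:3, ]))                         # srow_x/y/z
  writeBin(raw(16), con)                       # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)  # magic
  writeBin(raw(4), con)                        # extension flag
  stopifnot(seek(con) == 352)
  writeBin(as.numeric(arr), con, size = bitpix / 8, endian = "little")
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, sub("\\.nii$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rI <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rF <- function(n) readBin(con, "numeric", n = n, size = 4,
                            endian = "little")
  if (rI(1, 4) != 348) stop("read_nifti: not a NIfTI-1 file")
  seek(con, 40)
  dims <- rI(8, 2)
  nd <- dims[1]
  seek(con, 70)
  dt_code <- rI(1, 2)
  if (!dt_code %in% c(16L, 64L))
    stop("read_nifti: unsupported datatype code ", dt_code)
  seek(con, 76)
  pd <- rF(8)
  vox_offset <- rF(1)
  seek(con, 252)
  codes <- rI(2, 2)
  rF(6)
  srow <- matrix(rF(12), nrow = 3, byrow = TRUE)
  affine <- rbind(srow, c(0, 0, 0, 1))
  seek(con, vox_offset)
  n <- prod(dims[2:(nd + 1)])
  sz <- if (dt_code == 16L) 4L else 8L
  data <- readBin(con, "numeric", n = n, size = sz, endian = "little")
  dim(data) <- dims[2:(nd + 1)]
  scpath <- sub("\\.nii$", ".json", path)
  sidecar <- if (file.exists(scpath))
    jsonlite::read_json(scpath, simplifyVector = TRUE) else NULL
  list(data = data, pixdim = pd[2:4], affine = affine, sidecar = sidecar)
}

#' Write / read a set of co-registered parameter maps
#'
#' One `.nii` + `.json` sidecar per map under a common prefix; the sidecar
#' records the parameter unit (e.g. "1/s", "s", "fraction", "rad/s") and
#' any extra metadata. Reading verifies that all maps share one affine.
#'
#' @param prefix Path prefix; map `name` goes to `<prefix>_<name>.nii`.
#' @param maps Named list of 3-D (or 4-D) arrays.
#' @param units Named character vector of units per map (optional entries).
#' @param metadata Extra metadata stored in every sidecar.
#' @param pixdim,affine As in [write_nifti()].
#' @return `read_qmt_maps` returns `list(maps, units, metadata, affine)`.
#' @export
write_qmt_maps <- function(prefix, maps, units = NULL, metadata = list(),
                           pixdim = c(1, 1, 1), affine = NULL) {
  stopifnot(is.list(maps), length(names(maps)) == length(maps))
  for (nm in names(maps)) {
    sc <- c(list(parameter = nm,
                 unit = if (!is.null(units[[nm]])) units[[nm]] else ""),
            metadata)
    write_nifti(paste0(prefix, "_", nm, ".nii"), maps[[nm]],
                pixdim = pixdim, affine = affine, sidecar = sc)
  }
  invisible(prefix)
}

#' @rdname write_qmt_maps
#' @export
read_qmt_maps <- function(prefix) {
  files <- Sys.glob(paste0(prefix, "_*.nii"))
  if (!length(files)) stop("read_qmt_maps: no maps under prefix ", prefix)
  maps <- list(); units <- character(); aff <- NULL
  for (f in files) {
    nm <- sub("\\.nii$", "", sub(paste0("^", basename(prefix), "_"), "",
                                 basename(f)))
    x <- read_nifti(f)
    if (is.null(aff)) aff <- x$affine
    else if (max(abs(aff - x$affine)) > 1e-4)
      stop("read_qmt_maps: affine mismatch across maps (", nm, ")")
    maps[[nm]] <- x$data
    units[nm] <- x$sidecar$unit %||% ""
  }
  list(maps = maps, units = units, affine = aff,
       metadata = read_nifti(files[1])$sidecar)
}

#' Effective resolution of insphere (koosh-ball) k-space coverage
#'
#' A 3-D center-out radial trajectory samples the insphere of the Cartesian
#' k-space cube of a given nominal resolution. Comparing covered k-space
#' volumes, the effective resolution is larger by `(6/pi)^(1/3) ~ 1.2407`:
#' a nominal 1.0 mm acquisition has an effective resolution of 1.24 mm.
#'
#' @param nominal_res Nominal resolution, mm; `> 0`.
#' @return Effective resolution, mm.
#' @export
effective_resolution <- function(nominal_res) {
  if (any(nominal_res <= 0))
    stop("effective_resolution: nominal_res must be > 0")
  nominal_res * (6 / pi)^(1 / 3)
}
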