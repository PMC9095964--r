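# Serialisation: sequence containers and model checkpoints as RDS (no HDF5
# binding exists in this R stack, so the logical layout — image, kspace,
# mask, true velocity fields per sequence, with acceleration and seed
# attributes — is kept in plain R lists), plus a minimal single-file NIfTI-1
# writer for exporting magnitude series to external viewers.

#' Save / load a list of sequences
#'
#' Each item is a list with any of: `sequence` (a [dyn_sequence()]),
#' `kspace`, `mask`, `velocities`, plus free-form attributes such as
#' `acceleration` and `seed`.
#'
#' @param items list of sequence records.
#' @param path file path (`.rds`).
#' @return `load_sequences` returns the list.
#' @export
save_sequences <- function(items, path) {
  saveRDS(items, path, compress = FALSE)
  invisible(path)
}

#' @rdname save_sequences
#' @export
load_sequences <- function(path) {
  if (!file.exists(path)) stop("load_sequences: no such file: ", path)
  readRDS(path)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full model (both networks' parameters and
#' configurations) plus an arbitrary metadata list, in one file.
#'
#' @param model a [grd_model()].
#' @param path file path (`.rds`).
#' @param meta optional metadata (training config, history, seeds).
#' @return `load_checkpoint` returns `list(model, meta)`.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  stopifnot(inherits(model, "grd_model"))
  saveRDS(list(model = model, meta = meta), path, compress = FALSE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("load_checkpoint: no such file: ", path)
  readRDS(path)
}

#' Export a magnitude image series as single-file NIfTI-1
#'
#' Writes an `H x W x 1 x N` float32 volume (little-endian, `n+1` magic,
#' unit voxel dimensions) readable by standard viewers.
#'
#' @param magnitudes real array `H x W` or `H x W x N`.
#' @param path output path (`.nii`).
#' @return the path, invisibly.
#' @export
write_nifti <- function(magnitudes, path) {
  d <- dim(magnitudes)
  if (length(d) == 2) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # unused
  wi(c(4, d[1], d[2], 1, d[3], 1, 1, 1), 2)    # dim
  wf(c(0, 0, 0))                               # intent_p1..p3
  wi(0, 2)                                     # intent_code
  wi(16, 2)                                    # datatype: float32
  wi(32, 2)                                    # bitpix
  wi(0, 2)                                     # slice_start
  wf(c(1, 1, 1, 1, 1, 0, 0, 0))                # pixdim
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0, 2); wi(0, 1); wi(0, 1)                 # slice_end, slice_code, xyzt
  wf(c(max(magnitudes), min(magnitudes)))      # cal_max, cal_min
  wf(c(0, 0))                                  # slice_duration, toffset
  wi(c(0, 0), 4)                               # glmax, glmin
  writeBin(raw(80 + 24), con)                  # descrip, aux_file
  wi(c(0, 0), 2)                               # qform_code, sform_code
  wf(numeric(18))                              # quaternions + srows
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)                        # extension flag
  wf(as.numeric(magnitudes))
  invisible(path)
}
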