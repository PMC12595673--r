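# Package-native epochs bundle: meta.json + data.f32 (little-endian float32,
# trial-major). Lossless up to float32 precision, byte-stable for a given
# epochs set.

#' Write an epochs set as a bundle directory
#'
#' @param x An `epochs_set`.
#' @param dir Output directory (created if needed); receives `meta.json` and
#'   `data.f32`.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(x, dir) {
  stopifnot(inherits(x, "epochs_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "assrtools-epochs-bundle",
    version = 1L,
    n_trials = nrow(x$data),
    n_samples = ncol(x$data),
    fs_hz = x$fs_hz,
    t0_s = x$t0_s,
    stim_rate_hz = if (is.na(x$stim_rate_hz)) "none" else x$stim_rate_hz,
    dtype = "float32",
    byte_order = "little",
    units = "uV",
    order = "trial-major",
    meta = x$meta
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(dir, "data.f32"), "wb")
  on.exit(close(con))
  if (nrow(x$data) > 0) {
    writeBin(as.numeric(t(x$data)), con, size = 4, endian = "little")
  }
  invisible(dir)
}

#' Read an epochs bundle directory
#'
#' @param dir Directory containing `meta.json` and `data.f32`.
#' @return An `epochs_set`.
#' @export
read_bundle <- function(dir) {
  mpath <- file.path(dir, "meta.json")
  dpath <- file.path(dir, "data.f32")
  if (!file.exists(mpath) || !file.exists(dpath)) {
    stop("not an epochs bundle (missing meta.json or data.f32): ", dir)
  }
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  nt <- as.integer(meta$n_trials)
  ns <- as.integer(meta$n_samples)
  expect_bytes <- 4 * nt * ns
  if (file.size(dpath) != expect_bytes) {
    stop(sprintf("bundle integrity error: data.f32 has %d bytes, metadata implies %d",
                 file.size(dpath), expect_bytes))
  }
  vals <- if (expect_bytes > 0) {
    con <- file(dpath, "rb")
    on.exit(close(con))
    readBin(con, "numeric", n = nt * ns, size = 4, endian = "little")
  } else numeric(0)
  dat <- matrix(vals, nrow = nt, ncol = ns, byrow = TRUE)
  rate <- meta$stim_rate_hz
  rate <- if (identical(rate, "none")) NA_real_ else as.numeric(rate)
  epochs_set(dat, meta$fs_hz, meta$t0_s, rate, as.list(meta$meta))
}
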