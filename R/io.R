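num17 <- function(x) sprintf("%.17g", as.numeric(x))

# serialize a tibble column-wise with lossless numerics
df_to_json_list <- function(df) {
  lapply(as.list(df), function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      list(type = "double", values = num17(col))
    } else if (is.integer(col)) {
      list(type = "integer", values = col)
    } else if (is.logical(col)) {
      list(type = "logical", values = col)
    } else {
      list(type = "character", values = as.character(col))
    }
  })
}

df_from_json_list <- function(lst, n) {
  cols <- lapply(lst, function(col) {
    switch(col$type,
      double = as.numeric(unlist(col$values)),
      integer = as.integer(unlist(col$values)),
      logical = as.logical(unlist(col$values)),
      as.character(unlist(col$values))
    )
  })
  if (length(cols) == 0) return(tibble::tibble(.rows = n))
  tibble::as_tibble(cols)
}

#' Write epoched data to the package's JSON container
#'
#' Schema `entrainr-epochs-v1`: a single JSON object holding the trials x
#' channels x samples array (column-major, serialized as `%.17g` strings so
#' doubles round-trip bit-identically), the time axis, sampling rate, channel
#' names, and the per-trial metadata table. Round trips losslessly through
#' [read_epochs()].
#'
#' @param epochs An [eeg_epochs()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  obj <- list(
    schema = "entrainr-epochs-v1",
    fs = num17(epochs$fs),
    dim = dim(epochs$data),
    times = num17(epochs$times),
    ch_names = epochs$ch_names,
    data = num17(as.vector(epochs$data)),
    info = df_to_json_list(epochs$info)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read epoched data from the package's JSON container
#'
#' @param path File written by [write_epochs()].
#' @return An [eeg_epochs()] object.
#' @export
read_epochs <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$schema, "entrainr-epochs-v1")) {
    abort("not an entrainr-epochs-v1 file (missing or wrong 'schema')")
  }
  for (field in c("fs", "dim", "times", "ch_names", "data", "info")) {
    if (is.null(obj[[field]])) {
      abort(sprintf("epochs container is missing required field '%s'", field))
    }
  }
  d <- as.integer(unlist(obj$dim))
  eeg_epochs(
    array(as.numeric(unlist(obj$data)), d),
    times = as.numeric(unlist(obj$times)),
    fs = as.numeric(obj$fs),
    ch_names = as.character(unlist(obj$ch_names)),
    info = df_from_json_list(obj$info, d[1])
  )
}

#' Write a continuous recording as a BrainVision triplet
#'
#' Emits `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg` (binary multiplexed
#' IEEE float32, resolution 1 microvolt). Events are written as stimulus
#' markers. Primarily a fixture generator and round-trip oracle for
#' [read_brainvision()].
#'
#' @param raw An [eeg_raw()] recording.
#' @param base Path base (without extension).
#' @param markers Optional tibble with columns `description` and `time` (ms)
#'   to write as markers.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(raw, base, markers = NULL) {
  stem <- basename(base)
  vhdr <- paste0(base, ".vhdr")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(raw$data)),
    paste0("SamplingInterval=", format(1e6 / raw$fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(raw$data)), raw$ch_names)
  ), vhdr, useBytes = TRUE)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"
  )
  if (!is.null(markers) && nrow(markers) > 0) {
    pos <- round((markers$time - raw$t0) * raw$fs / 1000) + 1
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(markers)) + 1, markers$description, pos))
  }
  writeLines(mk, paste0(base, ".vmrk"), useBytes = TRUE)
  con <- file(paste0(base, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(raw$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

parse_bv_ini <- function(lines) {
  kv <- grep("^[A-Za-z0-9]+=", lines, value = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(as.list(vals), keys)
}

#' Read a BrainVision recording
#'
#' Supports the common binary layout: multiplexed, `IEEE_FLOAT_32` or
#' `INT_16` (with per-channel resolution applied). Markers from the `.vmrk`
#' file are returned as events with onset times in ms.
#'
#' @param vhdr Path to the `.vhdr` header file.
#' @return An [eeg_raw()]; `events` has columns `type`, `description`,
#'   `onset` (ms).
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  ini <- parse_bv_ini(lines)
  if (!identical(ini$DataOrientation %||% "MULTIPLEXED", "MULTIPLEXED")) {
    abort("only MULTIPLEXED BrainVision data are supported")
  }
  fmt <- ini$BinaryFormat %||% "IEEE_FLOAT_32"
  n_chan <- as.integer(ini$NumberOfChannels)
  fs <- 1e6 / as.numeric(ini$SamplingInterval)
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  ch_names <- vapply(ch_parts, `[`, "", 1)
  resolution <- vapply(ch_parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, 0.0)
  eeg_path <- file.path(dirname(vhdr), ini$DataFile)
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    x <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    x <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little")
  } else {
    abort(sprintf("unsupported BinaryFormat '%s'", fmt))
  }
  dat <- matrix(x, nrow = n_chan) * resolution
  events <- tibble::tibble(type = character(), description = character(),
                           onset = numeric())
  vmrk <- file.path(dirname(vhdr), ini$MarkerFile %||% "")
  if (nzchar(ini$MarkerFile %||% "") && file.exists(vmrk)) {
    mlines <- grep("^Mk[0-9]+=", readLines(vmrk, warn = FALSE), value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", mlines), ",")
    keep <- vapply(parts, function(p) length(p) >= 3, TRUE)
    parts <- parts[keep]
    events <- tibble::tibble(
      type = vapply(parts, `[`, "", 1),
      description = vapply(parts, `[`, "", 2),
      onset = (as.numeric(vapply(parts, `[`, "", 3)) - 1) * 1000 / fs
    )
  }
  eeg_raw(dat, fs, ch_names, t0 = 0, events = events)
}

#' Default pipeline configuration
#'
#' A small demo configuration: 2 simulated participants, 4 blocks of 32
#' trials (32 trials per rhythmicity x stimulation cell), reduced 8-channel
#' montage, 1000 Hz native rate, and a reduced permutation count. A run is
#' fully reproducible from (config, seed).
#'
#' @param seed Integer seed (mandatory).
#' @return A nested list understood by [run_pipeline()].
#' @export
default_config <- function(seed) {
  list(
    seed = seed,
    design = list(n_participants = 2, n_blocks = 4, trials_per_block = 32),
    model = list(kappa = 0.8, alpha_amp = 10, noise_amp = 10,
                 artifact_amp = 500, artifact_duration = 8, iaf_sd = 1),
    preprocess = list(fs = 1000, target_fs = 100, n_channels = 8),
    analysis = list(f = 10, channels = c("O2", "PO4"), n_perm = 200,
                    n_bins = 6, cluster_window = "W4"),
    behavior = list(dmax = 2.4, c50 = 0.16, n = 2,
                    contrasts = exp(seq(log(0.04), log(0.80), length.out = 7)),
                    trials_per_level = 200, target_dprime = 1.2)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [default_config()];
#' `seed` is mandatory.
#'
#' @param path Path to a YAML file.
#' @return A config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed)) abort("config must specify a seed")
  cfg <- default_config(user$seed)
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(over[[nm]]) && is.list(base[[nm]])) {
        merge_in(base[[nm]], over[[nm]])
      } else {
        over[[nm]]
      }
    }
    base
  }
  merge_in(cfg, user)
}
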