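# ---- run configuration ----------------------------------------------------

run_config_defaults <- function() {
  list(seed = 1L, algorithm = "dash", n_slm = 16L, n_scat = 32L,
       pad_factor = 2L, sample_model = "layer", i0 = 1000, f = 0.3,
       P = 5L, iterations = 1L, skip_zero_mode_first_iteration = TRUE,
       use_sqrt = TRUE, modes = NULL, ordering = "spiral_low_to_high",
       trials = 10L, out_dir = ".", verbosity = 1L,
       ga = list(population = 30L, elite_fraction = 0.25,
                 mutation_rate_initial = 0.1, mutation_rate_final = 0.013,
                 decay = 650))
}

#' Build a validated run configuration
#'
#' Collects every knob of a simulation run (grids, photon budget, DASH
#' parameters, GA hyperparameters, output directory) into one list with
#' defaults filled in, validates it, and keeps it round-trippable
#' through [save_config()]/[load_config()].
#'
#' @param ... named overrides of the defaults; unknown names are an
#'   error. `ga` may be a partial list of GA hyperparameters.
#' @return An object of class `"run_config"`.
#' @examples
#' run_config(seed = 42, i0 = 100)$f  # default 0.3
#' @export
run_config <- function(...) {
  over <- list(...)
  cfg <- run_config_defaults()
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(over)) {
    if (nm == "ga") {
      bad <- setdiff(names(over$ga), names(cfg$ga))
      if (length(bad))
        stop("unknown ga field(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      cfg$ga[names(over$ga)] <- over$ga
    } else cfg[nm] <- over[nm]  # single-bracket keeps explicit NULLs
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid configuration: field '", field, "' ", msg,
                  call. = FALSE)
  chk(cfg$f > 0 && cfg$f < 1, "f", "must lie strictly in (0, 1)")
  chk(cfg$P >= 3, "P", "must be >= 3")
  chk(cfg$i0 > 0, "i0", "must be > 0")
  chk(cfg$pad_factor >= 1, "pad_factor", "must be >= 1")
  chk(cfg$n_scat %% cfg$n_slm == 0, "n_scat",
      "must be an integer multiple of n_slm")
  chk(cfg$sample_model %in% c("layer", "point"), "sample_model",
      "must be 'layer' or 'point'")
  chk(cfg$ordering %in% c("spiral_low_to_high", "raster"), "ordering",
      "must be 'spiral_low_to_high' or 'raster'")
  chk(cfg$iterations >= 1, "iterations", "must be >= 1")
  chk(is.null(cfg$modes) || sqrt(cfg$modes) %% 1 == 0, "modes",
      "must be a perfect square (S^2 grating modes)")
  int_fields <- c("seed", "n_slm", "n_scat", "pad_factor", "P",
                  "iterations", "trials", "verbosity")
  cfg[int_fields] <- lapply(cfg[int_fields], as.integer)
  if (!is.null(cfg$modes)) cfg$modes <- as.integer(cfg$modes)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the package defaults
#' (`f = 0.3`, `P = 5`, `pad_factor = 2`, `sample_model = "layer"`, ...).
#'
#' @param path path to a YAML configuration file.
#' @return A validated `"run_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

#' Save a run configuration to a YAML file
#'
#' @param config a `"run_config"`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

# ---- 16-bit grayscale PNG codec -------------------------------------------
# No installed package writes 16-bit PNG, so the container (chunk
# layout + CRC32) is assembled here around the zlib stream produced by
# memCompress; reading uses png::readPNG, which supports 16-bit depth.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
          else bitwShiftR(bitwAnd(c, -2L), 1)
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8), tab[idx + 1L])
  }
  bitwXor(crc, -1L)
}

u32be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  c(u32be(length(data)), body, u32be(if (crc < 0) crc + 4294967296 else crc))
}

#' Write a phase mask as a 16-bit grayscale PNG
#'
#' Phases are wrapped to `[0, 2*pi)` and mapped linearly onto the 16-bit
#' range `[0, 65535]`; a JSON sidecar (`<path>.json`) records the grid
#' size and any extra metadata (e.g. the seed) so the mask is fully
#' reconstructible.
#'
#' @param phase real phase matrix.
#' @param path destination `.png` path.
#' @param metadata named list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_phase_png <- function(phase, path, metadata = list()) {
  stopifnot(is.matrix(phase))
  v <- round((phase %% (2 * pi)) / (2 * pi) * 65535)
  h <- nrow(v); w <- ncol(v)
  # scanlines: filter byte 0, then big-endian 16-bit samples, row-major
  sl <- raw((2L * w + 1L) * h)
  pos <- 0L
  for (r in seq_len(h)) {
    row <- as.integer(v[r, ])
    bytes <- as.raw(rbind(row %/% 256L, row %% 256L))
    sl[pos + 1L] <- as.raw(0)
    sl[pos + 1L + seq_len(2L * w)] <- bytes
    pos <- pos + 2L * w + 1L
  }
  # memCompress's "gzip" type emits a zlib stream (0x78 0x9c header,
  # Adler32 trailer), which is exactly what the IDAT chunk needs
  idat <- memCompress(sl, type = "gzip")
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  side <- c(list(side = h, bit_depth = 16L,
                 phase_range = c(0, 2 * pi)), metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a phase mask written by [write_phase_png()]
#'
#' @param path path to the `.png` file.
#' @return List with `phase` (matrix, radians in `[0, 2*pi)`) and
#'   `metadata` (sidecar contents, or `NULL` if absent).
#' @export
read_phase_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 2L)
    stop("expected a grayscale PNG", call. = FALSE)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  list(phase = img * 2 * pi, metadata = meta)
}

# ---- run outputs ----------------------------------------------------------

#' Write run outputs to a directory
#'
#' Serialises a `"wavefront_run"` or `"benchmark_result"` (or `NULL` for
#' metadata only) together with its configuration: CSV traces, JSON
#' metadata, 16-bit PNG correction masks, and a manifest with MD5
#' checksums of every file written.
#'
#' @param result a `"wavefront_run"`, `"benchmark_result"`, or `NULL`.
#' @param config the `"run_config"` (or any serialisable list) used.
#' @param out_dir output directory (created if needed).
#' @return Data frame manifest with columns `file` and `md5`.
#' @export
write_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  written <- character(0)
  emit <- function(fname) {
    written <<- c(written, fname)
    file.path(out_dir, fname)
  }
  meta <- list(package = "dashsim",
               version = as.character(utils::packageVersion("dashsim")),
               config = if (is.null(config)) NULL else unclass(config))
  if (inherits(result, "wavefront_run")) {
    utils::write.csv(as.data.frame(result$trace), emit("trace.csv"),
                     row.names = FALSE)
    if (!is.null(result$measurements))
      utils::write.csv(result$measurements, emit("measurements.csv"),
                       row.names = FALSE)
    write_phase_png(result$correction, emit("correction_mask.png"),
                    metadata = list(algorithm = result$trace$algorithm,
                                    seed = result$trace$seed))
    written <- c(written, "correction_mask.png.json")
    meta$algorithm <- result$trace$algorithm
    meta$final_eta <- result$trace$eta[length(result$trace$eta)]
  } else if (inherits(result, "benchmark_result")) {
    utils::write.csv(result$summary, emit("benchmark_summary.csv"),
                     row.names = FALSE)
    tidy <- do.call(rbind, lapply(unlist(result$traces,
                                         recursive = FALSE),
                                  as.data.frame))
    utils::write.csv(tidy, emit("benchmark_traces.csv"),
                     row.names = FALSE)
    meta$trials <- result$trials
    meta$scatterer_seeds <- result$scatterer_seeds
    meta$scatterer_hashes <- result$scatterer_hashes
  } else if (!is.null(result)) {
    stop("unsupported result class: ", paste(class(result), collapse = "/"),
         call. = FALSE)
  }
  jsonlite::write_json(meta, emit("metadata.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- file.path(out_dir, written)
  manifest <- data.frame(file = written,
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
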