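#' Write a thickness map as 16-bit PNG plus JSON sidecar
#'
#' Thickness in micrometers is stored as `round(um * 10)` in a 16-bit
#' grayscale PNG (resolution 0.1 um, range 0-6553.5 um); landmarks,
#' laterality, visit keys, and the pixel pitch go to a `.json` sidecar
#' next to the image. `NA` pixels are stored as the maximum code and
#' restored on read.
#'
#' @param map an [rnfl_map()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path) {
  stopifnot(inherits(map, "rnfl_map"), grepl("\\.png$", path))
  v <- map$values
  code <- round(v * 10)
  if (any(code > 65534, na.rm = TRUE))
    stop("write_map_png: thickness exceeds the 16-bit range")
  code[is.na(code)] <- 65535
  # 16-bit codes stored as two 8-bit planes (high byte, low byte)
  img <- array(0, c(nrow(code), ncol(code), 2L))
  img[, , 1L] <- (code %/% 256L) / 255
  img[, , 2L] <- (code %% 256L) / 255
  png::writePNG(img, target = path)
  meta <- list(laterality = map$laterality, orientation = map$orientation,
               fovea = map$fovea, onh = map$onh, mm_per_px = map$mm_per_px,
               participant_id = map$participant_id, eye_id = map$eye_id,
               visit_month = map$visit_month, units = "0.1um",
               na_code = 65535)
  jsonlite::write_json(meta, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a thickness map written by [write_map_png()]
#'
#' @param path path to the `.png` file (sidecar `.json` must sit next to it).
#' @return An [rnfl_map()].
#' @export
read_map_png <- function(path) {
  meta <- jsonlite::read_json(sub("\\.png$", ".json", path),
                              simplifyVector = TRUE)
  img <- png::readPNG(path)
  if (length(dim(img)) != 3L || dim(img)[3L] < 2L)
    stop("read_map_png: expected a two-plane thickness image")
  code <- round(img[, , 1L] * 255) * 256L + round(img[, , 2L] * 255)
  v <- code / 10
  v[code == meta$na_code] <- NA_real_
  rnfl_map(values = v, laterality = meta$laterality,
           fovea = meta$fovea, onh = meta$onh, mm_per_px = meta$mm_per_px,
           participant_id = meta$participant_id %||% NA_character_,
           eye_id = meta$eye_id %||% NA_character_,
           visit_month = meta$visit_month %||% NA_real_,
           orientation = meta$orientation %||% meta$laterality)
}

#' Write a cohort to disk as CSV metadata plus PNG maps
#'
#' @param cohort an `rnfl_cohort`.
#' @param dir output directory (created if needed); maps go under
#'   `dir/maps/`.
#' @return The metadata CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rnfl_cohort"))
  map_dir <- file.path(dir, "maps")
  dir.create(map_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$meta
  meta$map_path <- file.path("maps", paste0(meta$scan_id, ".png"))
  for (i in seq_len(nrow(meta)))
    write_map_png(cohort$maps[[meta$scan_id[i]]],
                  file.path(dir, meta$map_path[i]))
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(meta, csv, row.names = FALSE)
  invisible(csv)
}

#' Read a cohort from a metadata CSV plus PNG maps
#'
#' The CSV must carry the columns produced by [write_cohort()]
#' (`scan_id`, `participant_id`, `eye_id`, `laterality`, `group`, `age`,
#' `sex`, `visit_month`, functional and structural scalars, `map_path`
#' relative to the CSV).
#'
#' @param csv path to the metadata CSV.
#' @param config optional [cohort_config()] describing the grid (used for
#'   canonical landmark placement downstream); inferred defaults are used
#'   when `NULL`.
#' @return An `rnfl_cohort`.
#' @export
read_cohort <- function(csv, config = NULL) {
  meta <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("scan_id", "participant_id", "eye_id", "laterality", "group",
            "age", "visit_month", "mean_cprnflt", "map_path")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0L)
    stop("read_cohort: metadata is missing columns: ",
         paste(missing_cols, collapse = ", "))
  base <- dirname(csv)
  maps <- lapply(meta$map_path, function(p) read_map_png(file.path(base, p)))
  names(maps) <- meta$scan_id
  structure(list(meta = meta[setdiff(names(meta), "map_path")],
                 maps = maps, config = config),
            class = "rnfl_cohort")
}

#' Read a cohort configuration from YAML
#'
#' All fields of [cohort_config()] may appear; unknown fields are an
#' error, and `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L)
    stop("read_config_yaml: unknown config fields: ",
         paste(unknown, collapse = ", "))
  for (nm in c("age_mean", "age_sd", "pattern_weights", "eye_totals"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$field_mm)) y$field_mm <- as.numeric(unlist(y$field_mm))
  do.call(cohort_config, y)
}

#' Write a cohort configuration to YAML
#'
#' @param config a [cohort_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  keep <- intersect(names(formals(cohort_config)), names(config))
  out <- lapply(config[keep], function(v) {
    # named vectors become YAML maps so the names survive a round trip
    if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
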