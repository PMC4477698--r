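# Core-top database schema: canonical column names and per-row validation.
# The archive's exact headers vary between deposits, so the reader accepts a
# dialect mapping from canonical names to whatever the file uses.

CORETOP_COLUMNS <- c(
  "core_id", "core_type", "lat", "lon", "water_depth_m", "sample_depth_cm",
  "tex86", "f_gdgt0", "f_gdgt1", "f_gdgt2", "f_gdgt3", "f_cren",
  "f_cren_prime", "sst_woa_C", "subT_gamma_C", "sst_oisst_C",
  "reference", "doi"
)
CORETOP_CHARACTER <- c("core_id", "core_type", "reference", "doi")
CORETOP_REQUIRED <- c("core_id", "lat", "lon", "tex86")

#' Canonical core-top schema columns
#'
#' @return character vector of the canonical column names for surface
#'   sediment (core-top) records: core identity and type, geospatial
#'   information, sampling depths, TEX86, optional GDGT fractional
#'   abundances, matched surface and gamma-weighted subsurface
#'   temperatures, and reference metadata.
#' @export
coretop_schema <- function() CORETOP_COLUMNS

empty_coretop <- function(n = 0L) {
  out <- lapply(CORETOP_COLUMNS, function(cn) {
    if (cn %in% CORETOP_CHARACTER) rep(NA_character_, n) else rep(NA_real_, n)
  })
  names(out) <- CORETOP_COLUMNS
  structure(as.data.frame(out, stringsAsFactors = FALSE),
            class = c("coretop_records", "data.frame"))
}

validate_coretop_row <- function(row, tex_tol = 0.01) {
  # returns NULL if valid, else a reason string; may attach a warning message
  if (is.na(row$core_id) || !nzchar(row$core_id)) return("missing core_id")
  if (is.na(row$lat) || row$lat < -90 || row$lat > 90) return("latitude out of range [-90, 90]")
  if (is.na(row$lon)) return("missing or unparseable longitude")
  if (is.na(row$tex86)) return("missing tex86")
  if (row$tex86 < 0 || row$tex86 > 1) return("tex86 out of range [0,1]")
  if (!is.na(row$water_depth_m) && row$water_depth_m < 0) return("negative water depth")
  if (!is.na(row$sample_depth_cm) && row$sample_depth_cm < 0) return("negative sample depth")
  fr <- unlist(row[c("f_gdgt0", "f_gdgt1", "f_gdgt2", "f_gdgt3", "f_cren", "f_cren_prime")])
  if (any(!is.na(fr) & (fr < 0 | fr > 1))) return("GDGT fraction out of [0,1]")
  if (all(!is.na(fr)) && abs(sum(fr) - 1) > 0.02) return("GDGT fractions do not sum to 1")
  NULL
}

#' Read a core-top database table
#'
#' Reads a delimited-text (CSV or TSV) table of surface-sediment TEX86
#' records into the canonical schema (see [coretop_schema()]). Every row
#' becomes a validated record or is routed to a rejects report with a
#' reason; input ordering is preserved. Missing values may be empty fields
#' or the literal string `"NaN"`/`"NA"`. Longitudes are normalized to
#' `[-180, 180)` on ingest. When GDGT fractions are present, the TEX86
#' recomputed from them is compared to the stored value; a mismatch beyond
#' `tex_tol` raises a warning but keeps the stored (archived) value.
#' Duplicate `(core_id, sample_depth_cm)` keys are rejected after the first
#' occurrence.
#'
#' @param path path to a delimited text file. `.tsv`/`.txt` extensions are
#'   read tab-separated, anything else comma-separated; override with `sep`.
#' @param dialect optional column mapping adapting arbitrary headers to the
#'   canonical fields: a named character vector / list
#'   (`c(lat = "Latitude", ...)`, canonical name -> file header) or the path
#'   to a JSON file containing such a mapping. Unmapped canonical columns
#'   must then appear under their canonical names to be used.
#' @param sep field separator; default inferred from the file extension.
#' @param tex_tol tolerance for the stored-vs-recomputed TEX86 check.
#' @return a list with elements `records` (a `coretop_records` data.frame)
#'   and `rejects` (data.frame with columns `row`, `reason`).
#' @export
read_coretop_table <- function(path, dialect = NULL, sep = NULL, tex_tol = 0.01) {
  if (!file.exists(path)) stopf("read_coretop_table: file not found: %s", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA", "NaN"), comment.char = "",
                           colClasses = "character")
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect)) {
    dialect <- unlist(jsonlite::read_json(dialect, simplifyVector = TRUE))
  }
  dialect <- unlist(dialect)
  # resolve each canonical column to a source column, if available
  src <- names(raw)
  col_of <- function(canon) {
    if (!is.null(dialect) && canon %in% names(dialect)) {
      header <- dialect[[canon]]
      if (!header %in% src) stopf("read_coretop_table: dialect maps '%s' to missing column '%s'", canon, header)
      return(header)
    }
    if (canon %in% src) canon else NA_character_
  }
  resolved <- vapply(CORETOP_COLUMNS, col_of, character(1))
  missing_req <- CORETOP_REQUIRED[is.na(resolved[CORETOP_REQUIRED])]
  if (length(missing_req)) {
    stopf("read_coretop_table: required columns not mappable: %s",
          paste(missing_req, collapse = ", "))
  }

  n <- nrow(raw)
  rec <- empty_coretop(n)
  for (canon in CORETOP_COLUMNS) {
    if (is.na(resolved[[canon]])) next
    v <- raw[[resolved[[canon]]]]
    if (canon %in% CORETOP_CHARACTER) {
      rec[[canon]] <- as.character(v)
    } else {
      rec[[canon]] <- suppressWarnings(as.numeric(v))
      # remember rows where a value was present but unparseable
      attr(rec, paste0("unparseable_", canon)) <- which(!is.na(v) & is.na(rec[[canon]]))
    }
  }
  rec$lon <- ifelse(is.na(rec$lon), NA_real_, normalize_lon(rec$lon))

  reasons <- character(n)
  for (i in seq_len(n)) {
    for (canon in c("lat", "lon", "tex86")) {
      up <- attr(rec, paste0("unparseable_", canon))
      if (i %in% up) { reasons[i] <- sprintf("unparseable %s", canon); break }
    }
    if (!nzchar(reasons[i])) {
      r <- validate_coretop_row(rec[i, , drop = FALSE], tex_tol = tex_tol)
      if (!is.null(r)) reasons[i] <- r
    }
  }
  # duplicate (core_id, sample_depth_cm) keys: keep first occurrence
  key <- paste(rec$core_id, rec$sample_depth_cm, sep = "\r")
  ok_so_far <- !nzchar(reasons)
  dup <- duplicated(ifelse(ok_so_far, key, paste0(key, "\r", seq_len(n))))
  reasons[dup & ok_so_far] <- "duplicate (core_id, sample_depth_cm)"

  keep <- !nzchar(reasons)
  records <- rec[keep, , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("coretop_records", "data.frame")

  # stored-vs-recomputed TEX86 consistency: warn, keep the archived value
  fr_ok <- stats::complete.cases(records[, c("f_gdgt1", "f_gdgt2", "f_gdgt3", "f_cren_prime")])
  if (any(fr_ok)) {
    recomp <- compute_tex86(records$f_gdgt1[fr_ok], records$f_gdgt2[fr_ok],
                            records$f_gdgt3[fr_ok], records$f_cren_prime[fr_ok])
    off <- abs(recomp - records$tex86[fr_ok]) > tex_tol
    if (any(off)) {
      warnf("read_coretop_table: %d record(s) with stored TEX86 differing from value recomputed from fractions by > %g; stored values kept",
            sum(off), tex_tol)
    }
  }
  rejects <- data.frame(row = which(!keep), reason = reasons[!keep],
                        stringsAsFactors = FALSE)
  list(records = records, rejects = rejects)
}

#' Write core-top records to a delimited-text table
#'
#' Inverse of [read_coretop_table()]: writes the canonical columns with
#' empty fields for missing values, so a written table re-reads to
#' identical records.
#'
#' @param records a `coretop_records` data.frame.
#' @param path output path; `.tsv` writes tab-separated, else CSV.
#' @return `path`, invisibly.
#' @export
write_coretop_table <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  out <- records[, CORETOP_COLUMNS, drop = FALSE]
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "")
  invisible(path)
}

#' Write a rejects report
#'
#' @param rejects data.frame with columns `row` and `reason`, as returned by
#'   [read_coretop_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rejects_report <- function(rejects, path) {
  utils::write.csv(rejects, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a calibration dataset from core-top records
#'
#' Filters records to those usable for calibration and aligns the model
#' vectors: `P` (TEX86 observations), `C_diag` (target temperatures, the
#' diagonal of the C matrix) and the per-record grid-box assignment that
#' defines the selection matrix M. Records north of `lat_cutoff_deg` are
#' excluded (strictly: `lat > cutoff` is dropped, a site exactly at the
#' cutoff is retained), reflecting the weak TEX86-temperature relationship
#' in the Arctic. Records missing the requested target temperature are
#' dropped and counted.
#'
#' @param records a `coretop_records` data.frame.
#' @param target_kind `"SST"` (surface, column `sst_woa_C` by default) or
#'   `"SubT"` (gamma-weighted 0-200 m subsurface, column `subT_gamma_C`).
#' @param lat_cutoff_deg high-latitude exclusion cutoff in degrees north
#'   (default 70).
#' @param grid a [grid_spec()] defining the 20x20 degree boxes.
#' @param sst_column which archived SST column feeds the SST calibration
#'   (`"sst_woa_C"` default, or `"sst_oisst_C"`).
#' @return object of class `calibration_dataset`: list with `records`,
#'   `target_kind`, `P`, `C_diag`, `box_index` (index into `active_boxes`),
#'   `active_boxes` (global box ids containing >= 1 datum), `grid`, and
#'   `n_dropped_lat` / `n_dropped_target` bookkeeping.
#' @export
build_calibration_dataset <- function(records, target_kind = c("SST", "SubT"),
                                      lat_cutoff_deg = 70, grid = grid_spec(),
                                      sst_column = c("sst_woa_C", "sst_oisst_C")) {
  target_kind <- match.arg(target_kind)
  sst_column <- match.arg(sst_column)
  target_col <- if (target_kind == "SST") sst_column else "subT_gamma_C"

  north <- records$lat > lat_cutoff_deg
  n_dropped_lat <- sum(north)
  kept <- records[!north, , drop = FALSE]
  has_target <- !is.na(kept[[target_col]])
  n_dropped_target <- sum(!has_target)
  kept <- kept[has_target, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stopf("build_calibration_dataset: no records remain after the %g degN cutoff and missing-target filtering", lat_cutoff_deg)
  }
  rownames(kept) <- NULL

  global_box <- assign_grid_box(kept$lat, kept$lon, grid)
  stopifnot(!anyNA(global_box))
  active_boxes <- sort(unique(global_box))
  box_index <- match(global_box, active_boxes)

  structure(list(
    records = kept,
    target_kind = target_kind,
    P = kept$tex86,
    C_diag = kept[[target_col]],
    box_index = box_index,
    active_boxes = active_boxes,
    grid = grid,
    lat_cutoff_deg = lat_cutoff_deg,
    n_dropped_lat = n_dropped_lat,
    n_dropped_target = n_dropped_target
  ), class = "calibration_dataset")
}

#' @export
print.calibration_dataset <- function(x, ...) {
  cat(sprintf("calibration_dataset: %d records, target %s, %d active 20x20 deg boxes\n",
              length(x$P), x$target_kind, length(x$active_boxes)))
  cat(sprintf("  dropped: %d north of %g degN, %d missing target\n",
              x$n_dropped_lat, x$lat_cutoff_deg, x$n_dropped_target))
  invisible(x)
}

#' Fraction of TEX86 variance explained by the calibration target
#'
#' Squared Pearson correlation between TEX86 observations and the target
#' temperatures; the headline goodness-of-fit summary for a calibration
#' dataset.
#'
#' @param P TEX86 observations.
#' @param C_diag target temperatures (degrees C), same length.
#' @return fraction in `[0, 1]`.
#' @export
variance_explained <- function(P, C_diag) {
  if (length(P) != length(C_diag)) stopf("variance_explained: length mismatch")
  if (length(P) < 3L) stopf("variance_explained: need at least 3 observations")
  if (stats::sd(P) == 0 || stats::sd(C_diag) == 0) {
    stopf("variance_explained: undefined for constant input")
  }
  stats::cor(P, C_diag)^2
}

#' Spearman trend of calibration residuals against latitude
#'
#' A diagnostic for residual spatial structure: the rank correlation of
#' model residuals with site latitude and its two-sided significance. A
#' near-zero rho indicates the spatially-varying coefficients have absorbed
#' the latitudinal trend that plagues single-slope calibrations.
#'
#' @param residuals numeric vector of calibration residuals.
#' @param lats site latitudes, same length (>= 10).
#' @return list with `rho` and `p_value`.
#' @export
residual_latitude_trend <- function(residuals, lats) {
  if (length(residuals) != length(lats)) stopf("residual_latitude_trend: length mismatch")
  if (length(residuals) < 10L) stopf("residual_latitude_trend: need at least 10 points")
  if (length(unique(residuals)) == 1L || length(unique(lats)) == 1L) {
    stopf("residual_latitude_trend: degenerate (constant) input")
  }
  ct <- suppressWarnings(stats::cor.test(residuals, lats, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
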