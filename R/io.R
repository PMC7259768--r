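# CSV schemas (exact headers):
#   sessions.csv : session_id, patient_id, sex, age_yr, height_cm, modality,
#                  duration_min, uf_l, bw_post_kg, delivered_dialysate_l,
#                  sessions_per_week
#   blood.csv    : session_id, time_min, role, solute, conc, unit,
#                  total_protein_g_dl
#   dialysate.csv: session_id, kind, index_or_time, solute, conc, unit,
#                  volume_l

.schema <- list(
  sessions = c("session_id", "patient_id", "sex", "age_yr", "height_cm",
               "modality", "duration_min", "uf_l", "bw_post_kg",
               "delivered_dialysate_l", "sessions_per_week"),
  blood = c("session_id", "time_min", "role", "solute", "conc", "unit",
            "total_protein_g_dl"),
  dialysate = c("session_id", "kind", "index_or_time", "solute", "conc",
                "unit", "volume_l")
)

.read_schema_csv <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.schema[[what]], names(df))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), "; expected headers: ",
         paste(.schema[[what]], collapse = ", "))
  }
  df
}

# Atomic write: write to a temporary file in the target directory, then
# rename over the destination.
.atomic_write_csv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read session records from the three-file CSV schema
#'
#' Parses `sessions.csv`, `blood.csv` and `dialysate.csv` into typed
#' [kt_session] records with unit conversion applied.  Validation
#' findings (from [validate_session()]) are attached to each record as
#' the `"findings"` attribute rather than raised.
#'
#' @param sessions_csv,blood_csv,dialysate_csv File paths.
#' @param metrics Metric families to validate for (see
#'   [validate_session()]).
#' @return Named list of [kt_session] records.
#' @export
read_sessions <- function(sessions_csv, blood_csv, dialysate_csv,
                          metrics = c("balance", "instant")) {
  ses <- .read_schema_csv(sessions_csv, "sessions")
  blood <- .read_schema_csv(blood_csv, "blood")
  dial <- .read_schema_csv(dialysate_csv, "dialysate")
  if (anyDuplicated(ses$session_id)) {
    stop("duplicate session ids in ", sessions_csv, ": ",
         paste(unique(ses$session_id[duplicated(ses$session_id)]), collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(ses))) {
    row <- ses[i, ]
    pat <- if (!is.na(row$patient_id) && nzchar(row$patient_id)) {
      kt_patient(row$patient_id, row$sex, row$age_yr, row$height_cm,
                 row$bw_post_kg + row$uf_l)
    } else NULL
    b <- blood[blood$session_id == row$session_id,
               setdiff(names(blood), "session_id"), drop = FALSE]
    d <- dial[dial$session_id == row$session_id,
              setdiff(names(dial), "session_id"), drop = FALSE]
    rec <- kt_session(id = row$session_id, patient = pat,
                      modality = row$modality,
                      duration_min = row$duration_min, uf_l = row$uf_l,
                      bw_post_kg = row$bw_post_kg,
                      delivered_dialysate_l = row$delivered_dialysate_l,
                      sessions_per_week = row$sessions_per_week,
                      blood = b, dialysate = d)
    attr(rec, "findings") <- validate_session(rec, metrics = metrics)
    out[[row$session_id]] <- rec
  }
  out
}

#' Write session records to the three-file CSV schema
#'
#' Inverse of [read_sessions()]; writes are atomic (write-then-rename).
#' Concentrations are written in each solute's default unit.
#'
#' @param records List of [kt_session] records.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sessions <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ses <- do.call(rbind, lapply(records, function(r) {
    p <- r$patient
    data.frame(session_id = r$id,
               patient_id = if (is.null(p)) "" else p$id,
               sex = if (is.null(p)) "" else p$sex,
               age_yr = if (is.null(p)) NA_real_ else p$age_yr,
               height_cm = if (is.null(p)) NA_real_ else p$height_cm,
               modality = r$modality, duration_min = r$duration_min,
               uf_l = r$uf_l, bw_post_kg = r$bw_post_kg,
               delivered_dialysate_l = r$delivered_dialysate_l,
               sessions_per_week = r$sessions_per_week,
               stringsAsFactors = FALSE)
  }))
  to_default_unit <- function(conc_mg_l, solute) {
    u <- vapply(solute, function(s) solute_info(s)$default_unit, "")
    list(conc = conc_mg_l / ifelse(u == "mg/dl", 10, 1), unit = u)
  }
  blood <- do.call(rbind, lapply(records, function(r) {
    b <- r$blood
    cv <- to_default_unit(b$conc_mg_l, b$solute)
    data.frame(session_id = r$id, time_min = b$time_min, role = b$role,
               solute = b$solute, conc = cv$conc, unit = cv$unit,
               total_protein_g_dl = b$total_protein_g_dl,
               stringsAsFactors = FALSE)
  }))
  dial <- do.call(rbind, lapply(records, function(r) {
    d <- r$dialysate
    cv <- to_default_unit(d$conc_mg_l, d$solute)
    data.frame(session_id = r$id, kind = d$kind,
               index_or_time = d$index_or_time, solute = d$solute,
               conc = cv$conc, unit = cv$unit, volume_l = d$volume_l,
               stringsAsFactors = FALSE)
  }))
  paths <- file.path(dir, c("sessions.csv", "blood.csv", "dialysate.csv"))
  .atomic_write_csv(ses, paths[1])
  .atomic_write_csv(blood, paths[2])
  .atomic_write_csv(dial, paths[3])
  invisible(paths)
}

#' Write ground-truth rows for a simulated cohort
#'
#' One row per session x solute with the simulator's noiseless
#' reference quantities.
#'
#' @param cohort Output of [generate_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(cohort, path) {
  tr <- do.call(rbind, lapply(cohort, function(s) {
    cbind(session_id = s$record$id, s$truth$solutes)
  }))
  rownames(tr) <- NULL
  .atomic_write_csv(tr, path)
}

#' Read a deposited per-session study spreadsheet
#'
#' Best-effort ingestion of an external study table (XLS/XLSX via the
#' `readxl` package when installed, or a CSV export) using a
#' user-supplied column mapping, since the internal layout of deposited
#' datasets varies.  Unmapped required columns are reported in the
#' `"unmapped"` attribute, not raised.
#'
#' @param path Spreadsheet (`.xls`/`.xlsx`) or CSV file.
#' @param mapping Named character vector `c(source_column = target_name)`
#'   renaming source columns to package names; `NULL` keeps names as-is.
#' @param required Target column names expected after mapping.
#' @return Data frame of per-session rows; duplicate `session_id`s (if
#'   that column exists) raise an error.
#' @export
read_study_xls <- function(path, mapping = NULL,
                           required = c("session_id", "modality")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(xls|xlsx)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xls/.xlsx needs the 'readxl' package; export to CSV instead")
    }
    df <- as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty study table: ", path)
    return(df)
  }
  if (!is.null(mapping)) {
    hit <- names(df) %in% names(mapping)
    names(df)[hit] <- unname(mapping[names(df)[hit]])
  }
  unmapped <- setdiff(required, names(df))
  if (length(unmapped)) {
    warning("unavailable metric column(s) after mapping: ",
            paste(unmapped, collapse = ", "))
  }
  if ("session_id" %in% names(df) && anyDuplicated(df$session_id)) {
    stop("duplicate session ids in study table")
  }
  attr(df, "unmapped") <- unmapped
  df
}

#' Write a cohort report to CSV
#'
#' Serializes the `summary` component of a [build_report()] result as a
#' wide CSV: one row per (arm, solute, metric) with mean/sd/n, plus the
#' paired-test p value where that metric has an instant-vs-balance
#' comparison.
#'
#' @param report A `cohort_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  s <- report$summary
  s$p_paired <- NA_real_
  if (!is.null(report$paired)) {
    for (i in seq_len(nrow(report$paired))) {
      pr <- report$paired[i, ]
      lead <- sub(" vs .*", "", pr$comparison)
      hit <- s$arm == pr$arm & s$solute == pr$solute & s$metric == lead
      s$p_paired[hit] <- pr$p
    }
  }
  .atomic_write_csv(s, path)
}
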