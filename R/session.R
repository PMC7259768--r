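#' Patient descriptor
#'
#' Anthropometric data needed by the Watson total-body-water formula and
#' the short-daily (NSO) dialysate prescription.
#'
#' @param id Opaque identifier.
#' @param sex `"male"` or `"female"`.
#' @param age_yr Age in years (> 0).
#' @param height_cm Height, cm (100--230).
#' @param weight_kg Pre-dialysis body weight, kg (25--250).
#' @return An object of class `kt_patient`.
#' @export
kt_patient <- function(id, sex, age_yr, height_cm, weight_kg) {
  sex <- match.arg(tolower(sex), c("male", "female"))
  structure(list(id = as.character(id), sex = sex, age_yr = age_yr,
                 height_cm = height_cm, weight_kg = weight_kg),
            class = "kt_patient")
}

#' Dialysis modalities
#'
#' Treatment arms: low-flux and high-flux bicarbonate hemodialysis,
#' post-dilution hemodiafiltration, and short-daily low-dialysate-volume
#' hemodialysis (NxStage System One).
#' @export
kt_modalities <- c("BHD_lf", "BHD_hf", "HDF", "NSO")

#' Assemble a dialysis session record
#'
#' Bundles prescription data, timed blood samples and dialysate samples
#' (whole-collection bags and/or instant draws) for one treatment.
#' Concentrations are converted to mg/L internally.
#'
#' Blood samples are given as a data frame with columns `time_min`,
#' `role` (`"pre"`, `"post"` or `"instant"`), `solute`, `conc`, `unit`
#' and `total_protein_g_dl`.  Dialysate samples have columns `kind`
#' (`"bag"` or `"instant"`), `index_or_time` (bag ordinal or minutes),
#' `solute`, `conc`, `unit`, `volume_l` (bags only; `NA` for instants).
#'
#' The time convention is minutes from blood-pump start: the pre sample
#' is at t = 0 and the end-of-session sample (drawn after the 5-min
#' low-flow period) is timestamped `duration_min`.
#'
#' @param id Session identifier.
#' @param patient A [kt_patient] (or `NULL` when anthropometrics are not
#'   needed).
#' @param modality One of [kt_modalities].
#' @param duration_min Session length, minutes.
#' @param uf_l Total ultrafiltration (dialytic weight loss), liters.
#' @param bw_post_kg Post-dialysis body weight, kg.
#' @param delivered_dialysate_l Monitor-reported delivered dialysate,
#'   liters (excluding UF); `NA` if unavailable.
#' @param sessions_per_week Treatments per week (1--7).
#' @param blood,dialysate Sample data frames as described above.
#' @return An object of class `kt_session`.
#' @seealso [validate_session()], [session_metrics()]
#' @export
kt_session <- function(id, patient = NULL, modality, duration_min, uf_l,
                       bw_post_kg, delivered_dialysate_l = NA_real_,
                       sessions_per_week, blood, dialysate) {
  modality <- match.arg(modality, kt_modalities)
  blood <- as.data.frame(blood, stringsAsFactors = FALSE)
  dialysate <- as.data.frame(dialysate, stringsAsFactors = FALSE)
  if (is.null(blood$unit)) {
    blood$unit <- vapply(blood$solute, function(s) solute_info(s)$default_unit, "")
  }
  if (nrow(dialysate) && is.null(dialysate$unit)) {
    dialysate$unit <- vapply(dialysate$solute, function(s) solute_info(s)$default_unit, "")
  }
  blood$conc_mg_l <- conc_to_mg_l(blood$conc, blood$unit)
  if (nrow(dialysate)) {
    dialysate$conc_mg_l <- conc_to_mg_l(dialysate$conc, dialysate$unit)
  } else {
    dialysate <- data.frame(kind = character(), index_or_time = numeric(),
                            solute = character(), conc = numeric(),
                            unit = character(), volume_l = numeric(),
                            conc_mg_l = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(dialysate$volume_l)) dialysate$volume_l <- NA_real_
  structure(list(id = as.character(id), patient = patient,
                 modality = modality, duration_min = duration_min,
                 uf_l = uf_l, bw_post_kg = bw_post_kg,
                 delivered_dialysate_l = delivered_dialysate_l,
                 sessions_per_week = as.integer(sessions_per_week),
                 blood = blood, dialysate = dialysate),
            class = "kt_session")
}

#' @export
print.kt_session <- function(x, ...) {
  cat(sprintf("<kt_session %s> %s, %g min, UF %g L, %d/week\n", x$id,
              x$modality, x$duration_min, x$uf_l, x$sessions_per_week))
  cat(sprintf("  blood samples: %d; dialysate samples: %d (%d bags)\n",
              nrow(x$blood), nrow(x$dialysate),
              sum(x$dialysate$kind == "bag")))
  invisible(x)
}

.finding <- function(severity, field, message) {
  data.frame(severity = severity, field = field, message = message,
             stringsAsFactors = FALSE)
}

.no_findings <- function() {
  data.frame(severity = character(), field = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate a session record
#'
#' Checks type invariants and, per solute, that the samples required for
#' the requested metric families exist: balance metrics need a pre and a
#' post blood sample; instant metrics need at least one simultaneous
#' instant blood + dialysate pair.  Findings are returned as data, not
#' raised: each row carries a severity (`"error"` or `"warning"`), the
#' offending field path and a message.  An empty data frame means the
#' record is fully usable for the requested metrics.  A sample set
#' missing for a metric family that was *not* requested is reported as a
#' warning only.
#'
#' @param record A [kt_session].
#' @param metrics Metric families the caller intends to compute; any of
#'   `"balance"`, `"instant"`.
#' @param solutes Solutes to check; defaults to those present in the
#'   blood samples.
#' @return Data frame with columns `severity`, `field`, `message`.
#' @export
validate_session <- function(record, metrics = c("balance", "instant"),
                             solutes = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  f <- .no_findings()
  chk <- function(cond, severity, field, message) {
    if (!isTRUE(cond)) f <<- rbind(f, .finding(severity, field, message))
  }
  chk(record$duration_min > 0, "error", "duration_min", "duration_min must be > 0")
  chk(record$uf_l >= 0, "error", "uf_l", "uf_l must be >= 0")
  chk(record$sessions_per_week %in% 1:7, "error", "sessions_per_week",
      "sessions_per_week must be in 1..7")
  chk(is.na(record$bw_post_kg) || record$bw_post_kg > 0, "error",
      "bw_post_kg", "bw_post_kg must be > 0")
  p <- record$patient
  if (!is.null(p)) {
    chk(p$age_yr > 0, "error", "patient.age_yr", "age_yr must be > 0")
    chk(p$height_cm >= 100 && p$height_cm <= 230, "error",
        "patient.height_cm", "height_cm must be in [100, 230]")
    chk(p$weight_kg >= 25 && p$weight_kg <= 250, "error",
        "patient.weight_kg", "weight_kg must be in [25, 250]")
  }
  b <- record$blood
  for (i in seq_len(nrow(b))) {
    chk(b$conc_mg_l[i] > 0, "error", sprintf("blood[%d].conc", i),
        "blood concentration must be > 0")
    tp <- b$total_protein_g_dl[i]
    chk(is.na(tp) || (tp >= 0 && tp <= 12), "error",
        sprintf("blood[%d].total_protein_g_dl", i),
        "total protein must be in [0, 12] g/dl")
    chk(b$time_min[i] >= 0, "error", sprintf("blood[%d].time_min", i),
        "sample time must be >= 0")
  }
  d <- record$dialysate
  for (i in seq_len(nrow(d))) {
    chk(d$conc_mg_l[i] >= 0, "error", sprintf("dialysate[%d].conc", i),
        "dialysate concentration must be >= 0")
    if (d$kind[i] == "bag") {
      chk(!is.na(d$volume_l[i]) && d$volume_l[i] > 0, "error",
          sprintf("dialysate[%d].volume_l", i), "bag volume must be > 0")
    } else {
      chk(is.na(d$volume_l[i]), "warning",
          sprintf("dialysate[%d].volume_l", i),
          "instant dialysate samples carry no volume; value ignored")
    }
  }
  sol <- solutes
  if (is.null(sol)) sol <- unique(b$solute)
  for (s in sol) {
    bs <- b[b$solute == s, ]
    ds <- d[d$solute == s, ]
    has_pre <- any(bs$role == "pre")
    has_post <- any(bs$role == "post")
    inst_b <- bs[bs$role == "instant", ]
    inst_d <- ds[ds$kind == "instant", ]
    paired <- length(intersect(inst_b$time_min, inst_d$index_or_time)) > 0
    sev_bal <- if ("balance" %in% metrics) "error" else "warning"
    sev_inst <- if ("instant" %in% metrics) "error" else "warning"
    if (!has_pre || !has_post) {
      chk(FALSE, sev_bal, sprintf("blood[%s]", s),
          "balance metrics unavailable: need pre and post blood samples")
    }
    if ("balance" %in% metrics && nrow(ds[ds$kind == "bag", ]) == 0) {
      chk(FALSE, "error", sprintf("dialysate[%s]", s),
          "balance metrics unavailable: no dialysate bags")
    }
    if (!paired) {
      chk(FALSE, sev_inst, sprintf("instant[%s]", s),
          "instant metrics unavailable: need a simultaneous instant blood + dialysate pair")
    }
  }
  rownames(f) <- NULL
  f
}
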