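#' Effluent dialysate volume
#'
#' Total spent-dialysate volume as indicated by dialysis monitors:
#' delivered dialysate plus ultrafiltration.
#'
#' @param delivered_dialysate_l Delivered dialysate, liters (>= 0).
#' @param uf_l Ultrafiltration, liters (>= 0).
#' @return Effluent volume, liters.
#' @export
effluent_volume <- function(delivered_dialysate_l, uf_l) {
  stopifnot(delivered_dialysate_l >= 0, uf_l >= 0)
  delivered_dialysate_l + uf_l
}

#' Solute mass recovered in collected dialysate bags
#'
#' Whole-collection mass balance: the quantity of solute in spent
#' dialysate is the sum over bags of concentration times bag volume.
#'
#' @param conc_mg_l Bag concentrations, mg/L.
#' @param volume_l Bag volumes, liters (from weighed mass at density
#'   1.000 kg/L).
#' @return List with `q_mg` (total mass, mg) and `volume_l` (total
#'   measured volume, liters).
#' @export
q_from_bags <- function(conc_mg_l, volume_l) {
  if (length(conc_mg_l) == 0) stop("no dialysate bags")
  stopifnot(length(conc_mg_l) == length(volume_l), volume_l > 0, conc_mg_l >= 0)
  list(q_mg = sum(conc_mg_l * volume_l), volume_l = sum(volume_l))
}

#' Instant dialysate-to-plasma ratio
#'
#' D/P from a simultaneous mid-session dialysate and plasma-water pair.
#'
#' @param dialysate_conc_mg_l Dialysate concentration, mg/L (>= 0).
#' @param plasma_pw_mg_l Plasma-water concentration, mg/L (> 0).
#' @return D/P ratio (dimensionless, typically <= 1).
#' @export
dp_instant <- function(dialysate_conc_mg_l, plasma_pw_mg_l) {
  if (any(plasma_pw_mg_l <= 0)) stop("plasma concentration must be > 0")
  dialysate_conc_mg_l / plasma_pw_mg_l
}

#' Whole-study mean dialysate-to-plasma ratio
#'
#' Mean study D/P: mean spent-dialysate concentration (total recovered
#' mass over total measured volume) divided by the balance TAC.
#'
#' @param q_bal_mg Recovered mass, mg.
#' @param total_volume_l Total dialysate volume, liters (> 0).
#' @param tac_bal_mg_l Balance TAC, mg/L (> 0).
#' @return D/P ratio.
#' @export
dp_balance <- function(q_bal_mg, total_volume_l, tac_bal_mg_l) {
  if (any(total_volume_l <= 0) || any(tac_bal_mg_l <= 0)) {
    stop("volume and TAC must be > 0")
  }
  (q_bal_mg / total_volume_l) / tac_bal_mg_l
}

#' Session Kt from whole-dialysate balance
#'
#' The central metric: Kt, the volume of plasma totally cleared of a
#' solute during one session, measured as recovered dialysate mass over
#' the time-averaged plasma-water concentration.
#'
#' @param q_bal_mg Recovered solute mass, mg.
#' @param tac_bal_mg_l Balance TAC, mg/L (> 0).
#' @return Kt, liters per session.
#' @export
kt_balance <- function(q_bal_mg, tac_bal_mg_l) {
  if (any(tac_bal_mg_l <= 0)) stop("TAC must be > 0")
  q_bal_mg / tac_bal_mg_l
}

#' Session Kt from instant D/P sampling
#'
#' The instant estimate that avoids whole-dialysate collection: mean
#' instant D/P (a single 60-min value in short-daily NSO, the mean of
#' the 3--4 serial determinations otherwise) multiplied by the effluent
#' dialysate volume.
#'
#' @param dp_values Instant D/P ratios (non-empty).
#' @param effluent_volume_l Effluent dialysate volume, liters (>= 0).
#' @return Kt, liters per session.
#' @export
kt_instant <- function(dp_values, effluent_volume_l) {
  if (length(dp_values) == 0) stop("no instant D/P values")
  stopifnot(effluent_volume_l >= 0)
  mean(dp_values) * effluent_volume_l
}

#' Removed mass estimated from instant metrics
#'
#' `Q_inst = Kt_inst * TAC_inst` (or `Kt_inst * P_60` for NSO, where
#' only one instant plasma level is available).
#'
#' @param kt_inst_l Instant Kt, liters (>= 0).
#' @param reference_conc_mg_l Instant TAC or 60-min plasma level, mg/L
#'   (>= 0).
#' @return Estimated removed mass, mg.
#' @export
q_instant <- function(kt_inst_l, reference_conc_mg_l) {
  stopifnot(kt_inst_l >= 0, reference_conc_mg_l >= 0)
  kt_inst_l * reference_conc_mg_l
}

#' Corrected instant Kt
#'
#' Converts the instant (machine-side) Kt to a whole-body equivalent by
#' dividing the instant mass estimate by the balance TAC:
#' `Kt_cor = Q_inst / TAC_bal`.
#'
#' @param q_inst_mg Instant mass estimate, mg.
#' @param tac_bal_mg_l Balance TAC, mg/L (> 0).
#' @return Corrected Kt, liters.
#' @export
kt_corrected <- function(q_inst_mg, tac_bal_mg_l) {
  if (any(tac_bal_mg_l <= 0)) stop("TAC must be > 0")
  q_inst_mg / tac_bal_mg_l
}

#' Fractional clearance of a non-urea solute
#'
#' Solute Kt expressed as a fraction of urea Kt in the same session and
#' metric route; urea against itself is exactly 1.
#'
#' @param kt_solute_l Solute Kt, liters.
#' @param kt_urea_l Urea Kt, liters (> 0).
#' @return Dimensionless ratio.
#' @export
fractional_clearance <- function(kt_solute_l, kt_urea_l) {
  if (any(kt_urea_l <= 0)) stop("urea Kt must be > 0")
  ifelse(kt_solute_l == kt_urea_l, 1, kt_solute_l / kt_urea_l)
}

#' Weekly Kt extrapolation
#'
#' Sum of the week's treatments: session Kt times sessions per week
#' (3 for thrice-weekly BHD/HDF, 6 for short-daily NSO).
#'
#' @param kt_session_l Session Kt, liters.
#' @param sessions_per_week Treatments per week (>= 1).
#' @return Weekly Kt, liters/week.
#' @export
weekly_kt <- function(kt_session_l, sessions_per_week) {
  stopifnot(sessions_per_week >= 1)
  kt_session_l * sessions_per_week
}

# Instant plasma-water and dialysate series for one solute; pairs
# matched by sampling time.
.instant_pairs <- function(record, solute) {
  b <- .blood_pw(record, solute)
  bi <- b[b$role == "instant", , drop = FALSE]
  d <- record$dialysate
  di <- d[d$kind == "instant" & d$solute == solute, , drop = FALSE]
  times <- sort(intersect(bi$time_min, di$index_or_time))
  if (length(times) == 0) return(NULL)
  data.frame(
    time_min = times,
    plasma_pw = bi$pw[match(times, bi$time_min)],
    dialysate = di$conc_mg_l[match(times, di$index_or_time)]
  )
}

#' Compute the full per-solute metric set for one session
#'
#' Runs both metric routes for every requested solute: the balance route
#' (bag mass, balance TAC, `Kt_bal`, `D/P_bal`) and the instant route
#' (instant D/P series, `Kt_inst`, `Q_inst`, `Kt_cor`), plus fractional
#' clearances relative to urea and weekly extrapolations.
#'
#' For the instant route the effluent volume is the monitor-reported
#' delivered dialysate plus UF when available (the point of the instant
#' method is to avoid bag collection), falling back to the measured
#' bag-volume sum; both are reported and a relative difference above 3%
#' is flagged in the `volume_flag` column.  For NSO sessions the single
#' 60-min D/P is used and `Q_inst` references the 60-min plasma-water
#' level (`p60`); otherwise the mean of all instant D/P values is used
#' and `Q_inst` references the instant TAC.
#'
#' @param record A [kt_session].
#' @param solutes Solutes to evaluate (default: all present in blood
#'   samples, ordered as [kt_solutes]).
#' @return Data frame, one row per solute, with columns `session_id`,
#'   `modality`, `solute`, `tac_bal`, `tac_inst`, `p60`, `dp_bal`,
#'   `dp_inst_mean`, `dp_inst_cv_pct`, `kt_bal_l`, `kt_inst_l`,
#'   `kt_cor_l`, `q_bal_mg`, `q_inst_mg`, `frac_kt_bal`, `frac_kt_inst`,
#'   `wkt_bal_l`, `wkt_inst_l`, `effluent_bags_l`, `effluent_monitor_l`,
#'   `volume_flag`.  Concentrations in mg/L, masses in mg, volumes in
#'   liters.
#' @export
session_metrics <- function(record, solutes = NULL) {
  if (is.null(solutes)) {
    solutes <- intersect(kt_solutes, unique(record$blood$solute))
  }
  v_monitor <- if (is.na(record$delivered_dialysate_l)) NA_real_ else
    effluent_volume(record$delivered_dialysate_l, record$uf_l)
  out <- lapply(solutes, function(s) {
    bags <- record$dialysate[record$dialysate$kind == "bag" &
                             record$dialysate$solute == s, , drop = FALSE]
    qb <- if (nrow(bags)) q_from_bags(bags$conc_mg_l, bags$volume_l) else NULL
    v_bags <- if (is.null(qb)) NA_real_ else qb$volume_l
    v_eff <- if (!is.na(v_monitor)) v_monitor else v_bags
    flag <- !is.na(v_monitor) && !is.na(v_bags) &&
      abs(v_monitor - v_bags) / v_bags > 0.03
    tac_bal <- tryCatch(tac_balance(record, s), error = function(e) NA_real_)
    q_bal <- if (is.null(qb)) NA_real_ else qb$q_mg
    dp_bal_v <- if (!is.na(q_bal) && !is.na(tac_bal) && !is.na(v_bags))
      dp_balance(q_bal, v_bags, tac_bal) else NA_real_
    kt_bal <- if (!is.na(q_bal) && !is.na(tac_bal))
      kt_balance(q_bal, tac_bal) else NA_real_

    pairs <- .instant_pairs(record, s)
    if (!is.null(pairs)) {
      dps <- dp_instant(pairs$dialysate, pairs$plasma_pw)
      if (record$modality == "NSO") {
        use <- which.min(abs(pairs$time_min - 60))
        dp_use <- dps[use]
        p60 <- pairs$plasma_pw[use]
        tac_inst <- NA_real_
        ref <- p60
      } else {
        dp_use <- dps
        p60 <- if (any(pairs$time_min == 60)) pairs$plasma_pw[pairs$time_min == 60] else NA_real_
        tac_inst <- tac_instant(pairs$plasma_pw[1], pairs$plasma_pw[nrow(pairs)])
        ref <- tac_inst
      }
      kt_inst <- kt_instant(dp_use, v_eff)
      q_inst <- q_instant(kt_inst, ref)
      kt_cor <- if (!is.na(tac_bal)) kt_corrected(q_inst, tac_bal) else NA_real_
      dp_mean <- mean(dp_use)
      dp_cv <- if (length(dps) >= 2) coefficient_of_variation(dps) else NA_real_
    } else {
      dp_mean <- dp_cv <- kt_inst <- q_inst <- kt_cor <- tac_inst <- p60 <- NA_real_
    }
    data.frame(
      session_id = record$id, modality = record$modality, solute = s,
      tac_bal = tac_bal, tac_inst = tac_inst, p60 = p60,
      dp_bal = dp_bal_v, dp_inst_mean = dp_mean, dp_inst_cv_pct = dp_cv,
      kt_bal_l = kt_bal, kt_inst_l = kt_inst, kt_cor_l = kt_cor,
      q_bal_mg = q_bal, q_inst_mg = q_inst,
      wkt_bal_l = weekly_kt(kt_bal, record$sessions_per_week),
      wkt_inst_l = weekly_kt(kt_inst, record$sessions_per_week),
      effluent_bags_l = v_bags, effluent_monitor_l = v_monitor,
      volume_flag = flag, stringsAsFactors = FALSE
    )
  })
  m <- do.call(rbind, out)
  ku_b <- m$kt_bal_l[m$solute == "urea"]
  ku_i <- m$kt_inst_l[m$solute == "urea"]
  m$frac_kt_bal <- if (length(ku_b) == 1 && !is.na(ku_b) && ku_b > 0)
    fractional_clearance(m$kt_bal_l, ku_b) else NA_real_
  m$frac_kt_inst <- if (length(ku_i) == 1 && !is.na(ku_i) && ku_i > 0)
    fractional_clearance(m$kt_inst_l, ku_i) else NA_real_
  rownames(m) <- NULL
  m
}
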