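#' Plasma-water concentration (Colton)
#'
#' Converts a measured plasma concentration to the plasma-water level by
#' dividing by the water fraction `1 - 0.0107 * TP`, where TP is total
#' plasma protein in g/dl.  Solute exchange across the dialyzer membrane
#' is governed by water-phase concentrations, so all D/P and TAC
#' calculations use plasma-water values.
#'
#' @param conc Measured plasma concentration, mg/L (> 0).
#' @param total_protein_g_dl Total plasma protein, g/dl (0 <= TP < 93.4).
#' @return Plasma-water concentration, mg/L (>= `conc`).
#' @examples
#' to_plasma_water(1000, 7)  # 1080.96
#' @export
to_plasma_water <- function(conc, total_protein_g_dl) {
  w <- 1 - 0.0107 * total_protein_g_dl
  if (any(w <= 0)) stop("total protein too high: plasma water fraction non-positive")
  if (any(conc <= 0)) stop("concentration must be > 0")
  conc / w
}

#' Hemoconcentration correction of the end-dialysis sample (Bergstrom-Wehle)
#'
#' Removes the concentrating effect of intradialytic ultrafiltration on
#' the post-dialysis plasma level: `P_cor = P_post / (1 + UF / (0.2 * BW_post))`,
#' with `0.2 * BW_post` approximating the extracellular volume.
#'
#' @param p_post_pw Post-dialysis plasma-water concentration, mg/L.
#' @param uf_l Ultrafiltration volume (dialytic weight loss), liters.
#' @param bw_post_kg Post-dialysis body weight, kg (> 0).
#' @return Corrected concentration, mg/L (<= `p_post_pw`).
#' @examples
#' correct_hemoconcentration(400, 3, 70)  # 329.41
#' @export
correct_hemoconcentration <- function(p_post_pw, uf_l, bw_post_kg) {
  if (any(bw_post_kg <= 0)) stop("bw_post_kg must be > 0")
  if (any(uf_l < 0)) stop("uf_l must be >= 0")
  p_post_pw / (1 + uf_l / (0.2 * bw_post_kg))
}

#' Post-dialysis rebound equilibration (Tattersall)
#'
#' Projects the corrected end-dialysis concentration to its
#' post-rebound equilibrated value:
#' `P_eq = P_pre * (P_cor / P_pre)^(t / (t + tx))`, where `t` is
#' treatment time and `tx` the solute-specific equilibration time
#' (35 min urea, 50 creatinine, 60 phosphorus, 110 beta-2-microglobulin;
#' see [solute_tx()]).
#'
#' @param p_pre Pre-dialysis plasma-water concentration, mg/L (> 0).
#' @param p_cor Corrected end-dialysis concentration, mg/L (> 0).
#' @param t_min Treatment time, minutes (> 0).
#' @param tx_min Equilibration time, minutes (>= 0).
#' @return Equilibrated concentration, mg/L; lies between `p_cor` and
#'   `p_pre` for a falling-concentration session.
#' @examples
#' equilibrate_rebound(1000, 300, 240, 35)  # 349.68
#' @export
equilibrate_rebound <- function(p_pre, p_cor, t_min, tx_min) {
  stopifnot(p_pre > 0, p_cor > 0, t_min > 0, tx_min >= 0)
  p_pre * (p_cor / p_pre)^(t_min / (t_min + tx_min))
}

#' Logarithmic-mean time-averaged concentration
#'
#' The time-averaged concentration of a solute decaying (approximately)
#' exponentially between two levels is their logarithmic mean
#' `(a - b) / ln(a / b)`.  Near-equal endpoints take the continuous
#' limit (the common value).
#'
#' @param p_start,p_end Endpoint concentrations, mg/L (> 0).
#' @return Logarithmic mean, mg/L; always between the two inputs.
#' @export
tac_logmean <- function(p_start, p_end) {
  if (any(p_start <= 0) || any(p_end <= 0)) stop("concentrations must be > 0")
  ifelse(abs(p_start - p_end) / p_start < 1e-9,
         p_start,
         (p_start - p_end) / log(p_start / p_end))
}

# Pull pre/post/instant plasma-water values for one solute out of a
# session record.  Missing per-sample total protein falls back to the
# session's pre (for pre/instant) or post (for post) sample TP, with a
# warning.
.blood_pw <- function(record, solute) {
  b <- record$blood[record$blood$solute == solute, , drop = FALSE]
  if (nrow(b) == 0) stop("no blood samples for solute ", solute)
  tp_pre <- b$total_protein_g_dl[b$role == "pre"][1]
  tp_post <- b$total_protein_g_dl[b$role == "post"][1]
  tp <- b$total_protein_g_dl
  fb <- is.na(tp)
  if (any(fb)) {
    tp[fb] <- ifelse(b$role[fb] == "post", tp_post, tp_pre)
    if (any(is.na(tp))) stop("total protein missing and no session-level fallback for ", solute)
    warning("missing total protein: using session-level fallback for ",
            sum(fb), " sample(s) of ", solute)
  }
  b$pw <- to_plasma_water(b$conc_mg_l, tp)
  b
}

#' Balance-study time-averaged concentration
#'
#' Full blood-side correction chain for whole-dialysate balance studies:
#' the pre sample is taken to plasma water; the end-of-session sample is
#' taken to plasma water, corrected for hemoconcentration
#' ([correct_hemoconcentration()]) and equilibrated for post-dialysis
#' rebound ([equilibrate_rebound()] with the solute's `tx`); the TAC is
#' the logarithmic mean of pre plasma-water and equilibrated values.
#'
#' @param record A [kt_session] with pre and post samples for `solute`.
#' @param solute Solute name.
#' @param tx_min Equilibration time override, minutes; defaults to the
#'   solute's physiological `tx` ([solute_tx()]).  Set to 0 for a
#'   system known to have no compartment disequilibrium (e.g. the
#'   simulator's perfectly mixed single-pool limit).
#' @return TAC, mg/L.
#' @export
tac_balance <- function(record, solute, tx_min = NULL) {
  if (is.null(tx_min)) tx_min <- solute_tx(solute)
  b <- .blood_pw(record, solute)
  pre <- b$pw[b$role == "pre"][1]
  post <- b$pw[b$role == "post"][1]
  if (is.na(pre) || is.na(post)) {
    stop("balance TAC unavailable: need pre and post blood samples for ", solute)
  }
  p_cor <- correct_hemoconcentration(post, record$uf_l, record$bw_post_kg)
  p_eq <- equilibrate_rebound(pre, p_cor, record$duration_min, tx_min)
  tac_logmean(pre, p_eq)
}

#' Instant-sample time-averaged concentration
#'
#' TAC estimated from two uncorrected mid-session plasma-water values
#' (by design the 60- and 180-min draws): their logarithmic mean.  No
#' hemoconcentration or rebound correction is applied to instant
#' samples.
#'
#' @param p_early_pw,p_late_pw Plasma-water concentrations at the
#'   earlier and later instant, mg/L.
#' @return TAC, mg/L.
#' @export
tac_instant <- function(p_early_pw, p_late_pw) {
  tac_logmean(p_early_pw, p_late_pw)
}
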