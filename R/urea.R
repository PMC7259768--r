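#' Single-pool Kt/V (Daugirdas second generation)
#'
#' `spKt/V = -ln(R - 0.008 t) + (4 - 3.5 R) UF / W`, with
#' `R = post/pre` plasma urea (uncorrected, not plasma-water), `t` the
#' session length in hours, `UF` the weight loss in liters and `W` the
#' post-dialysis weight in kg.
#'
#' @param pre,post Pre- and post-dialysis plasma urea, same unit
#'   (`pre > post > 0`).
#' @param t_hr Session length, hours.
#' @param uf_l Ultrafiltration, liters.
#' @param bw_post_kg Post-dialysis weight, kg.
#' @return Dimensionless single-pool Kt/V.
#' @examples
#' sp_ktv_daugirdas(1000, 350, 4, 3, 70)  # 1.2646
#' @export
sp_ktv_daugirdas <- function(pre, post, t_hr, uf_l, bw_post_kg) {
  stopifnot(pre > 0, post > 0, post < pre, uf_l >= 0, bw_post_kg > 0)
  r <- post / pre
  arg <- r - 0.008 * t_hr
  if (arg <= 0) stop("R - 0.008 t <= 0: implausible removal for session length")
  -log(arg) + (4 - 3.5 * r) * uf_l / bw_post_kg
}

#' Equilibrated Kt/V (Daugirdas rate equation)
#'
#' Arteriovenous-access rate adjustment of the single-pool dose for
#' post-dialysis rebound: `eKt/V = spKt/V - 0.6 spKt/V / t + 0.03`.
#'
#' @param sp_ktv Single-pool Kt/V.
#' @param t_hr Session length, hours (> 0).
#' @return Equilibrated Kt/V.
#' @examples
#' e_ktv(1.2646, 4)  # 1.1049
#' @export
e_ktv <- function(sp_ktv, t_hr) {
  stopifnot(t_hr > 0)
  sp_ktv - 0.6 * sp_ktv / t_hr + 0.03
}

#' Standardized weekly Kt/V (Leypoldt)
#'
#' Converts an equilibrated per-session dose to the continuous-
#' equivalent weekly dose, comparable across treatment frequencies:
#' \deqn{stdKt/V = \frac{10080 (1 - e^{-eKt/V}) / t}{(1 - e^{-eKt/V})/eKt/V + 10080/(N t) - 1}}
#' with `t` in minutes and `N` sessions per week (10080 = minutes/week).
#'
#' @param e_ktv Equilibrated Kt/V per session (> 0).
#' @param t_min Session length, minutes (> 0).
#' @param n_per_week Sessions per week (>= 1).
#' @return Weekly standardized Kt/V.
#' @examples
#' std_ktv_leypoldt(1.52, 240, 3)  # 2.428
#' @export
std_ktv_leypoldt <- function(e_ktv, t_min, n_per_week) {
  stopifnot(e_ktv > 0, t_min > 0, n_per_week >= 1)
  num <- 10080 * (1 - exp(-e_ktv)) / t_min
  den <- (1 - exp(-e_ktv)) / e_ktv + 10080 / (n_per_week * t_min) - 1
  num / den
}

#' Watson total body water
#'
#' Anthropometric urea distribution volume:
#' male `2.447 - 0.09156 age + 0.1074 ht + 0.3362 wt`;
#' female `-2.097 + 0.1069 ht + 0.2466 wt` (age in years, height cm,
#' weight kg).
#'
#' @param sex `"male"` or `"female"`.
#' @param age_yr Age, years (> 0).
#' @param height_cm Height, cm.
#' @param weight_kg Weight, kg.
#' @return Total body water, liters.
#' @examples
#' watson_tbw("male", 60, 170, 70)  # 38.75
#' @export
watson_tbw <- function(sex, age_yr, height_cm, weight_kg) {
  sex <- match.arg(tolower(sex), c("male", "female"))
  if (age_yr <= 0) stop("age_yr must be > 0")
  tbw <- if (sex == "male") {
    2.447 - 0.09156 * age_yr + 0.1074 * height_cm + 0.3362 * weight_kg
  } else {
    -2.097 + 0.1069 * height_cm + 0.2466 * weight_kg
  }
  if (tbw <= 0) stop("non-positive total body water")
  tbw
}

#' Urea distribution volume from dialysate balance
#'
#' Solves the session mass balance for the end-dialysis urea
#' distribution volume:
#' `V = Q / (P_pre - P_eq_post) - P_pre UF / (P_pre - P_eq_post)`,
#' i.e. recovered dialysate urea mass `Q` equals the pool loss
#' `P_pre (V + UF) - P_eq_post V`.  Plasma entries are *uncorrected*
#' concentrations (no plasma-water conversion), the post value being
#' rebound-equilibrated.
#'
#' @param q_bal_mg Urea mass recovered in spent dialysate, mg.
#' @param p_pre Pre-dialysis plasma urea, mg/L.
#' @param p_eq_post Equilibrated post-dialysis plasma urea, mg/L
#'   (`p_pre > p_eq_post > 0`).
#' @param uf_l Ultrafiltration, liters.
#' @return Distribution volume, liters.
#' @examples
#' v_from_balance(24000, 1000, 350, 3)  # 32.31
#' @export
v_from_balance <- function(q_bal_mg, p_pre, p_eq_post, uf_l) {
  stopifnot(p_eq_post > 0, uf_l >= 0)
  if (p_pre <= p_eq_post) stop("p_pre must exceed p_eq_post")
  (q_bal_mg - p_pre * uf_l) / (p_pre - p_eq_post)
}

#' Urea Kt from the blood-side kinetic chain
#'
#' `Kt_Daug = eKt/V * V`: the plasma-kinetic-model counterpart of the
#' dialysate-side [kt_balance()].
#'
#' @param e_ktv Equilibrated Kt/V (> 0).
#' @param v_l Urea distribution volume, liters (> 0).
#' @return Kt, liters per session.
#' @export
kt_from_ektv <- function(e_ktv, v_l) {
  stopifnot(e_ktv > 0, v_l > 0)
  e_ktv * v_l
}

#' Short-daily (NSO) dialysate prescription
#'
#' Single-session dialysate delivery targeting a per-session spKt/V:
#' `target_spktv * TBW / 0.85` liters (0.85 approximating the
#' dialysate/plasma urea saturation of the low-dialysate-flow system).
#'
#' @param tbw_l Total body water, liters (> 0).
#' @param target_spktv Target per-session spKt/V (default 0.5).
#' @return Dialysate volume, liters.
#' @examples
#' nso_dialysate_volume(38.75)  # 22.79
#' @export
nso_dialysate_volume <- function(tbw_l, target_spktv = 0.5) {
  stopifnot(tbw_l > 0, target_spktv >= 0)
  target_spktv * tbw_l / 0.85
}

#' Urea kinetic summary for one session
#'
#' Runs the blood-side reference chain on a session record: Daugirdas
#' spKt/V and eKt/V from the raw (uncorrected) pre/post plasma urea,
#' Leypoldt stdKt/V, the distribution volume from the dialysate urea
#' balance ([v_from_balance()], with the post value rebound-equilibrated
#' via the Tattersall exponent but otherwise uncorrected), the derived
#' `Kt_Daug = eKt/V * V`, and `eKt/V_bal = Kt_bal / V`.  Watson TBW is
#' included when the record carries patient anthropometrics.
#'
#' @param record A [kt_session] with urea pre/post blood samples and
#'   urea dialysate bags.
#' @return One-row data frame with columns `session_id`, `modality`,
#'   `r_post_pre`, `sp_ktv`, `e_ktv`, `std_ktv`, `v_l`, `kt_daug_l`,
#'   `kt_bal_l`, `e_ktv_bal`, `tbw_l`.
#' @export
urea_kinetics <- function(record) {
  b <- record$blood[record$blood$solute == "urea", , drop = FALSE]
  pre <- b$conc_mg_l[b$role == "pre"][1]
  post <- b$conc_mg_l[b$role == "post"][1]
  if (is.na(pre) || is.na(post)) stop("urea kinetics need pre and post urea samples")
  t_hr <- record$duration_min / 60
  sp <- sp_ktv_daugirdas(pre, post, t_hr, record$uf_l, record$bw_post_kg)
  ek <- e_ktv(sp, t_hr)
  st <- std_ktv_leypoldt(ek, record$duration_min, record$sessions_per_week)
  bags <- record$dialysate[record$dialysate$kind == "bag" &
                           record$dialysate$solute == "urea", , drop = FALSE]
  if (nrow(bags)) {
    qb <- q_from_bags(bags$conc_mg_l, bags$volume_l)
    p_cor <- correct_hemoconcentration(post, record$uf_l, record$bw_post_kg)
    p_eq <- equilibrate_rebound(pre, p_cor, record$duration_min, solute_tx("urea"))
    v <- v_from_balance(qb$q_mg, pre, p_eq, record$uf_l)
    kt_daug <- kt_from_ektv(ek, v)
    kt_bal <- kt_balance(qb$q_mg, tac_balance(record, "urea"))
    ektv_bal <- kt_bal / v
  } else {
    v <- kt_daug <- kt_bal <- ektv_bal <- NA_real_
  }
  tbw <- if (!is.null(record$patient)) {
    p <- record$patient
    watson_tbw(p$sex, p$age_yr, p$height_cm, p$weight_kg)
  } else NA_real_
  data.frame(session_id = record$id, modality = record$modality,
             r_post_pre = post / pre, sp_ktv = sp, e_ktv = ek,
             std_ktv = st, v_l = v, kt_daug_l = kt_daug,
             kt_bal_l = kt_bal, e_ktv_bal = ektv_bal, tbw_l = tbw,
             stringsAsFactors = FALSE)
}
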