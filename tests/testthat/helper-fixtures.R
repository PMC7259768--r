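# In-code fixtures: a small hand-built 4-hour session with known
# numbers, used across test files.

make_blood <- function(solute = "urea", pre = 100, post = 40,
                       instants = c(`60` = 70, `120` = 55, `180` = 45),
                       tp_pre = 7, tp_post = 7.5, tp_instant = 7.2,
                       unit = "mg/dl") {
  rbind(
    data.frame(time_min = 0, role = "pre", solute = solute, conc = pre,
               unit = unit, total_protein_g_dl = tp_pre),
    data.frame(time_min = as.numeric(names(instants)), role = "instant",
               solute = solute, conc = unname(instants), unit = unit,
               total_protein_g_dl = tp_instant),
    data.frame(time_min = 240, role = "post", solute = solute, conc = post,
               unit = unit, total_protein_g_dl = tp_post)
  )
}

make_dialysate <- function(solute = "urea",
                           bags = rep(20, 6), bag_conc = rep(20, 6),
                           instants = c(`60` = 30, `120` = 24, `180` = 20),
                           unit = "mg/dl") {
  rbind(
    data.frame(kind = "bag", index_or_time = seq_along(bags),
               solute = solute, conc = bag_conc, unit = unit,
               volume_l = bags),
    data.frame(kind = "instant", index_or_time = as.numeric(names(instants)),
               solute = solute, conc = unname(instants), unit = unit,
               volume_l = NA_real_)
  )
}

make_session <- function(id = "s1", solute = "urea", modality = "BHD_hf",
                         uf_l = 3, delivered = 120, ...) {
  kt_session(id = id,
             patient = kt_patient("p1", "male", 60, 170, 73),
             modality = modality, duration_min = 240, uf_l = uf_l,
             bw_post_kg = 70, delivered_dialysate_l = delivered,
             sessions_per_week = 3,
             blood = make_blood(solute = solute, ...),
             dialysate = make_dialysate(solute = solute))
}

# single-pool analytic configuration (perfectly mixed, no heart-lung
# disequilibrium, no UF, no noise, no generation)
single_pool_config <- function(kd = 200, v = 40, c0 = 1000, ...) {
  sim_config(co_l_min = Inf, uf_l = 0, assay_cv = 0, v_total_l = v,
             solutes = list(sim_solute("urea", c0, kd, kc_ml_min = Inf,
                                       frac_v1 = 0.5, g_mg_min = 0)),
             ...)
}
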