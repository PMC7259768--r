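# ktdial

Solute-specific dialysis efficiency metrics: the **Kt factor** — liters of
plasma totally cleared of a solute in one hemodialysis session — computed
either from whole spent-dialysate mass balances or from instant
dialysate-to-plasma (D/P) concentration ratios, for urea, creatinine,
phosphorus and β2-microglobulin.

## Why

Dialysis dose is conventionally measured with blood-side urea kinetics
(spKt/V, eKt/V, stdKt/V), but urea removal does not translate into
proportional removal of other uremic solutes — middle molecules such as
β2-microglobulin behave very differently across low-flux, high-flux,
hemodiafiltration and short-daily low-dialysate technologies. The Kt
factor extends dose metrics to any measurable solute:

* **Balance route** — collect all effluent dialysate,
  `Kt_bal = Q_bal / TAC_bal`, where `Q_bal` is the recovered solute mass
  and `TAC_bal` the time-averaged plasma-water concentration, the
  logarithmic mean of the pre-dialysis level and the hemoconcentration-
  corrected (Bergström–Wehle), rebound-equilibrated (Tattersall,
  `P_eq = P_pre (P_cor/P_pre)^{t/(t+tx)}`, tx = 35/50/60/110 min for
  urea/creatinine/phosphorus/β2M) end-of-session level, all on the
  plasma-water scale (Colton, `P_pw = P / (1 − 0.0107·TP)`).
* **Instant route** — no collection needed:
  `Kt_inst = mean(D/P) × V_effluent`, with the D/P ratio from one or a few
  simultaneous mid-session dialysate/blood draws and the effluent volume
  read off the machine (delivered dialysate + ultrafiltration).

The package also implements the blood-side urea reference chain
(Daugirdas second-generation spKt/V, the rate-equation eKt/V, Leypoldt
stdKt/V, Watson total body water, and the urea distribution volume solved
independently from the dialysate balance), summary statistics for cohort
comparisons (paired t, Pearson/OLS, one-way ANOVA with Scheffé post-hoc),
CSV session I/O with a CLI, and a **two-pool kinetic session simulator**
with cardiopulmonary disequilibrium used to validate every metric against
ground truth.

## Worked example

```r
library(ktdial)

# simulate one 4-hour high-flux session with known ground truth
sim <- simulate_session(sim_config(seed = 7))
m   <- session_metrics(sim$record)
m[, c("solute", "dp_inst_mean", "kt_inst_l", "kt_bal_l", "kt_cor_l")]
#>       solute dp_inst_mean kt_inst_l kt_bal_l kt_cor_l
#> 1       urea       0.4236     52.10    45.82    43.18
#> 2 creatinine       0.2555     31.43    29.67    29.22
#> 3 phosphorus       0.2604     32.02    29.68    29.78
#> 4        b2m       0.1149     14.13    13.49    13.29

urea_kinetics(sim$record)[, c("sp_ktv", "e_ktv", "std_ktv", "v_l", "kt_daug_l")]
#>    sp_ktv   e_ktv std_ktv     v_l kt_daug_l
#> 1 1.65462 1.43643   2.366 32.0279   46.0058
```

Reading: the instant route (`kt_inst_l`, from three mid-session D/P pairs
times 123 L of effluent) reports ~52 L of plasma cleared of urea — the
work done by the machine on the blood delivered to it — while the balance
route (`kt_bal_l`, 28 g of urea recovered over a 612 mg/L time-averaged
plasma-water concentration) reports ~46 L, the whole-body clearance. The
gap is cardiopulmonary disequilibrium: arterial-line blood runs ~5% below
systemic concentration during high-efficiency dialysis. Dividing the
instant-route mass estimate by the balance TAC (`kt_cor_l`) recovers the
balance value. The blood-side chain agrees: `kt_daug_l` (eKt/V × V from
the dialysate urea balance) is ~46 L.

Cohort level:

```r
cohort <- generate_cohort(n_per_arm = c(BHD_lf = 4, BHD_hf = 3, HDF = 2, NSO = 7),
                          seed = 7)
cm  <- cohort_metrics(cohort)
rep <- build_report(cm$metrics, cm$urea)
print(rep)   # per-arm Kt_bal / Kt_inst means ± SD per solute
```

## Command line

```sh
Rscript inst/scripts/ktdial simulate --out cohort/ --seed 42
Rscript inst/scripts/ktdial compute  --sessions cohort/sessions.csv \
    --blood cohort/blood.csv --dialysate cohort/dialysate.csv --out metrics.csv
Rscript inst/scripts/ktdial report   --metrics metrics.csv --out report.csv
```

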