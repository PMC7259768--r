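#' Solutes tracked by the package
#'
#' The four uremic solutes for which session Kt metrics are computed:
#' urea, creatinine, phosphorus and beta-2-microglobulin (`"b2m"`).
#'
#' @format Character vector of canonical solute names.
#' @export
kt_solutes <- c("urea", "creatinine", "phosphorus", "b2m")

# Per-solute constants.  tx_min is the post-dialysis equilibration time
# used in the Tattersall rebound correction; default_unit is the unit in
# which clinical laboratories usually report the solute (beta-2-microglobulin
# plasma levels of ~2 are physiological only in mg/L).
.solute_table <- data.frame(
  name         = c("urea", "creatinine", "phosphorus", "b2m"),
  tx_min       = c(35, 50, 60, 110),
  default_unit = c("mg/dl", "mg/dl", "mg/dl", "mg/l"),
  stringsAsFactors = FALSE
)

#' Solute parameter lookup
#'
#' Returns the fixed per-solute parameters: the Tattersall equilibration
#' time `tx_min` (35 min urea, 50 creatinine, 60 phosphorus, 110
#' beta-2-microglobulin) and the default input concentration unit.
#'
#' @param solute Solute name, one of [kt_solutes].
#' @return A list with elements `name`, `tx_min` and `default_unit`.
#' @examples
#' solute_info("urea")$tx_min    # 35
#' solute_info("b2m")$tx_min     # 110
#' @export
solute_info <- function(solute) {
  solute <- match.arg(tolower(solute), .solute_table$name)
  as.list(.solute_table[.solute_table$name == solute, ])
}

#' @rdname solute_info
#' @export
solute_tx <- function(solute) solute_info(solute)$tx_min

#' Convert a concentration to mg/L
#'
#' All concentrations are held internally in mg/L; inputs in mg/dl are
#' multiplied by 10.
#'
#' @param conc Numeric concentration value(s).
#' @param unit `"mg/dl"` or `"mg/l"` (case-insensitive, recycled).
#' @return Concentration(s) in mg/L.
#' @export
conc_to_mg_l <- function(conc, unit) {
  unit <- tolower(unit)
  ok <- unit %in% c("mg/dl", "mg/l")
  if (!all(ok)) stop("unknown concentration unit: ", paste(unique(unit[!ok]), collapse = ", "))
  conc * ifelse(unit == "mg/dl", 10, 1)
}
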