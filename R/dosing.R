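#' Plan a lean-mass-normalised injection
#'
#' Doses are normalised to lean body mass, not total body mass, so that
#' diet groups with similar lean mass but different fat mass receive the
#' same glucose and insulin amounts: glucose at 0.5 g/kg lean mass, and (in
#' ITT mode) insulin at 0.75 U/kg lean mass co-loaded in the same syringe.
#' The injection is brought to a total volume of 150 uL with physiological
#' saline.
#'
#' @param lean_mass_g Lean body mass in grams (> 0).
#' @param mode `"GTT"` (glucose only) or `"ITT"` (glucose + insulin).
#' @param glucose_g_per_kg,insulin_U_per_kg Dose rates per kg lean mass.
#' @param total_volume_ul Total injected volume (uL).
#' @return List with `glucose_mg`, `insulin_mU` (0 in GTT mode) and
#'   `total_volume_ul`.
#' @examples
#' plan_dose(20, "ITT")  # 10 mg glucose + 15 mU insulin in 150 uL
#' @export
plan_dose <- function(lean_mass_g, mode = c("GTT", "ITT"),
                      glucose_g_per_kg = 0.5, insulin_U_per_kg = 0.75,
                      total_volume_ul = 150) {
  mode <- match.arg(mode)
  if (!is.numeric(lean_mass_g) || length(lean_mass_g) != 1L ||
      is.na(lean_mass_g) || lean_mass_g <= 0)
    stop("lean mass must be a positive number")
  lean_kg <- lean_mass_g / 1000
  list(glucose_mg = glucose_g_per_kg * lean_kg * 1000,
       insulin_mU = if (mode == "ITT") insulin_U_per_kg * lean_kg * 1000 else 0,
       total_volume_ul = total_volume_ul)
}

#' Dosing sheet for an animal manifest
#'
#' @param manifest Data frame with `animal_id`, `group`, `body_mass_g`,
#'   `lean_mass_g` (lean mass must be positive and not exceed body mass).
#' @param mode Test mode, as in [plan_dose()].
#' @param ... Further arguments passed to [plan_dose()].
#' @return Data frame with one dosing row per animal.
#' @export
dose_sheet <- function(manifest, mode = c("GTT", "ITT"), ...) {
  mode <- match.arg(mode)
  need <- c("animal_id", "group", "body_mass_g", "lean_mass_g")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(manifest$lean_mass_g > 0 & manifest$lean_mass_g <= manifest$body_mass_g))
  if (length(bad))
    stop("invalid lean/body mass for animal(s): ",
         paste(manifest$animal_id[bad], collapse = ", "))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    d <- plan_dose(manifest$lean_mass_g[i], mode, ...)
    data.frame(animal_id = manifest$animal_id[i], group = manifest$group[i],
               test_mode = mode, lean_mass_g = manifest$lean_mass_g[i],
               glucose_mg = d$glucose_mg, insulin_mU = d$insulin_mU,
               saline_to_volume_ul = d$total_volume_ul,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
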