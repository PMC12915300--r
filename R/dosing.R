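# Whole-lake remediation dosing: metal-sulfide precipitation demand, a
# safety-factored sulfide target, the biomass dose and total mass for a
# stated lake volume, volumetric normalisations for comparison against
# passive AMD treatment, and pellet settling times.

.us_short_ton_kg <- 907.185
.mgallon_ML <- 3.785

.mineral_ratio <- c(ZnS = 1, As2S3 = 1.5, FeS = 1)

#' One dissolved metal(loid) and its sulfide sink
#'
#' @param metal Metal label, e.g. `"Zn"`.
#' @param conc_mM Dissolved concentration to remove (mM).
#' @param mineral Sulfide mineral formed (`"ZnS"`, `"As2S3"`, `"FeS"`), used
#'   to default `sulfide_per_metal`.
#' @param sulfide_per_metal mol S(-II) needed per mol metal removed (1 for
#'   ZnS and FeS, 3/2 for As2S3).
#' @return An object of class `metal_inventory`.
#' @export
#' @examples
#' metal_inventory("As", 0.23, "As2S3")
metal_inventory <- function(metal, conc_mM, mineral = NULL,
                            sulfide_per_metal = NULL) {
  if (is.null(sulfide_per_metal)) {
    if (is.null(mineral) || !mineral %in% names(.mineral_ratio)) {
      stop_sulfidogen("supply a known mineral or sulfide_per_metal",
                      "sulfidogen_lookup_error")
    }
    sulfide_per_metal <- .mineral_ratio[[mineral]]
  }
  if (conc_mM < 0 || sulfide_per_metal <= 0) {
    stop_sulfidogen("concentration must be >= 0 and stoichiometry > 0",
                    "sulfidogen_domain_error")
  }
  structure(list(metal = metal, conc_mM = conc_mM, mineral = mineral,
                 sulfide_per_metal = sulfide_per_metal),
            class = "metal_inventory")
}

#' Deep-layer metal inventories of the reference lake scenario
#'
#' Zn (1.67 mM, removed as ZnS) and As (0.23 mM, removed as As2S3). FeS is
#' deliberately excluded from the default demand — iron stays in solution
#' to preserve density stratification — but an Fe entry can be added.
#'
#' @return List of [metal_inventory] objects.
#' @export
cm_inventories <- function() {
  list(metal_inventory("Zn", 1.67, "ZnS"),
       metal_inventory("As", 0.23, "As2S3"))
}

#' Stoichiometric sulfide demand of a metal inventory
#'
#' `sum(concentration × sulfide_per_metal)`; additive over inventories and
#' linear in concentrations.
#'
#' @param inventories A [metal_inventory] or list of them.
#' @return Demand in mM S(-II).
#' @export
#' @examples
#' sulfide_demand(cm_inventories())  # ~2 mM
sulfide_demand <- function(inventories) {
  if (inherits(inventories, "metal_inventory")) inventories <- list(inventories)
  sum(vapply(inventories, function(m) m$conc_mM * m$sulfide_per_metal,
             numeric(1)))
}

#' Biomass dose required for a sulfide target
#'
#' @param target_mM Target sulfide production (mM).
#' @param yield_ratio Sulfide yield of the substrate (mM S(-II) per g/L of
#'   biomass, equivalently mmol per g); must be positive.
#' @return Dose in g biomass per L of treated water.
#' @export
required_dose <- function(target_mM, yield_ratio) {
  if (yield_ratio <= 0) {
    stop_sulfidogen("yield ratio must be positive", "sulfidogen_domain_error")
  }
  target_mM / yield_ratio
}

#' Total substrate mass for a treated volume
#'
#' @param dose_g_l Dose in g/L.
#' @param volume_m3 Treated volume in m³.
#' @return List with `kg`, `metric_tons` and `us_tons` (short ton =
#'   907.185 kg).
#' @export
total_mass <- function(dose_g_l, volume_m3) {
  if (dose_g_l < 0 || volume_m3 < 0) {
    stop_sulfidogen("dose and volume must be non-negative", "sulfidogen_domain_error")
  }
  kg <- dose_g_l * volume_m3 * 1000 / 1000
  list(kg = kg, metric_tons = kg / 1000, us_tons = kg / .us_short_ton_kg)
}

#' Volumetric substrate requirement
#'
#' @param mass_t Substrate mass in metric tons.
#' @param volume_ML Treated volume in millions of liters.
#' @return List with `t_per_ML` and `us_tons_per_mgal` (1 Mgallon =
#'   3.785 ML).
#' @export
volumetric_requirement <- function(mass_t, volume_ML) {
  if (volume_ML <= 0) {
    stop_sulfidogen("volume must be positive", "sulfidogen_domain_error")
  }
  t_per_ML <- mass_t / volume_ML
  list(t_per_ML = t_per_ML,
       us_tons_per_mgal = t_per_ML * 1000 / .us_short_ton_kg * .mgallon_ML)
}

#' Volume treated by a flow over a duration
#'
#' Uses a 365-day year.
#'
#' @param flow_l_min Flow in L/min.
#' @param years Duration in years.
#' @return Treated volume in millions of liters (ML).
#' @export
#' @examples
#' treatment_volume(3785, 10)  # ~19,900 ML
treatment_volume <- function(flow_l_min, years) {
  if (flow_l_min <= 0 || years <= 0) {
    stop_sulfidogen("flow and duration must be positive", "sulfidogen_domain_error")
  }
  flow_l_min * 60 * 24 * 365 * years / 1e6
}

#' Pellet settling time through a water column
#'
#' @param depth_m Water depth (m).
#' @param velocity_cm_s Settling velocity (cm/s); must be positive.
#' @return Settling time in minutes.
#' @export
#' @examples
#' settling_time(40, 15)  # ~4.4 min
settling_time <- function(depth_m, velocity_cm_s) {
  if (velocity_cm_s <= 0) {
    stop_sulfidogen("settling velocity must be positive", "sulfidogen_domain_error")
  }
  if (depth_m < 0) {
    stop_sulfidogen("depth must be non-negative", "sulfidogen_domain_error")
  }
  depth_m * 100 / velocity_cm_s / 60
}

#' Full whole-lake dosing plan
#'
#' Chains the dosing calculation: stoichiometric sulfide demand of the
#' inventories, a safety-factored target (either an absolute `target_mM` or
#' `safety_factor × demand`), the biomass dose from the substrate's sulfide
#' yield ratio, the total mass over the lake volume, and the volumetric
#' requirement. Deep-layer/upper-layer densities can be attached as
#' advisory context; they enter no calculation.
#'
#' @param inventories List of [metal_inventory] objects.
#' @param yield_ratio Substrate sulfide yield (mM S(-II) per g).
#' @param volume_m3 Treated volume (m³).
#' @param target_mM Absolute sulfide target (mM); overrides `safety_factor`.
#' @param safety_factor Multiplier on the stoichiometric demand (used when
#'   `target_mM` is `NULL`; default 1).
#' @param densities Optional named numeric vector of advisory layer
#'   densities (mg/cm³).
#' @return An object of class `dosing_plan`.
#' @export
#' @examples
#' dosing_plan(cm_inventories(), yield_ratio = 1.06, volume_m3 = 112800,
#'             target_mM = 3)
dosing_plan <- function(inventories, yield_ratio, volume_m3,
                        target_mM = NULL, safety_factor = NULL,
                        densities = NULL) {
  demand <- sulfide_demand(inventories)
  if (is.null(target_mM)) {
    target_mM <- demand * (safety_factor %||% 1)
  }
  if (!is.null(safety_factor) && safety_factor >= 1 && target_mM < demand) {
    stop_sulfidogen("safety-factored target below stoichiometric demand",
                    "sulfidogen_validation_error")
  }
  dose <- required_dose(target_mM, yield_ratio)
  mass <- total_mass(dose, volume_m3)
  vol_ML <- volume_m3 / 1000
  structure(list(
    inventories = inventories, demand_mM = demand, target_mM = target_mM,
    yield_ratio = yield_ratio, volume_m3 = volume_m3, volume_ML = vol_ML,
    dose_g_l = dose, mass = mass,
    volumetric = volumetric_requirement(mass$metric_tons, vol_ML),
    densities = densities), class = "dosing_plan")
}

#' Format a dosing plan as text lines
#'
#' @param plan A [dosing_plan].
#' @return Character vector of report lines.
#' @export
format_dosing_plan <- function(plan) {
  stopifnot(inherits(plan, "dosing_plan"))
  inv <- vapply(plan$inventories, function(m) {
    sprintf("  %-3s %6.3f mM as %-6s -> %6.3f mM S(-II)", m$metal, m$conc_mM,
            m$mineral %||% "?", m$conc_mM * m$sulfide_per_metal)
  }, character(1))
  lines <- c(
    "Whole-lake biosulfidogenesis dosing plan",
    "----------------------------------------",
    "Metal(loid) inventories:", inv,
    sprintf("Stoichiometric S(-II) demand: %.3f mM", plan$demand_mM),
    sprintf("Target S(-II) production:     %.3f mM", plan$target_mM),
    sprintf("Substrate yield ratio:        %.2f mM S(-II)/g", plan$yield_ratio),
    sprintf("Required dose:                %.3f g/L", plan$dose_g_l),
    sprintf("Treated volume:               %s m3 (%.1f ML)",
            format(plan$volume_m3, big.mark = ",", scientific = FALSE),
            plan$volume_ML),
    sprintf("Total substrate mass:         %.0f kg = %.1f t = %.1f US tons",
            plan$mass$kg, plan$mass$metric_tons, plan$mass$us_tons),
    sprintf("Volumetric requirement:       %.2f t/ML (%.2f US tons/Mgal)",
            plan$volumetric$t_per_ML, plan$volumetric$us_tons_per_mgal))
  if (!is.null(plan$densities)) {
    lines <- c(lines, "Advisory layer densities (mg/cm3):",
               sprintf("  %-10s %.0f", names(plan$densities), plan$densities))
  }
  lines
}

#' @export
print.dosing_plan <- function(x, ...) {
  cat(format_dosing_plan(x), sep = "\n")
  invisible(x)
}
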