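# The model's economic evidence table: unit costs (2025 USD), utilities,
# adverse-event incidences and disutilities, each with its plausible range
# and sampling distribution.

#' Default economic parameter set
#'
#' One row per parameter: internal `name`, the published `group`/`label`
#' pair, base `value`, `min`/`max` range and sampling `dist` (`beta`,
#' `gamma`, `normal` or `fixed`). Ranges without a published standard
#' deviation are plus/minus 25% around the base value. The best-supportive-care
#' row ships with an inconsistent published range (minimum above the base
#' value); it is repaired to plus/minus 25% with a warning.
#'
#' @param repair_bsc Repair the best-supportive-care range (default TRUE).
#' @return A tibble of class `econ_params`.
#' @export
econ_parameters <- function(repair_bsc = TRUE) {
  p <- tibble::tribble(
    ~name, ~group, ~label, ~value, ~min, ~max, ~dist,
    "ae_inc_dflot_diarrhea", "Risk for main adverse events in DFLOT group", "Diarrhea", 0.0630, 0.0473, 0.0788, "beta",
    "ae_inc_dflot_anemia", "Risk for main adverse events in DFLOT group", "Anemia", 0.0510, 0.0383, 0.0638, "beta",
    "ae_inc_dflot_neutropenia", "Risk for main adverse events in DFLOT group", "Neutropenia", 0.4090, 0.3068, 0.5113, "beta",
    "ae_inc_dflot_thrombocytopenia", "Risk for main adverse events in DFLOT group", "Thrombocytopenia", 0.0530, 0.0398, 0.0663, "beta",
    "ae_inc_flot_diarrhea", "Risk for main adverse events in FLOT group", "Diarrhea", 0.0600, 0.0450, 0.0750, "beta",
    "ae_inc_flot_anemia", "Risk for main adverse events in FLOT group", "Anemia", 0.0510, 0.0383, 0.0638, "beta",
    "ae_inc_flot_neutropenia", "Risk for main adverse events in FLOT group", "Neutropenia", 0.4460, 0.3345, 0.5575, "beta",
    "ae_inc_flot_thrombocytopenia", "Risk for main adverse events in FLOT group", "Thrombocytopenia", 0.0600, 0.0450, 0.0750, "beta",
    "util_efs", "Utility", "EFS", 0.797, 0.598, 0.996, "beta",
    "util_pd", "Utility", "PD", 0.577, 0.433, 0.721, "beta",
    "util_gastrectomy", "Utility", "Gastrectomy", 0.773, 0.580, 0.966, "beta",
    "disutil_diarrhea", "AEs disutility", "Diarrhea", 0.247, 0.164, 0.348, "beta",
    "disutil_anemia", "AEs disutility", "Anemia", 0.200, 0.150, 0.250, "beta",
    "disutil_neutropenia", "AEs disutility", "Neutropenia", 0.159, 0.106, 0.226, "beta",
    "disutil_thrombocytopenia", "AEs disutility", "Thrombocytopenia", 0.149, 0.101, 0.209, "beta",
    "ae_cost_diarrhea", "AEs cost per", "Diarrhea", 3928.00, 2946.00, 4910.00, "gamma",
    "ae_cost_anemia", "AEs cost per", "Anemia", 528.00, 396.00, 660.00, "gamma",
    "ae_cost_neutropenia", "AEs cost per", "Neutropenia", 18987.00, 14240.25, 23733.75, "gamma",
    "ae_cost_thrombocytopenia", "AEs cost per", "Thrombocytopenia", 96238.00, 72178.50, 120297.50, "gamma",
    "cost_durvalumab", "Drug cost per cycle", "Durvalumab", 12787.50, 9590.63, 15984.38, "gamma",
    "cost_fluorouracil", "Drug cost per cycle", "Fluorouracil", 35.40, 26.55, 44.26, "gamma",
    "cost_leucovorin", "Drug cost per cycle", "Leucovorin", 62.68, 47.01, 78.35, "gamma",
    "cost_oxaliplatin", "Drug cost per cycle", "Oxaliplatin", 61.42, 46.06, 76.77, "gamma",
    "cost_docetaxel", "Drug cost per cycle", "Docetaxel", 75.23, 56.42, 94.04, "gamma",
    "cost_ramucirumab", "Drug cost per cycle", "Ramucirumab", 20179.74, 15134.81, 25224.68, "gamma",
    "cost_paclitaxel", "Drug cost per cycle", "Paclitaxel", 50.50, 37.87, 63.12, "gamma",
    "cost_ct", "Administration cost per", "CT", 171.10, 128.33, 213.88, "gamma",
    "cost_visit_initial", "Administration cost per", "Ppps, initial visit", 165.44, 124.08, 206.80, "gamma",
    "cost_visit_subsequent", "Administration cost per", "Ppps, subsequent visit", 130.15, 97.61, 162.69, "gamma",
    "cost_cbc", "Administration cost per", "CBC", 19.00, 14.25, 23.75, "gamma",
    "cost_iv_short", "Administration cost per", "IV infusion 1h", 129.16, 96.87, 161.45, "gamma",
    "cost_iv_long", "Administration cost per", "IV infusion over 1h", 156.79, 117.59, 195.99, "gamma",
    "cost_gastrectomy", "Administration cost per", "Removal of stomach", 1910.80, 1433.10, 2388.49, "gamma",
    "cost_bsc", "Administration cost per", "Best supportive care", 16632.03, 16955.57, 28259.28, "gamma",
    "cost_hospice", "Administration cost per", "Hospice care", 4563.28, 3422.46, 5704.10, "gamma",
    "body_weight", "Patient", "Body weight (kg)", 84.70, 63.53, 105.88, "normal",
    "bsa", "Patient", "BSA (m^2)", 1.99, 1.49, 2.48, "normal",
    "gastrectomy_utility_cycles", "Patient", "Gastrectomy utility duration(cycle)", 13.00, 6.00, 20.00, "normal",
    "discount_rate", "Patient", "Discount rate, %", 0.03, 0.00, 0.05, "fixed"
  )
  if (repair_bsc) {
    i <- p$name == "cost_bsc"
    if (p$min[i] > p$value[i]) {
      warning("Best-supportive-care range has min > base value; repaired to ±25% around the base.",
              call. = FALSE)
      p$min[i] <- 0.75 * p$value[i]
      p$max[i] <- 1.25 * p$value[i]
    }
  }
  validate_econ_params(p)
  class(p) <- c("econ_params", class(p))
  p
}

validate_econ_params <- function(p) {
  util <- grepl("^(util_|disutil_|ae_inc_)", p$name)
  if (any(p$value[util] < 0 | p$value[util] > 1)) {
    stop("Utilities, disutilities and incidences must lie in [0, 1].", call. = FALSE)
  }
  costs <- grepl("^(cost_|ae_cost_)", p$name)
  if (any(p$value[costs] < 0)) stop("Costs must be non-negative.", call. = FALSE)
  bad_range <- p$min > p$value | p$max < p$value
  if (any(bad_range)) {
    warning("Range does not bracket the base value for: ",
            paste(p$name[bad_range], collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

#' Look up / modify a parameter value by internal name
#'
#' @param params An `econ_params` tibble.
#' @param name Internal parameter name(s).
#' @param value Replacement value (for `set_param`).
#' @return `param_value` returns the numeric value(s); `set_param` the
#'   modified table.
#' @export
param_value <- function(params, name) {
  i <- match(name, params$name)
  if (anyNA(i)) stop("Unknown parameter: ", paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  params$value[i]
}

#' @rdname param_value
#' @export
set_param <- function(params, name, value) {
  i <- match(name, params$name)
  if (anyNA(i)) stop("Unknown parameter: ", paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  params$value[i] <- value
  params
}

#' Read / write the parameter table as delimited text
#'
#' The file mirrors the published parameter table: columns `group`,
#' `label`, `value`, `min`, `max`, `dist`. Unknown group/label pairs are
#' rejected so silent typos cannot slip in.
#'
#' @param path File path (TSV).
#' @param params An `econ_params` tibble.
#' @return `read_econ_parameters` returns an `econ_params` tibble.
#' @export
read_econ_parameters <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    group = readr::col_character(), label = readr::col_character(),
    value = readr::col_double(), min = readr::col_double(),
    max = readr::col_double(), dist = readr::col_character()
  ))
  ref <- suppressWarnings(econ_parameters())
  key <- paste(tab$group, tab$label, sep = " / ")
  ref_key <- paste(ref$group, ref$label, sep = " / ")
  unknown <- setdiff(key, ref_key)
  if (length(unknown)) {
    stop("Unknown parameter rows: ", paste(unknown, collapse = "; "), call. = FALSE)
  }
  i <- match(ref_key, key)
  missing <- ref_key[is.na(i)]
  if (length(missing)) {
    stop("Missing parameter rows: ", paste(missing, collapse = "; "), call. = FALSE)
  }
  out <- ref
  out$value <- tab$value[i]
  out$min <- tab$min[i]
  out$max <- tab$max[i]
  out$dist <- tolower(tab$dist[i])
  validate_econ_params(out)
  out
}

#' @rdname read_econ_parameters
#' @export
write_econ_parameters <- function(params, path) {
  readr::write_tsv(params[, c("group", "label", "value", "min", "max", "dist")], path)
  invisible(path)
}

#' Mosteller body-surface area
#'
#' `sqrt(height_cm * weight_kg / 3600)` in square metres. (The square root
#' is essential: the published reference BSA of 1.99 m^2 at 84.7 kg is only
#' reproduced by the square-root form.)
#'
#' @param height_cm Height in centimetres, `> 0`.
#' @param weight_kg Weight in kilograms, `> 0`.
#' @return BSA in m^2.
#' @examples
#' mosteller_bsa(168.3, 84.7)  # ~1.99
#' @export
mosteller_bsa <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("Height and weight must be positive.", call. = FALSE)
  }
  sqrt(height_cm * weight_kg / 3600)
}
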