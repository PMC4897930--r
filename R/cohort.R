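# Cached IOTF cut-off table (packaged CSV with citation header).
.iotf_env <- new.env(parent = emptyenv())

#' IOTF BMI cut-off table
#'
#' The packaged International Obesity Task Force age- and sex-specific BMI
#' cut-offs for overweight and obesity at half-year ages 12 to 18. The
#' overweight (obesity) column passes through 25 (30) kg/m^2 at age 18, so
#' youth and adult classification agree at the boundary.
#'
#' @return Tibble with columns `age`, `sex`, `overweight`, `obesity`.
#' @export
iotf_table <- function() {
  if (is.null(.iotf_env$tab)) {
    path <- system.file("extdata", "iotf_cutoffs.csv", package = "microprev")
    .iotf_env$tab <- readr::read_csv(path, comment = "#",
                                     show_col_types = FALSE)
  }
  .iotf_env$tab
}

#' Age- and sex-specific overweight BMI cut-off
#'
#' Returns the BMI threshold above which a respondent counts as having
#' excess bodyweight: the adult value 25 kg/m^2 from age 18 up, and the IOTF
#' overweight cut-off at the nearest half-year of age for ages 12-17.
#'
#' @param age_years Numeric vector of ages (>= 12).
#' @param sex Character vector, `"M"` or `"F"` (recycled).
#' @return Numeric vector of BMI cut-offs.
#' @export
#' @examples
#' iotf_cutoff(c(12, 15, 40), c("M", "F", "M"))
iotf_cutoff <- function(age_years, sex) {
  n <- max(length(age_years), length(sex))
  age_years <- rep_len(age_years, n)
  sex <- rep_len(as.character(sex), n)
  if (!all(sex %in% .mp_sexes)) abort('`sex` must be "M" or "F".')
  tab <- iotf_table()
  out <- rep(25, n)
  juv <- age_years < 18
  if (any(juv)) {
    half_age <- pmin(pmax(round(age_years[juv] * 2) / 2, 12), 18)
    key <- paste(half_age, sex[juv])
    idx <- match(key, paste(tab$age, tab$sex))
    out[juv] <- tab$overweight[idx]
  }
  out
}

#' Classify current smoking from the raw survey response
#'
#' A respondent reporting daily or occasional smoking at the time of survey
#' is a current smoker; former and never smokers are not; a missing response
#' stays missing.
#'
#' @param smoking_response Character vector with values `daily`,
#'   `occasional`, `former`, `never`, or `missing` (NA also counts missing).
#' @return Integer vector: 1 (current smoker), 0 (not), or `NA` (missing).
#' @export
#' @examples
#' classify_current_smoker(c("daily", "former", "missing"))
classify_current_smoker <- function(smoking_response) {
  x <- as.character(smoking_response)
  x[is.na(x)] <- "missing"
  bad <- setdiff(unique(x), c("daily", "occasional", "former", "never",
                              "missing"))
  if (length(bad) > 0) {
    abort(paste0("Unrecognized smoking response(s): ",
                 paste(bad, collapse = ", ")))
  }
  dplyr::case_match(x,
    c("daily", "occasional") ~ 1L,
    c("former", "never") ~ 0L,
    "missing" ~ NA_integer_
  )
}

#' Classify excess bodyweight from self-reported height and weight
#'
#' Computes BMI = weight / height^2 and dichotomizes: adults (18+) at
#' BMI >= 25 kg/m^2, ages 12-17 at the IOTF age-sex overweight cut-off
#' (nearest half-year). Pregnant or lactating respondents are `"excluded"`;
#' missing height or weight gives `"missing"`. Heights above 3 m are
#' rejected as a centimetre/metre unit error rather than silently classified.
#'
#' @param height_m,weight_kg Numeric vectors (metres, kilograms); `NA`
#'   allowed.
#' @param age_years Numeric vector of ages >= 12.
#' @param sex `"M"`/`"F"` vector.
#' @param pregnant_or_lactating Logical vector (default all `FALSE`).
#' @return Character vector with values `"1"`, `"0"`, `"excluded"`,
#'   `"missing"`.
#' @export
#' @examples
#' classify_excess_bodyweight(1.7321, 75, 40, "M")  # BMI 25.0 -> "1"
classify_excess_bodyweight <- function(height_m, weight_kg, age_years, sex,
                                       pregnant_or_lactating = FALSE) {
  n <- max(length(height_m), length(weight_kg), length(age_years),
           length(sex), length(pregnant_or_lactating))
  height_m <- rep_len(height_m, n)
  weight_kg <- rep_len(weight_kg, n)
  age_years <- rep_len(age_years, n)
  sex <- rep_len(as.character(sex), n)
  preg <- rep_len(as.logical(pregnant_or_lactating), n)
  if (any(height_m <= 0, na.rm = TRUE) || any(weight_kg <= 0, na.rm = TRUE)) {
    abort("Nonpositive height or weight supplied.")
  }
  if (any(height_m > 3, na.rm = TRUE)) {
    abort("Height above 3 m: input looks like centimetres, expected metres.")
  }
  out <- rep("missing", n)
  preg[is.na(preg)] <- FALSE
  have <- !is.na(height_m) & !is.na(weight_kg)
  bmi <- weight_kg[have] / height_m[have]^2
  out[have] <- ifelse(bmi >= iotf_cutoff(age_years[have], sex[have]),
                      "1", "0")
  out[preg] <- "excluded"
  out
}

#' Derive analysis outcomes for a respondent table
#'
#' Adds the classified outcome columns to a respondent tibble: `smoker`
#' (0/1/NA) when `smoking_response` is present, and `excess_bodyweight`
#' (`"0"`/`"1"`/`"excluded"`/`"missing"`) when height and weight are present.
#' No record is dropped; exclusions and missingness stay explicit.
#'
#' @param respondents Respondent tibble.
#' @return The tibble with outcome column(s) added.
#' @export
derive_outcomes <- function(respondents) {
  if ("smoking_response" %in% names(respondents)) {
    respondents$smoker <- classify_current_smoker(respondents$smoking_response)
  }
  if (all(c("height_m", "weight_kg") %in% names(respondents))) {
    preg <- if ("pregnant_or_lactating" %in% names(respondents)) {
      respondents$pregnant_or_lactating
    } else FALSE
    respondents$excess_bodyweight <- classify_excess_bodyweight(
      respondents$height_m, respondents$weight_kg,
      respondents$age_years, respondents$sex, preg
    )
  }
  respondents
}

# Numeric 0/1/NA outcome vector for modelling; "excluded" becomes NA too,
# but the caller can count exclusions separately from the classified column.
.outcome_vector <- function(respondents, outcome) {
  col <- switch(outcome,
                current_smoking = "smoker",
                excess_bodyweight = "excess_bodyweight",
                abort("Unknown outcome."))
  if (!col %in% names(respondents)) {
    respondents <- derive_outcomes(respondents)
  }
  if (!col %in% names(respondents)) {
    abort(paste0("Cannot derive outcome `", outcome,
                 "`: raw response columns absent."))
  }
  x <- respondents[[col]]
  if (is.character(x)) x <- dplyr::case_match(x, "1" ~ 1L, "0" ~ 0L,
                                              .default = NA_integer_)
  as.integer(x)
}

#' Rescale design and bootstrap weights for pooled-cycle analysis
#'
#' Divides every design weight (and each bootstrap replicate weight) by the
#' number of pooled cycles, so the pooled weighted total equals the mean of
#' the per-cycle weighted totals and the pooled sample stays on the scale of
#' a single cycle's population. The alternative `"cycle_share"` method
#' multiplies each respondent's weight by their cycle's share of the total
#' weighted population instead.
#'
#' @param respondents Respondent tibble with `design_weight`, `cycle`, and
#'   optionally `boot_wt_*` columns.
#' @param n_cycles Number of pooled cycles K (> 0); every `cycle` value must
#'   be in `1..K`.
#' @param method `"divide_k"` (default) or `"cycle_share"`.
#' @return The tibble with a `pooled_weight` column added and the
#'   `boot_wt_*` columns rescaled identically.
#' @export
rescale_pooled_weights <- function(respondents, n_cycles,
                                   method = c("divide_k", "cycle_share")) {
  method <- match.arg(method)
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles <= 0) {
    abort("`n_cycles` must be a single positive number.")
  }
  if (!all(respondents$cycle %in% seq_len(n_cycles))) {
    abort("All `cycle` values must lie in 1..n_cycles.")
  }
  if (method == "divide_k") {
    fac <- rep(1 / n_cycles, nrow(respondents))
  } else {
    tot <- tapply(respondents$design_weight, respondents$cycle, sum)
    share <- tot / sum(tot)
    fac <- unname(share[as.character(respondents$cycle)])
  }
  respondents$pooled_weight <- respondents$design_weight * fac
  bw <- grep("^boot_wt_", names(respondents), value = TRUE)
  for (b in bw) respondents[[b]] <- respondents[[b]] * fac
  respondents
}
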