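#' Sire/dam constants for the 100-kg standardisation
#'
#' Backfat and age at 100 kg are standardised with sex-class-specific
#' constants: sires use A = 13.47, B = 0.1115 mm/kg and a correction-factor
#' multiplier of 1.826; dams use A = 15.65, B = 0.156 and 1.715.
#'
#' @param sexClass character vector of "sire" / "dam".
#' @return list of vectors A, B, cfMultiplier aligned with `sexClass`.
#' @export
adjustmentConstants <- function(sexClass) {
  sexClass <- as.character(sexClass)
  bad <- !sexClass %in% c("sire", "dam")
  if (any(bad))
    stop("unknown sex class: ", paste(unique(sexClass[bad]), collapse = ", "),
         " (must be 'sire' or 'dam')")
  sire <- sexClass == "sire"
  list(A = ifelse(sire, 13.47, 15.65),
       B = ifelse(sire, 0.1115, 0.156),
       cfMultiplier = ifelse(sire, 1.826, 1.715))
}

#' Standardise measured backfat thickness to 100 kg live weight
#'
#' BFT100 = measured BFT x A / (A + B x (measured BW - 100)), with A and B
#' taken from the sex class. The mapping is the identity at 100 kg and
#' decreases in body weight for fixed measured backfat.
#'
#' @param measuredBft measured backfat, mm.
#' @param measuredBw measured body weight, kg.
#' @param sexClass "sire" or "dam" (recycled).
#' @param id optional record identifiers used in error messages.
#' @return backfat standardised to 100 kg, mm.
#' @export
adjustBft <- function(measuredBft, measuredBw, sexClass, id = NULL) {
  cons <- adjustmentConstants(rep_len(sexClass, length(measuredBft)))
  den <- cons$A + cons$B * (measuredBw - 100)
  if (any(den <= 0)) {
    bad <- which(den <= 0)
    lab <- if (!is.null(id)) paste(id[bad], collapse = ", ") else
      paste("record", paste(bad, collapse = ", "))
    stop("backfat correction denominator non-positive for ", lab)
  }
  measuredBft * cons$A / den
}

#' Standardise age to 100 kg and compute average daily gain
#'
#' CF = multiplier x measured BW / measured age; AGE100 = measured age -
#' (measured BW - 100)/CF; ADG100 = 100/AGE100 (kg/day).
#'
#' @inheritParams adjustBft
#' @param measuredAge measured age, days.
#' @return data.frame with columns `age100_days` and `adg100_kg_per_day`.
#' @export
adjustAgeAdg <- function(measuredBw, measuredAge, sexClass, id = NULL) {
  stopifnot(all(measuredBw > 0), all(measuredAge > 0))
  cons <- adjustmentConstants(rep_len(sexClass, length(measuredBw)))
  cf <- cons$cfMultiplier * measuredBw / measuredAge
  age100 <- measuredAge - (measuredBw - 100) / cf
  if (any(age100 <= 0)) {
    bad <- which(age100 <= 0)
    lab <- if (!is.null(id)) paste(id[bad], collapse = ", ") else
      paste("record", paste(bad, collapse = ", "))
    stop("standardised age non-positive for ", lab)
  }
  data.frame(age100_days = age100, adg100_kg_per_day = 100 / age100)
}

#' Standardise a raw measurement table
#'
#' Applies [adjustBft()] and [adjustAgeAdg()] to a raw test-station table.
#' Records with missing measurements are rejected (they are expected to be
#' excluded upstream); animals of unknown sex class raise an error rather
#' than being defaulted.
#'
#' @param raw data.frame with columns sample_id, sex_class, measured_bft_mm,
#'   measured_bw_kg, measured_age_days and optionally birth_weight_kg.
#' @return data.frame with sample_id, bft100_mm, age100_days,
#'   adg100_kg_per_day, bw_kg, birth_weight_kg.
#' @export
adjustPhenotypes <- function(raw) {
  need <- c("sample_id", "sex_class", "measured_bft_mm", "measured_bw_kg",
            "measured_age_days")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(raw[need]))
    stop("raw table contains missing measurements; exclude them first")
  stopifnot(all(raw$measured_bw_kg > 0), all(raw$measured_age_days > 0),
            all(raw$measured_bft_mm >= 0))
  bft <- adjustBft(raw$measured_bft_mm, raw$measured_bw_kg, raw$sex_class,
                   id = raw$sample_id)
  aa <- adjustAgeAdg(raw$measured_bw_kg, raw$measured_age_days,
                     raw$sex_class, id = raw$sample_id)
  data.frame(
    sample_id = raw$sample_id,
    bft100_mm = bft,
    age100_days = aa$age100_days,
    adg100_kg_per_day = aa$adg100_kg_per_day,
    bw_kg = raw$measured_bw_kg,
    birth_weight_kg = if ("birth_weight_kg" %in% names(raw))
      raw$birth_weight_kg else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Coefficient of variation in percent
#'
#' @param mean trait mean.
#' @param sd trait standard deviation (n-1 denominator).
#' @return 100 * sd / mean.
#' @export
cvPercent <- function(mean, sd) 100 * sd / mean

#' Summary statistics for a trait
#'
#' Mean, sample standard deviation (n-1 denominator), coefficient of
#' variation in percent, maximum and minimum — the usual descriptive row of
#' a breeding-program phenotype table.
#'
#' @param values numeric vector, no missing values, length >= 2.
#' @param trait trait label.
#' @return one-row data.frame: trait, n, mean, sd, cv_percent, max, min.
#' @export
summarizeTrait <- function(values, trait = "trait") {
  if (anyNA(values)) stop("missing values must be excluded upstream")
  n <- length(values)
  if (n < 2) stop("need at least 2 observations")
  m <- mean(values)
  s <- sd(values)
  data.frame(trait = trait, n = n, mean = m, sd = s,
             cv_percent = cvPercent(m, s),
             max = max(values), min = min(values),
             stringsAsFactors = FALSE)
}
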