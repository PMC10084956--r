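#' Body mass index from weight and height
#'
#' BMI = weight (kg) / height (m)^2.
#'
#' @param weight_kg body weight in kilograms (> 0).
#' @param height_m standing height in metres (> 0).
#' @return BMI in kg/m^2 (vectorised).
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("weight_kg must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(height_m)) || any(height_m <= 0)) {
    stop("height_m must be finite and positive", call. = FALSE)
  }
  weight_kg / height_m^2
}

nutrition_levels <- c("underweight", "normal", "overweight", "obese")

#' WHO four-category BMI classification
#'
#' Underweight if BMI < 18.5; normal if 18.5 <= BMI <= 24.9; overweight if
#' 24.9 < BMI <= 29.9; obese if BMI > 29.9. The boundary values 24.9 and 29.9
#' belong to the lower category (closed upper bounds). Values outside the
#' plausibility window are set to `NA` and counted via `message()` — the
#' survey instrument cannot produce them.
#'
#' @param bmi numeric vector of finite, positive BMI values (kg/m^2).
#' @param plausible length-2 numeric window of plausible BMI values
#'   (default `c(10, 60)`); values outside become `NA`.
#' @return Factor with levels underweight/normal/overweight/obese.
#' @export
classify_bmi <- function(bmi, plausible = c(10, 60)) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("bmi must be finite and positive", call. = FALSE)
  }
  out <- ifelse(bmi < 18.5, "underweight",
         ifelse(bmi <= 24.9, "normal",
         ifelse(bmi <= 29.9, "overweight", "obese")))
  implausible <- bmi < plausible[1] | bmi > plausible[2]
  if (any(implausible)) {
    message(sprintf("%d implausible BMI value(s) outside [%g, %g] set to NA",
                    sum(implausible), plausible[1], plausible[2]))
    out[implausible] <- NA
  }
  factor(out, levels = nutrition_levels)
}

#' Recode nutrition category to the binary DBM indicator
#'
#' The double burden of malnutrition outcome is 1 for any malnutrition
#' (underweight, overweight or obese) and 0 for normal weight.
#'
#' @param category factor/character of nutrition categories.
#' @return Integer vector in \{0, 1\} (`NA` propagates).
#' @export
recode_dbm <- function(category) {
  x <- as.character(category)
  bad <- !is.na(x) & !x %in% nutrition_levels
  if (any(bad)) stop("unknown nutrition category", call. = FALSE)
  ifelse(is.na(x), NA_integer_, as.integer(x != "normal"))
}

#' Weighted prevalence of the four nutrition categories and of DBM
#'
#' @param table a `survey_table` with `category` assigned and weights present;
#'   rows with `NA` category are excluded (counted via `message()`).
#' @return data.frame with rows underweight/normal/overweight/obese/dbm and
#'   columns `weighted_n` and `percent`; category percentages sum to 100 and
#'   the DBM row is the sum of the three non-normal rows.
#' @export
prevalence_table <- function(table) {
  if (is.null(table$category)) stop("category column missing; classify BMI first", call. = FALSE)
  w <- table$weight
  keep <- !is.na(table$category)
  if (any(!keep)) message(sprintf("%d row(s) with missing category excluded", sum(!keep)))
  w <- w[keep]
  cat <- factor(table$category[keep], levels = nutrition_levels)
  tot <- sum(w)
  if (tot <= 0) stop("total weight is zero", call. = FALSE)
  wn <- vapply(nutrition_levels, function(l) sum(w[cat == l]), 0)
  pct <- 100 * wn / tot
  data.frame(
    category = c(nutrition_levels, "dbm"),
    weighted_n = c(wn, sum(wn[nutrition_levels != "normal"])),
    percent = c(pct, sum(pct[nutrition_levels != "normal"])),
    row.names = NULL
  )
}
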