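# Gender-Age-Physiology (GAP) index: points (0-8) and stage (1-3).
#
# Point table (frozen constants of the published index):
#   Gender: female 0, male 1
#   Age:    <=60 y 0; 61-65 y 1; >65 y 2
#   FVC %predicted:  >=75 0; 50-74 1; <50 2
#   DLco %predicted: >=55 0; 36-54 1; <=35 2; unable to perform 3
# Stage: points 0-3 -> 1, 4-5 -> 2, 6-8 -> 3.

gap_gender_points <- function(sex) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female", "m", "f")))
    stopf("sex must be 'male' or 'female'")
  ifelse(sex %in% c("male", "m"), 1L, 0L)
}

gap_age_points <- function(age) {
  ifelse(age <= 60, 0L, ifelse(age <= 65, 1L, 2L))
}

gap_fvc_points <- function(fvc) {
  ifelse(fvc >= 75, 0L, ifelse(fvc >= 50, 1L, 2L))
}

gap_dlco_points <- function(dlco) {
  # NA encodes "unable to perform"
  ifelse(is.na(dlco), 3L,
         ifelse(dlco >= 55, 0L, ifelse(dlco >= 36, 1L, 2L)))
}

#' GAP points and stage
#'
#' Computes the Gender-Age-Physiology prognostic index for idiopathic
#' pulmonary fibrosis: 0-8 points from sex, age, FVC %predicted and DLco
#' %predicted, mapped to stages 1 (0-3), 2 (4-5) and 3 (6-8); stage 3 is
#' the worst-case scenario. All arguments are vectorised.
#'
#' @param sex `"male"`/`"female"` (or `"m"`/`"f"`).
#' @param age_years age in years (18-110).
#' @param fvc_pct_pred forced vital capacity, percent of predicted (0-200).
#' @param dlco_pct_pred diffusing capacity, percent of predicted; `NA`
#'   means the patient was unable to perform the test (3 points).
#' @return data.frame with columns `points` (integer 0-8) and `stage`
#'   (integer 1-3).
#' @examples
#' gap_score("male", 68, 89, 63)      # 3 points, stage 1
#' gap_score("male", 70, 45, NA)      # 8 points, stage 3
#' @export
gap_score <- function(sex, age_years, fvc_pct_pred, dlco_pct_pred) {
  n <- max(length(sex), length(age_years), length(fvc_pct_pred),
           length(dlco_pct_pred))
  sex <- rep_len(sex, n); age_years <- rep_len(age_years, n)
  fvc_pct_pred <- rep_len(fvc_pct_pred, n)
  dlco_pct_pred <- rep_len(dlco_pct_pred, n)
  if (anyNA(sex) || anyNA(age_years) || anyNA(fvc_pct_pred))
    stopf("missing sex, age or FVC: GAP undefined (only DLco may be NA)")
  if (any(age_years < 18 | age_years > 110))
    stopf("age_years outside [18, 110]")
  if (any(fvc_pct_pred <= 0 | fvc_pct_pred >= 200))
    stopf("fvc_pct_pred outside (0, 200)")
  if (any(!is.na(dlco_pct_pred) &
            (dlco_pct_pred <= 0 | dlco_pct_pred >= 200)))
    stopf("dlco_pct_pred outside (0, 200)")
  points <- gap_gender_points(sex) + gap_age_points(age_years) +
    gap_fvc_points(fvc_pct_pred) + gap_dlco_points(dlco_pct_pred)
  data.frame(points = as.integer(points), stage = gap_stage(points))
}

#' Map GAP points to stage
#' @param points integer vector in 0-8.
#' @return integer stage 1, 2 or 3.
#' @export
gap_stage <- function(points) {
  if (any(points < 0 | points > 8)) stopf("GAP points must be in 0..8")
  as.integer(ifelse(points <= 3, 1L, ifelse(points <= 5, 2L, 3L)))
}

#' Read a clinical table and append GAP points/stage
#'
#' Expects a CSV with header `patient_id, sex, age_years, fvc_pct_pred,
#' dlco_pct_pred`; `NA` in the DLco column means unable to perform.
#'
#' @param path CSV path.
#' @return data.frame with the input columns plus `gap_points`, `gap_stage`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("clinical table does not exist: %s", path)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "sex", "age_years", "fvc_pct_pred", "dlco_pct_pred")
  missing <- setdiff(need, names(tbl))
  if (length(missing))
    stopf("clinical table is missing column(s): %s",
          paste(missing, collapse = ", "))
  g <- gap_score(tbl$sex, tbl$age_years, tbl$fvc_pct_pred, tbl$dlco_pct_pred)
  tbl$gap_points <- g$points
  tbl$gap_stage <- g$stage
  tbl
}
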