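# MRI-based ordinal scoring system for pernicious placenta previa (PPP).
#
# Eleven items, each scored 0/1/2 by severity, except the cesarean-history
# item which is 1/2 (every eligible patient has at least one prior cesarean).
# The total score (1..22) grades the risk of placenta accreta spectrum (PAS)
# involvement.

#' Canonical score item names
#'
#' Returns the eleven score item identifiers in their canonical order:
#' ten T2-weighted MRI signs followed by the prior-cesarean-count item.
#' These names are the CSV column contract for cohort files.
#'
#' @return Character vector of length 11.
#' @export
#' @examples
#' mri_score_items()
mri_score_items <- function() {
  c("placenta_position",
    "placental_uterine_bulge",
    "placental_heterogeneity",
    "t2_dark_bands",
    "abnormal_intraplacental_vascularity",
    "abnormal_placental_bed_vascularization",
    "loss_of_t2_hypointense_interface",
    "bladder_wall_interruption",
    "penetrating_placenta_implantation",
    "myometrial_thinning_interruption",
    "previous_cesarean_deliveries_item")
}

#' PAS class levels
#'
#' The four placenta accreta spectrum classes in increasing order of villous
#' invasion depth: no PAS, placental adhesion (superficial myometrium),
#' placental implantation (deep myometrium), placenta percreta (through the
#' serosa).
#'
#' @return Character vector `c("non_pas", "pa", "pi", "pp")`.
#' @export
pas_levels <- function() c("non_pas", "pa", "pi", "pp")

#' Coerce a vector to an ordered PAS factor
#'
#' @param x Character or factor vector of PAS labels.
#' @return Ordered factor with levels `pas_levels()`.
#' @export
as_pas_class <- function(x) {
  x <- tolower(as.character(x))
  bad <- setdiff(unique(x), pas_levels())
  if (length(bad) > 0) {
    stop("unknown PAS class label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(pas_levels(), collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = pas_levels(), ordered = TRUE)
}

# Allowed value set per item. All items admit {0,1,2} except the cesarean
# item, which is never 0: inclusion requires a cesarean history.
item_allowed_values <- function(item) {
  if (item == "previous_cesarean_deliveries_item") c(1L, 2L) else c(0L, 1L, 2L)
}

#' Validate one patient's score items
#'
#' Checks that all eleven items are present, integer-valued and within their
#' allowed sets ({0,1,2} for the ten MRI signs, {1,2} for the cesarean item).
#' Missing or out-of-range items are errors naming the offending item; no
#' imputation or coercion is performed.
#'
#' @param features Named numeric vector or single-row list/data.frame holding
#'   the eleven items of [mri_score_items()].
#' @return The validated features as a named integer vector, invisibly usable
#'   by [compute_total_score()].
#' @export
validate_features <- function(features) {
  if (is.data.frame(features)) {
    if (nrow(features) != 1L) {
      stop("'features' data.frame must have exactly one row", call. = FALSE)
    }
    features <- unlist(features[1, , drop = TRUE])
  }
  features <- unlist(features)
  items <- mri_score_items()
  missing_items <- setdiff(items, names(features))
  if (length(missing_items) > 0) {
    stop("missing score item(s): ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  features <- features[items]
  for (item in items) {
    v <- features[[item]]
    if (is.na(v) || !is.numeric(v) || v != as.integer(v) ||
        !(as.integer(v) %in% item_allowed_values(item))) {
      stop("invalid value for score item '", item, "': ", v,
           " (allowed: ", paste(item_allowed_values(item), collapse = ", "),
           ")", call. = FALSE)
    }
  }
  stats::setNames(as.integer(features), items)
}

#' Compute a patient's total PPP score
#'
#' Sums the eleven validated ordinal items. The total lies in 1..22: the
#' minimum is forced by the cesarean item (always at least 1 point), the
#' maximum is 10 x 2 + 2.
#'
#' @inheritParams validate_features
#' @return Integer total score in `[1, 22]`.
#' @export
#' @examples
#' f <- setNames(c(rep(0, 10), 1), mri_score_items())
#' compute_total_score(f)  # 1, the minimum
compute_total_score <- function(features) {
  sum(validate_features(features))
}

#' Score a cohort
#'
#' Computes the total score for every patient in a cohort table, preserving
#' input order.
#'
#' @param records Cohort data.frame: `patient_id`, the eleven item columns of
#'   [mri_score_items()], `pas_class`, `blood_loss_ml` (see
#'   [read_cohort()] for the CSV contract).
#' @return data.frame with columns `patient_id`, `total_score`, `pas_class`
#'   (ordered factor), `blood_loss_ml`; one row per input record.
#' @export
score_cohort <- function(records) {
  records <- validate_cohort(records)
  items <- mri_score_items()
  scores <- vapply(seq_len(nrow(records)), function(i) {
    tryCatch(
      compute_total_score(unlist(records[i, items])),
      error = function(e) {
        stop("patient '", records$patient_id[i], "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }, integer(1))
  data.frame(
    patient_id = records$patient_id,
    total_score = scores,
    pas_class = as_pas_class(records$pas_class),
    blood_loss_ml = records$blood_loss_ml,
    stringsAsFactors = FALSE
  )
}

#' Validate a cohort table
#'
#' Enforces the cohort contract: unique patient ids, all eleven item columns
#' present with in-range values, valid PAS labels, strictly positive blood
#' loss, and (when present) gestational age within the 28-39 week inclusion
#' window.
#'
#' @param records Cohort data.frame.
#' @return The validated data.frame (invisible changes: none).
#' @export
validate_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("cohort must be a non-empty data.frame", call. = FALSE)
  }
  required <- c("patient_id", mri_score_items(), "pas_class", "blood_loss_ml")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dup <- records$patient_id[duplicated(records$patient_id)]
  if (length(dup) > 0) {
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  as_pas_class(records$pas_class)  # errors on unknown labels
  if (any(is.na(records$blood_loss_ml)) || any(records$blood_loss_ml <= 0)) {
    bad <- records$patient_id[is.na(records$blood_loss_ml) |
                                records$blood_loss_ml <= 0]
    stop("blood_loss_ml must be positive; offending patient(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("gestational_age_weeks" %in% names(records)) {
    ga <- records$gestational_age_weeks
    bad <- !is.na(ga) & (ga < 28 | ga > 39)
    if (any(bad)) {
      stop("gestational_age_weeks outside the 28-39 week inclusion window ",
           "for patient(s): ", paste(records$patient_id[bad], collapse = ", "),
           call. = FALSE)
    }
  }
  records
}

#' Read a cohort CSV
#'
#' Reads a UTF-8, comma-separated cohort file with a header row: `patient_id`,
#' the eleven item columns in [mri_score_items()] order, `pas_class` in
#' `{non_pas, pa, pi, pp}`, `blood_loss_ml`, and optionally `age_years`,
#' `gestational_age_weeks`, `neonatal_weight_g`,
#' `previa_type` in `{complete, low}`. The table is validated on read.
#'
#' @param path Path to the CSV file.
#' @return Validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  records$patient_id <- as.character(records$patient_id)
  validate_cohort(records)
}

#' Write a cohort CSV
#'
#' @param records Cohort data.frame (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  records <- validate_cohort(records)
  records$pas_class <- as.character(records$pas_class)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
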