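# Derivation of the two alcohol phenotypes from raw questionnaire fields.

#' Units of alcohol per reported drink, by beverage type
#'
#' Standard multipliers converting a count of drinks of each beverage into
#' units of alcohol: beer/cider 2.6, white wine 1.5, red wine 1.5,
#' fortified wine 1.1, spirits 1 and other 1.5.
#'
#' @return Named numeric vector of units per drink.
#' @export
drink_unit_table <- function() {
  c("beer/cider" = 2.6, "white wine" = 1.5, "red wine" = 1.5,
    "fortified wine" = 1.1, "spirits" = 1, "other" = 1.5)
}

.pheno_levels <- c("case", "control", "missing")

#' Assign the heavy-drinking phenotype from 24-hour dietary recall
#'
#' Each completed recall occasion yields an estimated daily intake in units
#' (sum of drink counts times the per-beverage multiplier). A subject is a
#' case if, on any completed occasion, seven times the daily intake strictly
#' exceeds 50 units (males) or 35 units (females); a control if they
#' completed at least one occasion without ever exceeding the limit; and
#' missing if they never completed an occasion. The comparison is strict: a
#' projected weekly intake exactly at the limit is a control.
#'
#' @param drinks Long-format data.frame of reported drinks with columns
#'   `subject`, `occasion`, `beverage`, `count` (non-negative). Occasions
#'   appearing here are treated as completed even if absent from
#'   `completed`.
#' @param completed Data.frame with columns `subject`, `occasion` listing
#'   completed recall occasions (including those with no drinks reported).
#' @param sex Data.frame with columns `subject`, `sex` (`"male"` or
#'   `"female"`); its subjects define the output universe.
#' @param units Named units-per-drink vector, see [drink_unit_table()].
#'   Reported beverages absent from it are an error.
#' @param male_limit,female_limit Weekly unit thresholds (strictly exceeded
#'   implies case).
#' @return Data.frame with columns `subject`, `status` (factor
#'   case/control/missing) and `max_weekly` (highest projected weekly
#'   intake over completed occasions; `NA` when missing).
#' @export
assign_heavy_drinking <- function(drinks, completed, sex,
                                  units = drink_unit_table(),
                                  male_limit = 50, female_limit = 35) {
  stopifnot(all(c("subject", "occasion", "beverage", "count") %in% names(drinks)),
            all(c("subject", "occasion") %in% names(completed)),
            all(c("subject", "sex") %in% names(sex)))
  if (any(units <= 0)) stop("units per drink must be positive")
  if (!all(sex$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (nrow(drinks) > 0 && any(is.na(drinks$count) | drinks$count < 0)) {
    stop("drink counts must be non-negative")
  }
  unknown <- setdiff(unique(drinks$beverage), names(units))
  if (length(unknown) > 0) {
    stop("unknown beverage type(s): ", paste(unknown, collapse = ", "))
  }

  occ_key <- function(s, o) paste(s, o, sep = "\r")
  all_occ <- unique(rbind(completed[c("subject", "occasion")],
                          drinks[c("subject", "occasion")]))
  daily <- numeric(nrow(all_occ))
  names(daily) <- occ_key(all_occ$subject, all_occ$occasion)
  if (nrow(drinks) > 0) {
    contrib <- drinks$count * units[drinks$beverage]
    got <- tapply(contrib, occ_key(drinks$subject, drinks$occasion), sum)
    daily[names(got)] <- got
  }
  weekly <- 7 * daily
  max_weekly <- tapply(weekly, all_occ$subject, max)

  subj <- sex$subject
  mw <- as.numeric(max_weekly[match(subj, names(max_weekly))])
  limit <- ifelse(sex$sex == "male", male_limit, female_limit)
  status <- ifelse(is.na(mw), "missing",
                   ifelse(mw > limit, "case", "control"))
  data.frame(subject = subj,
             status = factor(status, levels = .pheno_levels),
             max_weekly = mw,
             stringsAsFactors = FALSE)
}

#' Assign the problem-drinking phenotype from mental-health questionnaire
#'
#' A subject who completed the questionnaire is a case if they answered Yes
#' to any of the three dependence items (physically dependent on alcohol;
#' relative/friend/doctor concerned or suggested cutting down; addicted to
#' alcohol), or selected "Monthly" or a more frequent response on any of the
#' five adverse-experience frequency items (failed expectations, memory
#' blackout, guilt/remorse, morning drinking, unable to stop). Completers
#' meeting no criterion are controls; non-completers are missing. Blank
#' (`NA`) answers among completers count as non-endorsement.
#'
#' @param responses Data.frame with columns `subject`, `completed`
#'   (logical), three yes/no columns `dependent`, `concerned`, `addicted`
#'   (values `"Yes"`, `"No"` or `NA`) and five frequency columns
#'   `failed_expectations`, `memory_blackout`, `guilt`, `morning_drinking`,
#'   `unable_to_stop` whose values belong to `frequency_levels` (or `NA`).
#' @param frequency_levels Ordered character vector of the response scale,
#'   least frequent first. Supplied rather than hard-coded so any
#'   questionnaire coding dialect can be declared.
#' @param case_level The least frequent level that still qualifies as a
#'   case (default `"Monthly"`); must appear in `frequency_levels`.
#' @return Data.frame with columns `subject`, `status` (factor
#'   case/control/missing).
#' @export
assign_problem_drinking <- function(responses,
                                    frequency_levels = c("Never",
                                                         "Less than monthly",
                                                         "Monthly", "Weekly",
                                                         "Daily or almost daily"),
                                    case_level = "Monthly") {
  yes_no_cols <- c("dependent", "concerned", "addicted")
  freq_cols <- c("failed_expectations", "memory_blackout", "guilt",
                 "morning_drinking", "unable_to_stop")
  stopifnot(all(c("subject", "completed", yes_no_cols, freq_cols) %in%
                  names(responses)))
  if (!case_level %in% frequency_levels) {
    stop("case_level must be one of the declared frequency levels")
  }
  yn <- as.matrix(responses[yes_no_cols])
  if (!all(yn %in% c("Yes", "No", NA))) {
    stop("yes/no items must be 'Yes', 'No' or NA")
  }
  fr <- as.matrix(responses[freq_cols])
  bad <- setdiff(unique(as.vector(fr)), c(frequency_levels, NA))
  if (length(bad) > 0) {
    stop("unknown frequency level(s): ", paste(bad, collapse = ", "),
         "\ndeclared scale: ", paste(frequency_levels, collapse = " < "))
  }
  cutoff <- match(case_level, frequency_levels)
  rank <- matrix(match(fr, frequency_levels), nrow = nrow(fr))
  any_yes <- rowSums(yn == "Yes", na.rm = TRUE) > 0
  any_freq <- rowSums(rank >= cutoff, na.rm = TRUE) > 0
  status <- ifelse(!responses$completed, "missing",
                   ifelse(any_yes | any_freq, "case", "control"))
  data.frame(subject = responses$subject,
             status = factor(status, levels = .pheno_levels),
             stringsAsFactors = FALSE)
}

#' Convert a phenotype assignment to a 1/0/NA status vector
#'
#' @param assignment Data.frame from [assign_heavy_drinking()] or
#'   [assign_problem_drinking()].
#' @return Integer vector named by subject: 1 case, 0 control, `NA` missing.
#' @export
phenotype_status <- function(assignment) {
  s <- c(case = 1L, control = 0L, missing = NA)[as.character(assignment$status)]
  names(s) <- assignment$subject
  s
}
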