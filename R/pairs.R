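#' Build consecutive visit-pairs from a person-visit table
#'
#' Constructs all (index, next) pairs of consecutive study visits per person
#' in which the two visit dates are at most \code{max_gap} days apart and a
#' cART regimen was reported at the index visit. A person contributes
#' overlapping pairs: visits (1,2), (2,3), and so on.
#'
#' @param visits Data frame with columns \code{id}, \code{visit} (0-based
#'   integer index), \code{date} (\code{Date}) and \code{regimen} (regimen
#'   string parseable by [parse_regimen()], or \code{NA}/\code{""} for no
#'   reported ART). Additional columns are carried along with \code{_i} /
#'   \code{_next} suffixes when listed in \code{carry}.
#' @param max_gap Maximum gap in days between the paired visits ("within one
#'   year" is interpreted as 365 days).
#' @param carry Character vector of extra column names to carry from both
#'   visits into the pair table.
#' @return Data frame with one row per eligible pair: \code{id},
#'   \code{visit_i}, \code{visit_next}, \code{date_i}, \code{date_next},
#'   \code{gap} (days), \code{regimen_i}, \code{regimen_next},
#'   \code{same_regimen}, plus carried columns.
#' @export
build_visit_pairs <- function(visits, max_gap = 365, carry = character(0)) {
  stopifnot(all(c("id", "visit", "date", "regimen") %in% names(visits)))
  visits <- visits[order(visits$id, visits$visit), , drop = FALSE]
  n <- nrow(visits)
  if (n < 2L) return(.empty_pairs(carry))
  idx <- seq_len(n - 1L)
  same_person <- visits$id[idx] == visits$id[idx + 1L]
  consecutive <- visits$visit[idx + 1L] == visits$visit[idx] + 1L
  gap <- as.numeric(visits$date[idx + 1L] - visits$date[idx])
  reg_i <- as.character(visits$regimen[idx])
  on_cart <- !is.na(reg_i) & nzchar(reg_i) &
    vapply(reg_i, function(r) {
      if (is.na(r) || !nzchar(r)) return(FALSE)
      tryCatch(is_cart(r), error = function(e) FALSE)
    }, logical(1))
  keep <- which(same_person & consecutive & gap <= max_gap & on_cart)
  if (!length(keep)) return(.empty_pairs(carry))
  reg_next <- as.character(visits$regimen[keep + 1L])
  pairs <- data.frame(
    id = visits$id[keep],
    visit_i = visits$visit[keep],
    visit_next = visits$visit[keep + 1L],
    date_i = visits$date[keep],
    date_next = visits$date[keep + 1L],
    gap = gap[keep],
    regimen_i = reg_i[keep],
    regimen_next = reg_next,
    stringsAsFactors = FALSE
  )
  pairs$same_regimen <- mapply(function(a, b) {
    if (is.na(b) || !nzchar(b)) return(FALSE)
    same_regimen(a, b)
  }, pairs$regimen_i, pairs$regimen_next, USE.NAMES = FALSE)
  for (cc in carry) {
    pairs[[paste0(cc, "_i")]] <- visits[[cc]][keep]
    pairs[[paste0(cc, "_next")]] <- visits[[cc]][keep + 1L]
  }
  rownames(pairs) <- NULL
  pairs
}

.empty_pairs <- function(carry) {
  out <- data.frame(
    id = character(0), visit_i = integer(0), visit_next = integer(0),
    date_i = as.Date(character(0)), date_next = as.Date(character(0)),
    gap = numeric(0), regimen_i = character(0), regimen_next = character(0),
    same_regimen = logical(0), stringsAsFactors = FALSE
  )
  for (cc in carry) {
    out[[paste0(cc, "_i")]] <- logical(0)
    out[[paste0(cc, "_next")]] <- logical(0)
  }
  out
}

#' Derive the switching outcome for visit-pairs
#'
#' Switching occurred if the regimen reported at the next visit differs (as a
#' drug-code set) from the index regimen, or if no ART was reported at the
#' next visit (discontinuation).
#'
#' @param regimen_i,regimen_next Character vectors of regimen strings;
#'   \code{NA} or \code{""} in \code{regimen_next} means ART was discontinued.
#' @return Logical vector.
#' @export
derive_switching <- function(regimen_i, regimen_next) {
  mapply(function(a, b) {
    if (is.na(b) || !nzchar(b)) return(TRUE)
    !same_regimen(a, b)
  }, as.character(regimen_i), as.character(regimen_next), USE.NAMES = FALSE)
}

#' Derive the adherence outcome for visit-pairs
#'
#' Complete (100\%) adherence, assessed at the next visit, is defined only for
#' pairs in which the same regimen was reported at both visits; otherwise the
#' outcome is not applicable (\code{NA}).
#'
#' @param same_regimen Logical vector: same drug-code set at both visits.
#' @param adherent_next Logical/0-1 vector: 100\% self-reported adherence over
#'   the 4-day recall at the next visit (see [adherence_full()]).
#' @return Logical vector with \code{NA} where not applicable.
#' @export
derive_adherence <- function(same_regimen, adherent_next) {
  out <- ifelse(same_regimen, as.logical(adherent_next), NA)
  as.logical(out)
}

#' 100\% adherence from per-drug recall
#'
#' Strict rule on the 4-day recall: complete adherence requires every
#' prescribed drug to have been taken on every prescribed day.
#'
#' @param days_taken Numeric vector, days each drug was taken.
#' @param days_prescribed Days in the recall window (default 4).
#' @return Logical scalar; \code{NA} if any report is missing.
#' @export
adherence_full <- function(days_taken, days_prescribed = 4) {
  if (any(is.na(days_taken))) return(NA)
  all(days_taken >= days_prescribed)
}

#' Derive the HIV RNA suppression outcome
#'
#' Suppression is a strictly-below-threshold rule on the plasma HIV RNA
#' measurement. Assay-floor ("below detection limit") readings count as
#' suppressed whenever the assay limit does not exceed the analysis threshold;
#' a floor reading whose limit exceeds the threshold is indeterminate
#' (\code{NA}).
#'
#' @param hiv_rna Numeric vector of copies/mL.
#' @param threshold Analysis threshold in copies/mL (20 for effectiveness
#'   analyses; 50 for the long trend era).
#' @param below_limit Logical vector: reading is at the assay floor.
#' @param limit Assay lower detection limit(s), copies/mL.
#' @return Logical vector.
#' @export
derive_suppression <- function(hiv_rna, threshold = 20,
                               below_limit = FALSE, limit = 20) {
  n <- max(length(hiv_rna), length(below_limit))
  hiv_rna <- rep_len(hiv_rna, n)
  below_limit <- rep_len(below_limit, n)
  limit <- rep_len(limit, n)
  out <- hiv_rna < threshold
  bl <- !is.na(below_limit) & below_limit
  out[bl] <- ifelse(limit[bl] <= threshold, TRUE, NA)
  out
}

# three-valued OR: TRUE if any TRUE; NA if none TRUE and any NA
.or3 <- function(...) {
  args <- list(...)
  m <- do.call(cbind, args)
  any_true <- rowSums(m == TRUE, na.rm = TRUE) > 0
  any_na <- rowSums(is.na(m)) > 0
  out <- any_true
  out[!any_true & any_na] <- NA
  out
}

#' Derive clinical covariate flags from raw measurements
#'
#' Applies the clinical thresholds used throughout the analysis:
#' \itemize{
#'   \item depression: CES-D score >= 16;
#'   \item kidney disease: eGFR < 60 mL/min/1.73m2 or proteinuria >= 200 mg/g;
#'   \item hypertension: SBP >= 140 or DBP >= 90 mm Hg, or hypertension
#'     medication;
#'   \item diabetes: fasting glucose >= 126 mg/dL or diabetes medication;
#'   \item dyslipidemia: total cholesterol >= 200, LDL >= 130, HDL < 40,
#'     triglycerides >= 150 mg/dL, or lipid-lowering medication with clinical
#'     diagnosis;
#'   \item heavy drinking: >= 14 drinks/week;
#'   \item CD4 category: < 350, 350-499, >= 500 (reference) cells/mm3;
#'   \item detectable HIV RNA: >= 20 vs < 20 (reference) copies/mL.
#' }
#' Missing inputs propagate to missing flags (three-valued logic for the OR
#' rules), so downstream multiple imputation sees them as missing.
#'
#' @param visits Data frame of raw person-visit measurements. Recognised
#'   columns: \code{cesd}, \code{egfr}, \code{proteinuria}, \code{sbp},
#'   \code{dbp}, \code{htn_meds}, \code{glucose}, \code{dm_meds}, \code{chol},
#'   \code{ldl}, \code{hdl}, \code{trig}, \code{lipid_meds}, \code{lipid_dx},
#'   \code{drinks_week}, \code{cd4}, \code{hiv_rna}, \code{smoking}.
#' @return Data frame of derived flags aligned with \code{visits} rows.
#' @export
derive_covariates <- function(visits) {
  g <- function(nm) if (nm %in% names(visits)) visits[[nm]] else
    rep(NA, nrow(visits))
  out <- data.frame(row.names = seq_len(nrow(visits)))
  out$depression <- g("cesd") >= 16
  out$kidney_disease <- .or3(g("egfr") < 60, g("proteinuria") >= 200)
  out$hypertension <- .or3(g("sbp") >= 140, g("dbp") >= 90,
                           as.logical(g("htn_meds")))
  out$diabetes <- .or3(g("glucose") >= 126, as.logical(g("dm_meds")))
  out$dyslipidemia <- .or3(g("chol") >= 200, g("ldl") >= 130, g("hdl") < 40,
                           g("trig") >= 150,
                           as.logical(g("lipid_meds")) & as.logical(g("lipid_dx")))
  out$heavy_drinking <- g("drinks_week") >= 14
  cd4 <- g("cd4")
  out$cd4_cat <- factor(
    ifelse(is.na(cd4), NA,
           ifelse(cd4 < 350, "lt350", ifelse(cd4 < 500, "350to499", "ge500"))),
    levels = c("ge500", "350to499", "lt350")
  )
  out$rna_detectable <- g("hiv_rna") >= 20
  if ("smoking" %in% names(visits)) {
    out$smoking <- factor(visits$smoking, levels = c("never", "past", "current"))
  }
  out
}
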