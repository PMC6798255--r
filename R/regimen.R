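#' Is a drug set a cART regimen?
#'
#' Combination antiretroviral therapy (cART) requires at least three active
#' antiretroviral drugs drawn from at least two drug classes. Pharmacokinetic
#' boosters (ritonavir, cobicistat) never count towards the three-drug
#' minimum nor towards the class count.
#'
#' @param regimen Character vector of canonical drug codes, or a single
#'   regimen string parseable by [parse_regimen()].
#' @return \code{TRUE} if the set qualifies as cART.
#' @examples
#' is_cart(c("EFV", "TDF", "FTC"))   # TRUE
#' is_cart(c("TDF", "FTC"))          # FALSE: two drugs
#' is_cart(c("TDF", "FTC", "3TC"))   # FALSE: one class
#' @export
is_cart <- function(regimen) {
  codes <- if (length(regimen) == 1L) parse_regimen(regimen) else
    sort(unique(as.character(regimen)))
  if (!length(codes)) stop("empty regimen", call. = FALSE)
  cls <- drug_class(codes)
  active <- cls != "booster"
  sum(active) >= 3L && length(unique(cls[active])) >= 2L
}

#' Classify a cART regimen into PI / NNRTI / INSTI / other
#'
#' Applies the class hierarchy used for anchor-based cART classification:
#' PI-cART if the regimen contains a boosted protease inhibitor (a PI together
#' with ritonavir or cobicistat); NNRTI-cART if it contains an NNRTI and no
#' PI; INSTI-cART if it contains an INSTI and neither PI nor NNRTI; otherwise
#' \code{"other"}. Regimens with an unboosted PI fall to \code{"other"} unless
#' rescued by the NNRTI/INSTI rules (which the presence of any PI forbids), so
#' in practice they classify as \code{"other"}.
#'
#' @inheritParams is_cart
#' @return One of \code{"PI"}, \code{"NNRTI"}, \code{"INSTI"}, \code{"other"}.
#' @examples
#' classify_cart_class(c("DRV", "RTV", "TDF", "FTC"))        # "PI"
#' classify_cart_class(c("EVG", "COBI", "TDF", "FTC"))       # "INSTI"
#' classify_cart_class(c("EFV", "DRV", "RTV", "TDF", "FTC")) # "PI" dominates
#' @export
classify_cart_class <- function(regimen) {
  codes <- if (length(regimen) == 1L) parse_regimen(regimen) else
    sort(unique(as.character(regimen)))
  if (!is_cart(codes)) {
    stop("regimen is not cART; classification is defined for cART regimens",
         call. = FALSE)
  }
  cls <- drug_class(codes)
  has_pi <- any(cls == "PI")
  boosted <- has_pi && any(cls == "booster")
  if (boosted) return("PI")
  if (any(cls == "NNRTI") && !has_pi) return("NNRTI")
  if (any(cls == "INSTI") && !has_pi && !any(cls == "NNRTI")) return("INSTI")
  "other"
}

#' Set equality of two regimens
#'
#' Regimens are equal iff their canonical drug-code sets are equal; drug
#' order, case and aliasing never matter.
#'
#' @param a,b Regimens (code vectors or strings; see [parse_regimen()]).
#' @return Logical scalar.
#' @export
same_regimen <- function(a, b) {
  ca <- if (length(a) == 1L) parse_regimen(a) else sort(unique(as.character(a)))
  cb <- if (length(b) == 1L) parse_regimen(b) else sort(unique(as.character(b)))
  identical(ca, cb)
}
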