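#' Antiretroviral drug-class dictionary
#'
#' Returns the packaged dictionary mapping canonical antiretroviral drug codes
#' to drug classes, together with lower-case aliases (generic and brand names).
#' Classes are \code{NRTI}, \code{NNRTI}, \code{PI}, \code{INSTI},
#' \code{booster} (pharmacokinetic enhancers ritonavir and cobicistat) and
#' \code{other} (entry/fusion inhibitors).
#'
#' @return A data frame with columns \code{code}, \code{class}, \code{aliases}
#'   (pipe-separated).
#' @seealso [parse_regimen()], [drug_class()]
#' @export
drug_dictionary <- function() {
  .dict_env$classes
}

#' Fixed-dose combination dictionary
#'
#' Brand-name fixed-dose combinations (e.g. \code{"Atripla"}) mapped to their
#' canonical component codes.
#'
#' @return A data frame with columns \code{alias} and \code{components}
#'   (comma-separated canonical codes).
#' @export
drug_combos <- function() {
  .dict_env$combos
}

.dict_env <- new.env(parent = emptyenv())

.load_dictionaries <- function() {
  cl <- utils::read.delim(
    system.file("extdata", "drug_classes.tsv", package = "cartmsm"),
    stringsAsFactors = FALSE
  )
  cb <- utils::read.delim(
    system.file("extdata", "drug_combos.tsv", package = "cartmsm"),
    stringsAsFactors = FALSE
  )
  .dict_env$classes <- cl
  .dict_env$combos <- cb
  # flat alias lookup: lower-cased token -> canonical code(s)
  alias_map <- list()
  for (i in seq_len(nrow(cl))) {
    alias_map[[tolower(cl$code[i])]] <- cl$code[i]
    for (a in strsplit(cl$aliases[i], "|", fixed = TRUE)[[1]]) {
      if (nzchar(a)) alias_map[[tolower(a)]] <- cl$code[i]
    }
  }
  for (i in seq_len(nrow(cb))) {
    alias_map[[tolower(cb$alias[i])]] <-
      strsplit(cb$components[i], ",", fixed = TRUE)[[1]]
  }
  .dict_env$alias_map <- alias_map
  class_map <- cl$class
  names(class_map) <- cl$code
  .dict_env$class_map <- class_map
  invisible(NULL)
}

.alias_map <- function() {
  if (is.null(.dict_env$alias_map)) .load_dictionaries()
  .dict_env$alias_map
}

.class_map <- function() {
  if (is.null(.dict_env$class_map)) .load_dictionaries()
  .dict_env$class_map
}

#' Look up the drug class of canonical codes
#'
#' @param codes Character vector of canonical drug codes (see
#'   [drug_dictionary()]).
#' @return Character vector of classes, one per code.
#' @export
drug_class <- function(codes) {
  cm <- .class_map()
  unknown <- setdiff(codes, names(cm))
  if (length(unknown)) {
    stop("unknown drug code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(cm[codes])
}

#' Parse a regimen string into a canonical drug-code set
#'
#' Splits a regimen description on \code{/}, \code{+}, commas or whitespace,
#' resolves aliases (generic names, brand names, fixed-dose combinations) via
#' the packaged dictionary, and returns the sorted set of canonical codes.
#' Matching is case-insensitive; \code{"ATV/r"}-style booster shorthand is
#' supported (\code{r} resolves to ritonavir, \code{c} to cobicistat).
#'
#' @param x A single regimen string, or a character vector of drug
#'   codes/aliases already split.
#' @return Character vector of canonical codes (sorted, unique). A regimen is
#'   identified with this set: drug order never matters.
#' @examples
#' parse_regimen("Atripla")
#' parse_regimen("ATV/r + TDF/FTC")
#' @export
parse_regimen <- function(x) {
  if (length(x) == 1L) {
    tokens <- strsplit(x, "[/+,[:space:]]+")[[1]]
  } else {
    tokens <- as.character(x)
  }
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(character(0))
  am <- .alias_map()
  out <- character(0)
  for (tok in tokens) {
    hit <- am[[tolower(tok)]]
    if (is.null(hit)) {
      stop("unknown drug code or alias: ", tok, call. = FALSE)
    }
    out <- c(out, hit)
  }
  sort(unique(out))
}
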