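#' Read or write a simulation configuration as YAML
#'
#' Round-trippable serialization of a [sim_config()]: matrices are stored
#' with their dimnames, dates as ISO strings.
#'
#' @param path YAML file path.
#' @return For \code{read_sim_config}, a validated \code{"sim_config"}.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- y$treatment
  if (!is.null(tr)) {
    tr$intercepts <- unlist(tr$intercepts)
    cf <- do.call(rbind, lapply(tr$coefs, unlist))
    tr$coefs <- cf
  }
  cfn <- y$confounders
  if (!is.null(cfn)) {
    cfn$rna <- unlist(cfn$rna)
    cfn$comorb$treat_effects <- unlist(cfn$comorb$treat_effects)
    cfn$cd4_cuts <- unlist(cfn$cd4_cuts)
  }
  oc <- lapply(y$outcomes, function(o) {
    o$regimen <- unlist(o$regimen)
    o
  })
  sim_config(
    n_persons = y$n_persons, n_visits = y$n_visits,
    visit_interval = y$visit_interval,
    start_date = as.Date(y$start_date),
    regimens = unlist(y$regimens),
    treatment = tr, confounders = cfn,
    censoring = unlist(y$censoring), outcomes = oc,
    missingness = if (length(y$missingness)) unlist(y$missingness) else "none",
    seed = y$seed
  )
}

#' @rdname read_sim_config
#' @param cfg A \code{"sim_config"} object.
#' @export
write_sim_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$start_date <- format(y$start_date)
  y$treatment$coefs <- apply(y$treatment$coefs, 1, as.list, simplify = FALSE)
  # yaml drops names on atomic vectors; store named vectors as maps
  y$treatment$intercepts <- as.list(y$treatment$intercepts)
  y$confounders$rna <- as.list(y$confounders$rna)
  y$confounders$comorb$treat_effects <-
    as.list(y$confounders$comorb$treat_effects)
  y$censoring <- as.list(y$censoring)
  y$outcomes <- lapply(y$outcomes, function(o) {
    o$regimen <- as.list(o$regimen)
    o
  })
  y$missingness <- as.list(y$missingness)
  y$frailty_range <- NULL
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
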