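#' Covariate schema for the dexamethasone dosing trial
#'
#' The ten pre-selected baseline effect modifiers examined for heterogeneity
#' of treatment effect, with their measurement kinds. Respiratory support is
#' the only categorical covariate, with three ordered levels
#' (`open` < `niv_cpap` < `imv`); age (years) and weight (kg) are continuous;
#' the remaining seven are binary yes/no indicators.
#'
#' @return A tibble with columns `name`, `kind`
#'   (`"continuous"`, `"binary"` or `"categorical"`) and `levels`
#'   (a list column; ordered level labels for categorical entries,
#'   `NULL` otherwise).
#' @examples
#' hte_schema()
#' @export
hte_schema <- function() {
  tibble::tibble(
    name = c("age", "limitations", "resp_support", "il6_inhibitor",
             "dex_prior_3_4d", "weight", "diabetes", "ihd_hf", "copd",
             "immunosuppression"),
    kind = c("continuous", "binary", "categorical", "binary", "binary",
             "continuous", "binary", "binary", "binary", "binary"),
    levels = list(NULL, NULL, c("open", "niv_cpap", "imv"), NULL, NULL,
                  NULL, NULL, NULL, NULL, NULL)
  )
}

validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema),
            all(c("name", "kind", "levels") %in% names(schema)))
  if (anyDuplicated(schema$name)) {
    abort("schema covariate names must be unique")
  }
  if (!all(schema$kind %in% c("continuous", "binary", "categorical"))) {
    abort("schema kinds must be continuous, binary or categorical")
  }
  for (k in which(schema$kind == "categorical")) {
    lev <- schema$levels[[k]]
    if (length(lev) < 2 || anyDuplicated(lev)) {
      abort(paste0("categorical covariate '", schema$name[k],
                   "' needs >= 2 unique levels"))
    }
  }
  invisible(schema)
}

schema_continuous <- function(schema) schema$name[schema$kind == "continuous"]
schema_binary <- function(schema) schema$name[schema$kind == "binary"]
schema_categorical <- function(schema) {
  schema$name[schema$kind == "categorical"]
}
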