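#' Construct a validated trial dataset
#'
#' Builds the per-patient analysis table from a plain data frame: one row per
#' patient with an `id`, randomized arm (`1` = 12 mg/d dexamethasone,
#' `0` = 6 mg/d), the two outcomes (`dawols90`, days alive without life
#' support through day 90, an integer in \[0, 90\]; `mort90`, 90-day
#' mortality in \{0, 1\}; either may be missing), and a column per schema
#' covariate. Covariates must be complete; a missing covariate value is an
#' input error, while missing outcomes are allowed and carried as `NA`.
#'
#' @param df A data frame with columns `id`, `arm`, `dawols90`, `mort90` and
#'   one column per schema covariate.
#' @param schema Covariate schema, see [hte_schema()].
#' @param standardized Whether continuous covariates are already on the
#'   standardized (mean 0, sd 1) scale.
#' @param std_params Standardization parameters (tibble with `name`,
#'   `center`, `scale`) when `standardized = TRUE`.
#' @return A `trial_data` tibble.
#' @export
trial_data <- function(df, schema = hte_schema(), standardized = FALSE,
                       std_params = NULL) {
  validate_schema(schema)
  df <- tibble::as_tibble(df)
  required <- c("id", "arm", "dawols90", "mort90", schema$name)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- df[required]

  df$id <- as.character(df$id)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    abort(paste0("duplicate id(s): ", paste(unique(dup), collapse = ", ")))
  }

  check_int01 <- function(x, col) {
    bad <- which(!is.na(x) & !(x %in% c(0, 1)))
    if (length(bad)) {
      abort(paste0("column '", col, "', row ", bad[1],
                   ": value must be 0 or 1"))
    }
    as.integer(x)
  }
  df$arm <- check_int01(as_num(df$arm, "arm"), "arm")
  if (anyNA(df$arm)) {
    abort(paste0("column 'arm', row ", which(is.na(df$arm))[1],
                 ": arm may not be missing"))
  }

  daw <- as_num(df$dawols90, "dawols90")
  bad <- which(!is.na(daw) & (daw < 0 | daw > 90 | daw != round(daw)))
  if (length(bad)) {
    abort(paste0("column 'dawols90', row ", bad[1],
                 ": must be an integer in [0, 90]"))
  }
  df$dawols90 <- as.integer(daw)
  df$mort90 <- check_int01(as_num(df$mort90, "mort90"), "mort90")

  for (k in seq_len(nrow(schema))) {
    nm <- schema$name[k]
    x <- df[[nm]]
    if (anyNA(x)) {
      abort(paste0("column '", nm, "', row ", which(is.na(x))[1],
                   ": covariates may not be missing"))
    }
    df[[nm]] <- switch(
      schema$kind[k],
      continuous = {
        v <- as_num(x, nm)
        if (any(!is.finite(v))) {
          abort(paste0("column '", nm, "', row ",
                       which(!is.finite(v))[1], ": non-finite value"))
        }
        v
      },
      binary = check_int01(as_num(x, nm), nm),
      categorical = {
        lev <- schema$levels[[k]]
        xc <- as.character(x)
        bad <- which(!(xc %in% lev))
        if (length(bad)) {
          abort(paste0("column '", nm, "', row ", bad[1],
                       ": unknown level '", xc[bad[1]], "'"))
        }
        factor(xc, levels = lev)
      }
    )
  }

  if (standardized && is.null(std_params)) {
    abort("standardized = TRUE requires std_params")
  }
  new_trial_data(df, schema, standardized, std_params)
}

new_trial_data <- function(df, schema, standardized, std_params) {
  structure(df, schema = schema, standardized = standardized,
            std_params = std_params,
            class = c("trial_data", class(tibble::tibble())))
}

as_num <- function(x, col) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      abort(paste0("column '", col, "', row ", bad[1],
                   ": non-numeric value '", x[bad[1]], "'"))
    }
    out
  } else {
    as.numeric(x)
  }
}

#' @export
print.trial_data <- function(x, ...) {
  std <- if (isTRUE(attr(x, "standardized"))) "standardized" else
    "original units"
  cat("# trial_data: ", nrow(x), " patients (", std, ")\n", sep = "")
  NextMethod()
}

ds_schema <- function(ds) attr(ds, "schema")
ds_standardized <- function(ds) isTRUE(attr(ds, "standardized"))
ds_std_params <- function(ds) attr(ds, "std_params")

#' Read a trial table from a delimited text file
#'
#' Reads a CSV/TSV export of the trial schema and validates it (see
#' [trial_data()]). Unknown categorical levels, out-of-range outcomes,
#' missing covariate values and duplicate ids are rejected with the
#' offending row and column named; nothing is ever silently imputed.
#'
#' @param path File path; the delimiter is taken from the extension
#'   (`.tsv` for tab, otherwise comma) unless `delim` is given.
#' @param schema Covariate schema.
#' @param na Missing-outcome token (default `"NA"`).
#' @param col_map Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(dawols90 = "days_alive")`.
#' @param delim Field delimiter override.
#' @return A `trial_data` tibble.
#' @export
read_trial_data <- function(path, schema = hte_schema(), na = "NA",
                            col_map = NULL, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, na = na,
                           col_types = readr::cols(.default = "c"),
                           show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(raw)) {
        abort(paste0("mapped column '", col_map[[canon]], "' not in file"))
      }
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  trial_data(raw, schema = schema)
}

#' Write a trial table to a delimited text file
#'
#' Emits the same dialect [read_trial_data()] accepts, so datasets
#' round-trip exactly.
#'
#' @param ds A `trial_data` tibble.
#' @param path Output path (`.tsv` for tab-separated, otherwise CSV).
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(ds, path) {
  df <- tibble::as_tibble(ds)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(df, path, na = "NA", progress = FALSE)
  } else {
    readr::write_csv(df, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Standardize continuous covariates
#'
#' Centers and scales each continuous covariate to sample mean 0 and sample
#' standard deviation 1 (denominator n - 1), recording the per-covariate
#' center and scale so that model outputs (e.g. tree cutpoints) can be
#' translated back to the original units.
#'
#' @param ds A `trial_data` tibble in original units.
#' @return The standardized `trial_data`, with the parameters retrievable
#'   via `attr(ds, "std_params")`.
#' @export
standardize_covariates <- function(ds) {
  if (ds_standardized(ds)) abort("dataset is already standardized")
  schema <- ds_schema(ds)
  cont <- schema_continuous(schema)
  params <- tibble::tibble(
    name = cont,
    center = vapply(cont, function(nm) mean(ds[[nm]]), numeric(1),
                    USE.NAMES = FALSE),
    scale = vapply(cont, function(nm) sd(ds[[nm]]), numeric(1),
                   USE.NAMES = FALSE)
  )
  zero <- params$name[params$scale <= 0 | !is.finite(params$scale)]
  if (length(zero)) {
    abort(paste0("zero-variance continuous covariate: ",
                 paste(zero, collapse = ", ")))
  }
  out <- ds
  for (k in seq_along(cont)) {
    out[[cont[k]]] <- (ds[[cont[k]]] - params$center[k]) / params$scale[k]
  }
  new_trial_data(out, schema, TRUE, params)
}

#' Back-translate a standardized value to original units
#'
#' @param name Continuous covariate name.
#' @param x Value(s) on the standardized scale.
#' @param params Standardization parameters
#'   (`attr(ds, "std_params")` of a standardized dataset).
#' @return `x * scale + center` in original units.
#' @export
destandardize_value <- function(name, x, params) {
  k <- match(name, params$name)
  if (is.na(k)) abort(paste0("unknown standardized covariate '", name, "'"))
  x * params$scale[k] + params$center[k]
}

#' Undo covariate standardization on a dataset
#'
#' @param ds A standardized `trial_data`.
#' @return The dataset with continuous covariates in original units.
#' @export
destandardize_covariates <- function(ds) {
  if (!ds_standardized(ds)) return(ds)
  params <- ds_std_params(ds)
  out <- ds
  for (k in seq_len(nrow(params))) {
    out[[params$name[k]]] <-
      ds[[params$name[k]]] * params$scale[k] + params$center[k]
  }
  new_trial_data(out, ds_schema(ds), FALSE, NULL)
}

#' Arm-wise summary table
#'
#' Per-arm summaries in the style of a trial baseline table: `n` per arm;
#' median and interquartile range for continuous covariates and DAWOLS
#' (among non-missing); count and percentage for binary and categorical
#' covariates (percentages rounded to integers, as printed in baseline
#' tables); deaths/total with the percentage to one decimal for 90-day
#' mortality. Missing outcomes are excluded from their own summary and the
#' denominator is reported.
#'
#' @param ds A `trial_data` tibble (either scale; continuous summaries are
#'   reported on the scale stored in the dataset).
#' @return A tibble with one row per (variable, level, arm).
#' @export
summarize_by_arm <- function(ds) {
  if (nrow(ds) == 0) abort("dataset is empty")
  schema <- ds_schema(ds)
  df <- tibble::as_tibble(ds)

  cont_row <- function(d, variable, x) {
    x <- x[!is.na(x)]
    tibble::tibble(variable = variable, level = NA_character_,
                   n = length(x), denom = length(x),
                   median = median(x), q1 = unname(quantile(x, 0.25)),
                   q3 = unname(quantile(x, 0.75)),
                   count = NA_real_, pct = NA_real_)
  }
  bin_row <- function(variable, x) {
    tibble::tibble(variable = variable, level = NA_character_,
                   n = length(x), denom = length(x),
                   median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                   count = sum(x), pct = round(100 * sum(x) / length(x)))
  }
  cat_rows <- function(variable, x) {
    purrr::map_dfr(levels(x), function(lv) {
      tibble::tibble(variable = variable, level = lv,
                     n = length(x), denom = length(x),
                     median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                     count = sum(x == lv),
                     pct = round(100 * mean(x == lv)))
    })
  }

  one_arm <- function(d) {
    rows <- purrr::map_dfr(seq_len(nrow(schema)), function(k) {
      nm <- schema$name[k]
      switch(schema$kind[k],
             continuous = cont_row(d, nm, d[[nm]]),
             binary = bin_row(nm, d[[nm]]),
             categorical = cat_rows(nm, d[[nm]]))
    })
    daw <- d$dawols90[!is.na(d$dawols90)]
    mort <- d$mort90[!is.na(d$mort90)]
    dplyr::bind_rows(
      rows,
      tibble::tibble(variable = "dawols90", level = NA_character_,
                     n = length(daw), denom = length(daw),
                     median = median(daw), q1 = unname(quantile(daw, 0.25)),
                     q3 = unname(quantile(daw, 0.75)),
                     count = NA_real_, pct = NA_real_),
      tibble::tibble(variable = "mort90", level = NA_character_,
                     n = length(mort), denom = length(mort),
                     median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                     count = sum(mort),
                     pct = round(100 * sum(mort) / length(mort), 1))
    )
  }

  df %>%
    dplyr::mutate(arm = factor(.data$arm, levels = c(1, 0),
                               labels = c("12mg", "6mg"))) %>%
    dplyr::group_by(.data$arm) %>%
    dplyr::group_modify(~ one_arm(.x)) %>%
    dplyr::ungroup() %>%
    dplyr::relocate("variable", "level", "arm")
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
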