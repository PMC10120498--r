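# Config-driven orchestration of the full two-stage analysis:
# load/standardize -> (optional hyperparameter CV) -> stage-1 CATEs per
# outcome -> convergence diagnostics -> stage-2 trees, partial dependence
# and quartile tables -> extreme-imputation sensitivity -> report bundle.

default_run_config <- function() {
  list(
    input = NULL,
    scenario = "constant",
    n = 982,
    seed = 1,
    outcomes = c("dawols", "mortality"),
    profile = "fast",
    mcmc = list(),
    cv = FALSE,
    cv_k = 10,
    cv_schedule = list(nchain = 1, ntotal = 200, nburn = 50),
    link = "probit",
    cart = list(max_depth = 3, min_leaf = 20, cp = 0.01),
    pd_covariates = c("age", "weight"),
    pd_grid = 25,
    sensitivity = TRUE,
    out_dir = NULL
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  cfg <- modifyList(default_run_config(), config)
  cfg$outcomes <- match.arg(cfg$outcomes, c("dawols", "mortality"),
                            several.ok = TRUE)
  cfg
}

pipeline_config <- function(cfg, seed) {
  base_cfg <- if (identical(cfg$profile, "full")) {
    list(ntree = 200, nchain = 4, ntotal = 1100, nburn = 100)
  } else {
    list(ntree = 50, nchain = 1, ntotal = 300, nburn = 100)
  }
  args <- modifyList(base_cfg, cfg$mcmc)
  args$seed <- seed
  do.call(bart_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full two-stage analysis
#'
#' Executes the pipeline described by a configuration (a list, or the path
#' of a YAML/JSON file): load a trial table (or generate a named synthetic
#' scenario), standardize covariates, optionally cross-validate the
#' hyperparameter grid, estimate CATEs per outcome, run convergence
#' diagnostics, fit the subgroup trees, partial-dependence curves and
#' quartile summaries, rerun everything under best/worst-case imputation,
#' and write a plain-text report bundle with a provenance manifest. The
#' whole bundle is deterministic given the configuration and seed.
#'
#' Configuration fields (with defaults): `input` (CSV/TSV path; when NULL a
#' synthetic `scenario` of size `n` is generated), `seed`, `outcomes`,
#' `profile` (`"fast"`: 1 chain, 300/100, 50 trees; `"full"`: 4 chains,
#' 1100/100, 200 trees) plus `mcmc` overrides, `cv` / `cv_k` /
#' `cv_schedule`, `link`, `cart` (`max_depth`, `min_leaf`, `cp`),
#' `pd_covariates`, `pd_grid`, `sensitivity`, `out_dir`.
#'
#' @param config Configuration list or file path.
#' @param out_dir Output directory (overrides the config field; required
#'   in one of the two places).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_analysis <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  cfg <- read_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) abort("an output directory is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[bartcate] ", ...)
  outpath <- function(...) file.path(cfg$out_dir, paste0(...))

  ds <- run_stage("load", {
    if (!is.null(cfg$input)) {
      say("loading ", cfg$input)
      read_trial_data(cfg$input)
    } else {
      say("generating scenario '", cfg$scenario, "' (n = ", cfg$n, ")")
      sc <- trial_scenario(cfg$scenario)
      generate_trial(n = cfg$n, marginals = sc$marginals,
                     effects = sc$effects, seed = cfg$seed)
    }
  })

  run_stage("summaries", {
    tab1 <- summarize_by_arm(ds)
    readr::write_tsv(tab1, outpath("table1.tsv"), progress = FALSE)
    jsonlite::write_json(tab1, outpath("table1.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
  })

  std <- run_stage("standardize", standardize_covariates(ds))

  results <- list()
  for (oc in cfg$outcomes) {
    say("outcome: ", oc)
    fit_cfg <- pipeline_config(cfg, cfg$seed)
    if (isTRUE(cfg$cv)) {
      cv <- run_stage(paste0("cv_", oc), {
        cross_validate(std, oc, k = cfg$cv_k, seed = cfg$seed,
                       schedule = cfg$cv_schedule, link = cfg$link)
      })
      readr::write_tsv(tidy(cv), outpath("cv_", oc, ".tsv"),
                       progress = FALSE)
      jsonlite::write_json(attr(cv, "selected"),
                           outpath("cv_selection_", oc, ".json"),
                           auto_unbox = TRUE, digits = NA)
      sel <- attr(cv, "selected")
      fit_cfg <- pipeline_config(
        modifyList(cfg, list(mcmc = modifyList(cfg$mcmc,
                                               list(ntree = sel$ntree)))),
        cfg$seed)
      fit_cfg$base <- sel$base
      fit_cfg$power <- sel$power
    } else {
      cv <- NULL
    }

    cate <- run_stage(paste0("cate_", oc), {
      estimate_cate(std, oc, fit_cfg, link = cfg$link)
    })
    cate_tab <- tidy(cate)
    cate_tab$rank <- rank(cate_tab$estimate, ties.method = "first")
    readr::write_tsv(cate_tab, outpath("cate_", oc, ".tsv"),
                     progress = FALSE)

    diag <- run_stage(paste0("diagnostics_", oc), diagnose(cate_fit(cate)))
    jsonlite::write_json(diagnostics_to_list(diag),
                         outpath("diagnostics_", oc, ".json"),
                         auto_unbox = TRUE, digits = NA, na = "null")

    pds <- list()
    for (cv_name in cfg$pd_covariates) {
      pd <- run_stage(paste0("pd_", oc, "_", cv_name), {
        partial_dependence(cate, cv_name, grid_size = cfg$pd_grid)
      })
      readr::write_tsv(pd, outpath("pd_", oc, "_", cv_name, ".tsv"),
                       progress = FALSE)
      pds[[cv_name]] <- pd
    }

    tree <- run_stage(paste0("tree_", oc), {
      fit_subgroups(cate, max_depth = cfg$cart$max_depth,
                    min_leaf = cfg$cart$min_leaf, cp = cfg$cart$cp)
    })
    writeLines(render_tree(tree, "text"), outpath("tree_", oc, ".txt"))
    writeLines(render_tree(tree, "json"), outpath("tree_", oc, ".json"))

    quart <- run_stage(paste0("quartiles_", oc), quartile_summary(cate))
    readr::write_tsv(quart, outpath("quartiles_", oc, ".tsv"),
                     progress = FALSE)

    sens <- NULL
    if (isTRUE(cfg$sensitivity)) {
      sens <- run_stage(paste0("sensitivity_", oc), {
        run_sensitivity(std, oc, fit_cfg, max_depth = cfg$cart$max_depth,
                        min_leaf = cfg$cart$min_leaf, cp = cfg$cart$cp,
                        link = cfg$link)
      })
      jsonlite::write_json(sens$comparison,
                           outpath("sensitivity_", oc, ".json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      for (nm in names(sens$trees)) {
        writeLines(render_tree(sens$trees[[nm]], "text"),
                   outpath("sensitivity_", oc, "_", nm, ".txt"))
      }
    }

    results[[oc]] <- list(cv = cv, cate = cate, diagnostics = diag,
                          partial_dependence = pds, tree = tree,
                          quartiles = quart, sensitivity = sens)
  }

  manifest <- run_stage("manifest", {
    cfg_json <- outpath("config.json")
    jsonlite::write_json(cfg, cfg_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
    m <- list(seed = cfg$seed,
              config_hash = unname(tools::md5sum(cfg_json)),
              package_version = as.character(utils::packageVersion("bartcate")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              outputs = sort(list.files(cfg$out_dir)))
    jsonlite::write_json(m, outpath("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    m
  })
  say("bundle written to ", cfg$out_dir)
  invisible(list(data = ds, results = results, manifest = manifest,
                 config = cfg))
}
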