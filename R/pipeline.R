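#' Build a pipeline configuration
#'
#' Collects every knob of the full analysis pipeline in one validated list.
#' Exactly one of `input` (a panel CSV readable by [read_panel()]) or
#' `simulate` (a list with `seed` and optionally `n0`, `retention`,
#' generating a panel from [default_truth()]) must be supplied. Every
#' stochastic stage carries its own explicit seed; nothing is seeded from
#' the clock.
#'
#' @param input Optional path to a panel CSV.
#' @param simulate Optional list: `seed`, and optionally `n0`, `retention`.
#' @param out_dir Output directory (created if needed).
#' @param cor_method,gamma,n_lambda,lambda_min_ratio Network estimation
#'   settings, see [estimate_network()].
#' @param bootstrap_B,bootstrap_seed Edge-accuracy bootstrap settings.
#' @param cs_drop_grid,cs_B_per_drop,cs_corr_threshold,cs_confidence,cs_seed
#'   Case-dropping stability settings, see [cs_coefficient()].
#' @param clpn_folds,clpn_seed,clpn_threshold Cross-lagged panel network
#'   settings, see [fit_clpn()].
#' @param redundancy_r_min,redundancy_alpha,redundancy_prop Redundancy
#'   screen settings, see [redundancy_screen()].
#' @param alpha_normality Normality cutoff for [compare_waves()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL, out_dir,
                            cor_method = "pearson", gamma = 0.5,
                            n_lambda = 100L, lambda_min_ratio = 0.01,
                            bootstrap_B = 1000L, bootstrap_seed = 101L,
                            cs_drop_grid = seq(0.05, 0.75, by = 0.05),
                            cs_B_per_drop = 200L, cs_corr_threshold = 0.7,
                            cs_confidence = 0.95, cs_seed = 202L,
                            clpn_folds = 10L, clpn_seed = 303L,
                            clpn_threshold = 0.1,
                            redundancy_r_min = 0.5, redundancy_alpha = 0.05,
                            redundancy_prop = 0.25,
                            alpha_normality = 0.05) {
  if (is.null(input) == is.null(simulate)) {
    stop("supply exactly one of `input` or `simulate`", call. = FALSE)
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input file does not exist: ", input, call. = FALSE)
  }
  if (!is.null(simulate) && is.null(simulate$seed)) {
    stop("`simulate` must carry an explicit `seed`", call. = FALSE)
  }
  structure(list(
    input = input, simulate = simulate, out_dir = out_dir,
    cor_method = cor_method, gamma = gamma, n_lambda = n_lambda,
    lambda_min_ratio = lambda_min_ratio,
    bootstrap_B = bootstrap_B, bootstrap_seed = bootstrap_seed,
    cs_drop_grid = cs_drop_grid, cs_B_per_drop = cs_B_per_drop,
    cs_corr_threshold = cs_corr_threshold, cs_confidence = cs_confidence,
    cs_seed = cs_seed,
    clpn_folds = clpn_folds, clpn_seed = clpn_seed,
    clpn_threshold = clpn_threshold,
    redundancy_r_min = redundancy_r_min,
    redundancy_alpha = redundancy_alpha,
    redundancy_prop = redundancy_prop,
    alpha_normality = alpha_normality
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys are the [pipeline_config()] arguments; omitted keys keep their
#' defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path,
                               call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, vals)
}

pipeline_stage_error <- function(stage, parent) {
  structure(
    class = c("panelnet_stage_error", "error", "condition"),
    list(message = paste0("stage '", stage, "' failed: ",
                          conditionMessage(parent)),
         call = NULL, stage = stage, parent = parent)
  )
}

#' Run the full two-wave network analysis pipeline
#'
#' Executes, in order: descriptive summaries, the redundancy screen,
#' per-wave regularized network estimation, centrality, bootstrap edge
#' accuracy, case-dropping stability, paired T0-vs-T1 comparisons, and the
#' cross-lagged panel network. All stage outputs are written under
#' `config$out_dir` as CSV/JSON, together with a `manifest.json` recording
#' the configuration hash, seeds, package version and per-stage status.
#' Re-running with an identical configuration reproduces identical files.
#' A stage failure writes a machine-readable `error.json` naming the stage
#' and halts.
#'
#' @param config A [pipeline_config()] (or a path readable by
#'   [read_config()]).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$input) && !file.exists(config$input)) {
    stop("input file does not exist: ", config$input, call. = FALSE)
  }

  cfg_json <- file.path(out, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  cfg_hash <- unname(tools::md5sum(cfg_json))

  stages <- c("describe", "redundancy_screen", "networks", "centrality",
              "bootstrap_accuracy", "stability", "paired_comparisons",
              "clpn")
  status <- setNames(rep("pending", length(stages)), stages)

  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) {
      err <- pipeline_stage_error(stage, e)
      jsonlite::write_json(
        list(stage = stage, message = conditionMessage(e)),
        file.path(out, "error.json"), auto_unbox = TRUE)
      stop(err)
    })
    status[stage] <<- "completed"
    res
  }

  # input acquisition (validation, not a counted stage)
  if (!is.null(config$simulate)) {
    truth <- default_truth(seed = config$simulate$seed)
    panel <- simulate_panel(truth,
                            n0 = config$simulate$n0 %||% truth$n0,
                            retention = config$simulate$retention %||%
                              truth$retention)
    write_truth(truth, file.path(out, "truth.json"))
    write_panel(panel, file.path(out, "panel.csv"))
  } else {
    panel <- read_panel(config$input)
    rej <- attr(panel, "rejects")
    if (nrow(rej)) readr::write_csv(rej, file.path(out, "rejects.csv"))
  }
  t0 <- wave_slice(panel, "T0")
  t1 <- wave_slice(panel, "T1")

  run_stage("describe", {
    readr::write_csv(describe_panel(panel, "T0"),
                     file.path(out, "describe_t0.csv"))
    readr::write_csv(describe_panel(panel, "T1"),
                     file.path(out, "describe_t1.csv"))
  })

  run_stage("redundancy_screen", {
    scr <- redundancy_screen(t0, r_min = config$redundancy_r_min,
                             alpha = config$redundancy_alpha,
                             prop_threshold = config$redundancy_prop,
                             cor_method = config$cor_method)
    readr::write_csv(tibble::as_tibble(scr),
                     file.path(out, "redundancy_t0.csv"))
  })

  nets <- run_stage("networks", {
    nets <- list(
      T0 = estimate_network(t0, gamma = config$gamma,
                            n_lambda = config$n_lambda,
                            lambda_min_ratio = config$lambda_min_ratio,
                            cor_method = config$cor_method),
      T1 = estimate_network(t1, gamma = config$gamma,
                            n_lambda = config$n_lambda,
                            lambda_min_ratio = config$lambda_min_ratio,
                            cor_method = config$cor_method)
    )
    write_network(nets$T0, file.path(out, "network_t0"))
    write_network(nets$T1, file.path(out, "network_t1"))
    nets
  })

  run_stage("centrality", {
    readr::write_csv(centrality_table(nets$T0),
                     file.path(out, "centrality_t0.csv"))
    readr::write_csv(centrality_table(nets$T1),
                     file.path(out, "centrality_t1.csv"))
  })

  run_stage("bootstrap_accuracy", {
    for (wv in c("T0", "T1")) {
      bt <- bootstrap_edges(if (wv == "T0") t0 else t1,
                            B = config$bootstrap_B,
                            seed = config$bootstrap_seed,
                            gamma = config$gamma,
                            n_lambda = config$n_lambda,
                            lambda_min_ratio = config$lambda_min_ratio,
                            cor_method = config$cor_method)
      readr::write_csv(tibble::as_tibble(bt),
                       file.path(out, paste0("bootstrap_",
                                             tolower(wv), ".csv")))
    }
  })

  cs_tbl <- run_stage("stability", {
    grid <- expand.grid(wave = c("T0", "T1"),
                        index = c("strength", "expected_influence"),
                        stringsAsFactors = FALSE)
    cs_tbl <- purrr::pmap_dfr(grid, function(wave, index) {
      st <- cs_coefficient(if (wave == "T0") t0 else t1, index = index,
                           drop_grid = config$cs_drop_grid,
                           B_per_drop = config$cs_B_per_drop,
                           corr_threshold = config$cs_corr_threshold,
                           confidence = config$cs_confidence,
                           seed = config$cs_seed,
                           gamma = config$gamma,
                           n_lambda = config$n_lambda,
                           lambda_min_ratio = config$lambda_min_ratio,
                           cor_method = config$cor_method)
      readr::write_csv(st$correlations,
                       file.path(out, paste0("stability_", tolower(wave),
                                             "_", index, ".csv")))
      dplyr::mutate(glance(st), wave = wave, .before = 1)
    })
    readr::write_csv(cs_tbl, file.path(out, "cs_coefficients.csv"))
    cs_tbl
  })

  run_stage("paired_comparisons", {
    cmp <- compare_waves(panel, alpha_normality = config$alpha_normality)
    readr::write_csv(cmp, file.path(out, "paired_comparisons.csv"))
    readr::write_csv(format_comparison_table(cmp),
                     file.path(out, "paired_comparisons_table.csv"))
  })

  run_stage("clpn", {
    model <- fit_clpn(panel, n_folds = config$clpn_folds,
                      seed = config$clpn_seed,
                      report_threshold = config$clpn_threshold)
    write_clpn(model, file.path(out, "clpn"))
    readr::write_csv(reported_edges(model),
                     file.path(out, "clpn_reported_edges.csv"))
    readr::write_csv(temporal_ei(model), file.path(out, "temporal_ei.csv"))
  })

  manifest <- list(
    package = "panelnet",
    version = as.character(utils::packageVersion("panelnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = cfg_hash,
    seeds = list(
      simulate = config$simulate$seed,
      bootstrap = config$bootstrap_seed,
      stability = config$cs_seed,
      clpn_folds = config$clpn_seed
    ),
    n_t0 = nrow(t0),
    n_t1 = nrow(t1),
    stages = lapply(seq_along(stages), function(i) {
      list(name = stages[i], status = unname(status[stages[i]]))
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
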