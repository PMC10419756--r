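#' Assemble a pipeline run configuration
#'
#' Validates and freezes every knob of a comparison run; the configuration is
#' serialized verbatim into the run's outputs so results are replayable.
#'
#' @param data Path to a spectra CSV (see [read_spectra_csv()]) or a
#'   `spectra_dataset` / `synthetic_spec` object.
#' @param reference_column Reference column name (CSV input only).
#' @param split Either `"ks:<fraction>"` (Kennard-Stone) or a list with
#'   integer `calibration` / `validation` indices; ignored when the dataset
#'   already carries roles.
#' @param preprocessing `"mean_center"` (default), `"none"`, or
#'   `"snv+mean_center"`.
#' @param methods Character vector from
#'   `c("bnmi", "cc", "vip", "uve", "cars", "bipls", "full")`.
#' @param bin_grid,stride B-NMI bin-count grid controls (see [bnmi_select()]).
#' @param objective,lv_rule,lv_cap,rmse_divisor Shared modeling knobs.
#' @param seed Single RNG seed threaded to every stochastic stage.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(data, reference_column = "ref", split = "ks:0.75",
                       preprocessing = "mean_center",
                       methods = c("bnmi", "cc", "vip", "uve", "cars",
                                   "bipls", "full"),
                       bin_grid = NULL, stride = 1L,
                       objective = "rmsep", lv_rule = "parsimonious",
                       lv_cap = 10, rmse_divisor = "m", seed = 1L,
                       out_dir = "bnmi-run") {
  known <- c("bnmi", "cc", "vip", "uve", "cars", "bipls", "full")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) {
    stop("unknown method name(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(preprocessing %in% c("none", "mean_center", "snv+mean_center"),
            objective %in% c("rmsep", "rmsecv"),
            lv_rule %in% c("parsimonious", "global_min"),
            rmse_divisor %in% c("m", "m-1"))
  structure(
    list(
      data = data, reference_column = reference_column, split = split,
      preprocessing = preprocessing, methods = methods, bin_grid = bin_grid,
      stride = as.integer(stride), objective = objective, lv_rule = lv_rule,
      lv_cap = lv_cap, rmse_divisor = rmse_divisor, seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

resolve_dataset <- function(config) {
  d <- config$data
  ds <- if (inherits(d, "spectra_dataset")) {
    d
  } else if (inherits(d, "synthetic_spec")) {
    generate_dataset(d)
  } else if (is.character(d)) {
    read_spectra_csv(d, config$reference_column)
  } else {
    stop("unsupported data input of class ", paste(class(d), collapse = "/"))
  }
  ds <- preprocess(ds, config$preprocessing)
  if (!any(ds$role == "calibration")) {
    s <- config$split
    if (is.character(s) && grepl("^ks:", s)) {
      ds <- ks_assign(ds, fraction = as.numeric(sub("^ks:", "", s)))
    } else if (is.list(s)) {
      ds$role[s$calibration] <- "calibration"
      ds$role[s$validation] <- "validation"
    } else {
      stop("invalid split specification")
    }
  }
  ds
}

run_one_method <- function(method, ds, config) {
  switch(method,
    bnmi = bnmi_select(ds, bin_grid = config$bin_grid,
                       stride = config$stride, lv_cap = config$lv_cap,
                       lv_rule = config$lv_rule, objective = config$objective,
                       rmse_divisor = config$rmse_divisor),
    cc = cc_select(ds, lv_cap = config$lv_cap, lv_rule = config$lv_rule,
                   rmse_divisor = config$rmse_divisor),
    vip = vip_select(ds, lv_cap = config$lv_cap, lv_rule = config$lv_rule,
                     rmse_divisor = config$rmse_divisor),
    uve = uve_select(ds, seed = config$seed, lv_cap = config$lv_cap,
                     lv_rule = config$lv_rule,
                     rmse_divisor = config$rmse_divisor),
    cars = cars_select(ds, seed = config$seed, lv_cap = config$lv_cap,
                       lv_rule = config$lv_rule,
                       rmse_divisor = config$rmse_divisor),
    bipls = bipls_select(ds, lv_cap = config$lv_cap, lv_rule = config$lv_rule,
                         rmse_divisor = config$rmse_divisor),
    full = full_spectrum_pls(ds, lv_cap = config$lv_cap,
                             lv_rule = config$lv_rule,
                             rmse_divisor = config$rmse_divisor),
    stop("unknown method: ", method)
  )
}

serialize_result <- function(res) {
  list(
    method = res$method,
    selected = res$selected,
    ranked_order = res$ranked_order,
    chosen_bin_count = res$chosen_bin_count,
    metrics = as.list(res$metrics),
    rmsep_curve = if (!is.null(res$rmsep_curve)) {
      as.list(res$rmsep_curve)
    },
    nmi_profile = if (!is.null(res$nmi_profile)) as.list(res$nmi_profile)
  )
}

#' Run the full selection/comparison pipeline
#'
#' Resolves the dataset, assigns roles, runs every configured selector, and
#' writes an artifact directory: per-method result JSONs, the comparison
#' table (CSV + JSON), the B-NMI NMI profile and RMSEP accumulation curve as
#' two-column text, the frozen configuration, and a log of the quantities a
#' comparison table reports (chosen bin count, subset sizes, latent
#' variables).
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the `results` (named by method), the
#'   comparison `table`, and the artifact directory path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ds <- resolve_dataset(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  log_lines <- c(
    paste0("bnmi pipeline | seed ", config$seed, " | R ",
           getRversion()),
    paste0("samples: ", sum(ds$role == "calibration"), " calibration / ",
           sum(ds$role == "validation"), " validation; ",
           length(ds$wavelengths), " wavelengths")
  )
  for (method in config$methods) {
    res <- run_one_method(method, ds, config)
    results[[method]] <- res
    log_lines <- c(log_lines, paste0(
      method, ": ", length(res$selected), " variables, ",
      res$metrics$n_lv, " LV",
      if (!is.na(res$chosen_bin_count)) paste0(", B = ", res$chosen_bin_count),
      ", RMSEP = ", signif(res$metrics$rmsep, 6)
    ))
    jsonlite::write_json(serialize_result(res),
                         file.path(out, paste0(method, "_result.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  n_val <- sum(ds$role == "validation")
  tab <- comparison_table(results, n_val = n_val)
  readr::write_csv(tab, file.path(out, "comparison.csv"), progress = FALSE)
  jsonlite::write_json(tab, file.path(out, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(results$bnmi)) {
    readr::write_tsv(results$bnmi$nmi_profile[, c("wavelength", "nmi")],
                     file.path(out, "nmi_profile.tsv"), progress = FALSE)
    readr::write_tsv(results$bnmi$rmsep_curve,
                     file.path(out, "rmsep_curve.tsv"), progress = FALSE)
  }
  cfg <- config
  cfg$data <- if (is.character(cfg$data)) cfg$data else class(cfg$data)[1]
  jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(list(results = results, table = tab, out_dir = out))
}
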