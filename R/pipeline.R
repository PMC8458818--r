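#' Resolved run configuration with validated defaults
#'
#' All pipeline tunables in one flat list.  Unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param ... overrides of the defaults, by name.  Available keys:
#'   `kde.bandwidth_scale` (1.0), `grid.N` (9; 21 is the production
#'   profile), `grid.K` (41), `widths` (the seven default component sds),
#'   `lasso.lambda` (1e-5), `lasso.threshold` (1e-9), `lasso.target_nnz`
#'   (400), `lasso.max_outer` (50), `weights` (c(1,1,1,1,75)),
#'   `fusion.N_c` (6), `seed` (1).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    kde.bandwidth_scale = 1.0,
    grid.N = 9L,
    grid.K = 41L,
    widths = c(0.03, 0.05, 0.10, 0.15, 0.20, 0.30, 0.40),
    lasso.lambda = 1e-5,
    lasso.threshold = 1e-9,
    lasso.target_nnz = 400L,
    lasso.max_outer = 50L,
    weights = c(1, 1, 1, 1, 75),
    fusion.N_c = 6L,
    seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stopf("run_config: unknown key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$grid.N >= 3, cfg$grid.N %% 2 == 1,
            cfg$lasso.lambda > 0, cfg$lasso.threshold > 0,
            cfg$lasso.target_nnz >= 1, length(cfg$weights) == 5,
            cfg$fusion.N_c >= 2)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a flat key: value (YAML-style) text file
#'
#' @param path file of `key: value` lines; vector values comma-separated;
#'   `#` comments allowed.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, ":", fixed = TRUE)
  over <- stats::setNames(
    lapply(kv, function(p) {
      v <- trimws(paste(p[-1], collapse = ":"))
      vals <- suppressWarnings(as.numeric(trimws(strsplit(v, ",")[[1]])))
      if (any(is.na(vals))) stopf("read_run_config: bad value '%s'", v)
      vals
    }),
    vapply(kv, function(p) trimws(p[[1]]), character(1)))
  for (k in c("grid.N", "grid.K", "lasso.target_nnz", "lasso.max_outer",
              "fusion.N_c", "seed"))
    if (k %in% names(over)) over[[k]] <- as.integer(over[[k]])
  run_config(over)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the whole pipeline: marginals, fusion, three joint fits, report
#'
#' Composes the stages end to end and writes a model directory: the six
#' normalized marginals, the fitted fusion model, one fitted joint
#' density per outcome (per-outcome 4D fits), a supplied-vs-recovered
#' fidelity report, and a manifest carrying the resolved configuration
#' and its hash.  Deterministic for a fixed config seed.
#'
#' @param config a [run_config].
#' @param out_dir output directory (created if missing).
#' @param fixtures if `TRUE` (default) generate inputs from the synthetic
#'   suite; otherwise `inputs` must name real input files.
#' @param inputs when `fixtures = FALSE`: list with `sources` (observation
#'   CSV path covering all six variables; stress may span several units)
#'   and `effects` (effect-size CSV path).
#' @param fixture_sizes per-source sample sizes of the synthetic stress
#'   sources when `fixtures = TRUE`.
#' @param verbose print stage progress.
#' @return Invisibly, a list with the fitted `models`, `fusion`,
#'   `marginals`, `fidelity` and the manifest path.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         fixtures = TRUE, inputs = NULL,
                         fixture_sizes = rep(2000L, 4L), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "inputs"
  res <- tryCatch({
    esm <- default_effect_sizes()
    if (fixtures) {
      say("[inputs] synthetic fixture suite (seed %d)", config$seed)
      suite <- gen_marginal_suite(seed = config$seed)
      marginals <- suite$marginals
      fusion_sources <- gen_fusion_sources(default_fusion_truth(),
                                           sizes = fixture_sizes,
                                           seed = config$seed)
    } else {
      if (is.null(inputs$sources) || is.null(inputs$effects))
        stopf("run_pipeline: inputs$sources and inputs$effects required")
      esm <- read_effect_size_csv(inputs$effects)
      vars <- c("sleep", "exertion", "reaction_time",
                "executive_function", "perceptuo_motor")
      marginals <- lapply(stats::setNames(vars, vars), function(v) {
        src <- read_source_csv(inputs$sources, variable = v)
        normalize_axis(estimate_marginal(src, config$kde.bandwidth_scale))
      })
      fusion_sources <- read_source_csv(inputs$sources, variable = "stress")
    }
    stage <- "fusion"
    say("[fusion] fitting %d-component latent mixture over %d sources",
        config$fusion.N_c, length(fusion_sources))
    fusion <- fit_latent_fusion(fusion_sources,
                                n_components = config$fusion.N_c)
    # the stress marginal is always the fitted latent density, so the
    # joint fits consume the fusion stage's output
    marginals$stress <- normalize_axis(fused_marginal(fusion))
    write_fusion_model(fusion, file.path(out_dir, "fusion_model.json"))
    stage <- "marginals"
    for (v in names(marginals)) {
      if (is.null(marginals[[v]]))
        stopf("run_pipeline: missing marginal for variable '%s'", v)
      write_grid_pdf(marginals[[v]],
                     file.path(out_dir, paste0("marginal_", v, ".csv")))
    }
    stage <- "joint"
    outcomes <- c("reaction_time", "executive_function", "perceptuo_motor")
    predictors <- c("stress", "sleep", "exertion")
    models <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
      say("[joint] fitting outcome '%s' (N = %d, K = %d)", oc,
          config$grid.N, config$grid.K)
      mg <- c(marginals[oc], marginals[predictors])
      fit <- fit_joint_density(mg, esm, outcome = oc,
                               n_per_axis = config$grid.N,
                               widths = config$widths,
                               lam = config$lasso.lambda,
                               threshold = config$lasso.threshold,
                               target_nnz = config$lasso.target_nnz,
                               k_points = config$grid.K,
                               block_weights = config$weights,
                               max_outer = config$lasso.max_outer)
      write_joint_density(fit, file.path(out_dir, paste0("joint_", oc, ".csv")))
      fit
    })
    stage <- "report"
    fidelity <- lapply(models, recovered_stats)
    rep_rows <- do.call(rbind, lapply(names(fidelity), function(oc)
      data.frame(outcome = oc, predictor = predictors,
                 supplied = fidelity[[oc]]$r_supplied,
                 recovered = fidelity[[oc]]$r_recovered,
                 abs_error = fidelity[[oc]]$r_abs_error,
                 marginal_l1_outcome = fidelity[[oc]]$marginal_l1[1])))
    utils::write.csv(rep_rows, file.path(out_dir, "fidelity_report.csv"),
                     row.names = FALSE)
    manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(format = "perfdens.manifest", version = 1L,
           config = unclass(config), config_hash = config_hash(config),
           outcomes = outcomes,
           files = list(fusion = "fusion_model.json",
                        marginals = paste0("marginal_", names(marginals),
                                           ".csv"),
                        joints = paste0("joint_", outcomes, ".csv"),
                        fidelity = "fidelity_report.csv")),
      manifest, auto_unbox = TRUE, digits = NA)
    list(models = models, fusion = fusion, marginals = marginals,
         fidelity = fidelity, manifest = manifest)
  }, error = function(e) {
    stopf("run_pipeline failed at stage '%s': %s", stage,
          conditionMessage(e))
  })
  invisible(res)
}
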