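#' Serialise a fitted model to versioned JSON
#'
#' Stores knots, covariate layout, coefficients, covariance and convergence
#' diagnostics so predictions are exactly reproducible from the file.
#'
#' @param model a fitted [relsurv_fpm()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  lay <- model$layout
  doc <- list(
    format = "lifelost-relsurv-model", version = 1L,
    coefficients = as.list(model$coefficients),
    vcov = model$vcov,
    layout = list(
      baseline_knots = lay$baseline$knots,
      age_knots = if (is.null(lay$age_spec)) NULL else lay$age_spec$knots,
      td_knots = if (is.null(lay$td_spec)) NULL else lay$td_spec$knots,
      ref_age = lay$ref_age, use_dep = lay$use_dep,
      interaction = lay$interaction, td_cov = lay$td_cov,
      sex = lay$sex, colnames = lay$colnames),
    diagnostics = list(loglik = model$loglik, grad_norm = model$grad_norm,
                       iterations = model$iterations,
                       convergence = model$convergence,
                       n = model$n, n_events = model$n_events,
                       n_hazard_violations = model$n_hazard_violations,
                       follow_up_max = model$follow_up_max))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model serialised by [write_model_json()]
#'
#' @param path JSON file.
#' @return a `relsurv_fpm` object usable with all prediction functions.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "lifelost-relsurv-model"))
    stop("not a lifelost model file: ", path)
  lay <- doc$layout
  layout <- list(
    baseline = rcs_spec(lay$baseline_knots),
    age_spec = if (length(lay$age_knots) < 2) NULL else
      rcs_spec(unlist(lay$age_knots)),
    ref_age = lay$ref_age, use_dep = lay$use_dep,
    interaction = lay$interaction,
    td_cov = if (length(lay$td_cov)) unlist(lay$td_cov) else character(0),
    td_spec = if (length(lay$td_knots) < 2) NULL else
      rcs_spec(unlist(lay$td_knots)),
    sex = lay$sex, colnames = lay$colnames)
  co <- unlist(doc$coefficients)
  vc <- doc$vcov
  if (!is.null(vc)) dimnames(vc) <- list(names(co), names(co))
  structure(list(coefficients = co, vcov = vc, layout = layout,
                 loglik = doc$diagnostics$loglik,
                 grad_norm = doc$diagnostics$grad_norm,
                 iterations = doc$diagnostics$iterations,
                 convergence = doc$diagnostics$convergence,
                 n = doc$diagnostics$n,
                 n_events = doc$diagnostics$n_events,
                 n_hazard_violations = doc$diagnostics$n_hazard_violations,
                 follow_up_max = doc$diagnostics$follow_up_max),
            class = "relsurv_fpm")
}

pipeline_stages <- c("inputs", "prepare", "fit", "predict", "standardize",
                     "render")

validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(window = c(2007.0, 2014.0),
                   model = list(df_baseline = 5, df_age = 3, df_td = 3,
                                td = c("dep", "age")),
                   weights = "internal", average = "by-age",
                   pll = "mean_of_ratios",
                   year = 2013L, dx_year = 2013.0, gl_order = 15,
                   tau = NULL, seed = NULL, verbose = TRUE)
  config <- modifyList(defaults, config)
  if (is.null(config$out_dir)) stop("config error: 'out_dir' is required")
  has_scenario <- !is.null(config$scenario)
  has_paths <- !is.null(config$registry) && !is.null(config$lifetable)
  if (!has_scenario && !has_paths)
    stop("config error: supply either 'scenario' (synthetic run) or both ",
         "'registry' and 'lifetable' file paths")
  if (length(config$window) != 2L || config$window[2] <= config$window[1])
    stop("config error: window must be [start, end) with end > start")
  if (has_scenario && !is.null(config$seed))
    config$scenario$seed <- config$seed
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> period preparation -> model fitting
#' per cancer and sex -> age-specific loss in expectation of life ->
#' standardisation -> CSV/JSON artifact rendering, from a single config
#' (a list or a YAML file).  The config is schema-validated before any
#' stage runs; a `state.json` marker in the output directory records
#' completed stages so a partial failure is inspectable and resumable by
#' rerunning.
#'
#' Config fields: `out_dir` (required); either `scenario` (arguments to
#' [lel_scenario()]) or `registry`/`lifetable` file paths; `window`;
#' `model` (list: `df_baseline`, `df_age`, `df_td`, `td`); `weights`
#' (`"internal"`/`"pooled"`); `average`; `pll`; `year`; `dx_year`; `tau`;
#' `gl_order`; `seed` (overrides the scenario seed); `verbose`.
#'
#' @param config list or YAML path.
#' @return (invisibly) list with `summary`, `profiles`, `models`, `paths`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state_path <- file.path(config$out_dir, "state.json")
  done <- character(0)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, msg)
    if (isTRUE(config$verbose)) message(msg)
  }
  mark <- function(stage) {
    done <<- c(done, stage)
    jsonlite::write_json(list(completed = done), state_path,
                         auto_unbox = TRUE)
  }
  run_stage <- function(stage, expr) {
    say("stage ", stage, " ...")
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    mark(stage)
    out
  }

  inputs <- run_stage("inputs", {
    if (!is.null(config$scenario)) {
      sc <- do.call(lel_scenario, config$scenario)
      lt <- make_life_table(sc)
      list(scenario = sc, table = lt, registry = simulate_registry(sc, lt))
    } else {
      list(scenario = NULL, table = read_life_table(config$lifetable),
           registry = read_registry(config$registry))
    }
  })

  prep <- run_stage("prepare", {
    reg <- first_tumour_filter(inputs$registry)
    list(cohort = reg,
         strata = split(reg, list(reg$cancer, reg$sex), drop = TRUE))
  })

  models <- run_stage("fit", {
    ms <- list()
    for (nm in names(prep$strata)) {
      s <- prep$strata[[nm]]
      pd <- make_period_dataset(s, config$window[1], config$window[2])
      m <- config$model
      fit <- relsurv_fpm(pd, inputs$table,
                         df_baseline = m$df_baseline, df_age = m$df_age,
                         df_td = m$df_td, td = m$td)
      ms[[s$cancer[1]]][[s$sex[1]]] <- fit
      say("  fitted ", nm, ": n=", fit$n, " events=", fit$n_events,
          " loglik=", format(fit$loglik, digits = 8))
    }
    ms
  })

  profiles <- run_stage("predict", {
    out <- list()
    for (cz in names(models)) for (sx in names(models[[cz]])) {
      sub <- prep$cohort[prep$cohort$cancer == cz & prep$cohort$sex == sx, ]
      for (dep in 1:5) {
        ages <- internal_weights(sub, dep, config$year)$weights$age
        pr <- age_profile(models[[cz]][[sx]], inputs$table, ages, sx, dep,
                          config$dx_year, tau = config$tau,
                          gl_order = config$gl_order)
        pr <- cbind(cancer = cz, sex = sx, dep = dep, pr)
        out[[length(out) + 1L]] <- pr
      }
    }
    do.call(rbind, out)
  })

  summary <- run_stage("standardize", {
    summary_table(models, inputs$table, prep$cohort,
                  weights = config$weights, year = config$year,
                  average = config$average, dx_year = config$dx_year,
                  pll = config$pll, tau = config$tau,
                  gl_order = config$gl_order)
  })

  paths <- run_stage("render", {
    mdir <- file.path(config$out_dir, "models")
    dir.create(mdir, showWarnings = FALSE)
    for (cz in names(models)) for (sx in names(models[[cz]]))
      write_model_json(models[[cz]][[sx]],
                       file.path(mdir, paste0(cz, "_", sx, ".json")))
    ppath <- file.path(config$out_dir, "age_profiles.csv")
    utils::write.csv(profiles, ppath, row.names = FALSE)
    tabs <- render_tables(summary, config$out_dir)
    log_path <- file.path(config$out_dir, "run.log")
    writeLines(c(paste("lifelost", as.character(utils::packageVersion("lifelost"))),
                 paste("R", R.version.string),
                 paste("seed", if (!is.null(inputs$scenario))
                   inputs$scenario$seed else "NA"),
                 log_lines), log_path)
    c(tabs, age_profiles = ppath, models = mdir, log = log_path)
  })

  invisible(list(summary = summary, profiles = profiles, models = models,
                 paths = paths, config = config))
}

#' Render presentation tables
#'
#' Writes three CSVs: `summary_full.csv` (all quantities at full
#' precision — the canonical round-trippable output), `table_means.csv`
#' (average LEL in years and average percentage of life lost per quintile,
#' rounded to 2 dp at presentation only) and `table_totals.csv`
#' (reference-year group sizes, mean years lost and total life-years lost,
#' one row per cancer and quintile with explicit blank cells for a sex a
#' cancer does not occur in).  Totals are computed from full-precision
#' means, never from the rounded presentation values.
#'
#' @param summary a [summary_table()] result.
#' @param dir output directory.
#' @return named character vector of file paths.
#' @export
render_tables <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  full <- file.path(dir, "summary_full.csv")
  utils::write.csv(as.data.frame(summary), full, row.names = FALSE)

  means <- do.call(rbind, lapply(split(summary, list(summary$cancer, summary$sex),
                                       drop = TRUE), function(s) {
    s <- s[order(s$dep), ]
    data.frame(cancer = s$cancer[1], sex = s$sex[1],
               t(stats::setNames(round(s$mean_LEL, 2), paste0("lel_dep", s$dep))),
               t(stats::setNames(round(100 * s$mean_PLL, 2), paste0("pll_dep", s$dep))))
  }))
  mpath <- file.path(dir, "table_means.csv")
  utils::write.csv(means, mpath, row.names = FALSE)

  cancers <- unique(summary$cancer)
  rows <- list()
  for (cz in cancers) for (dep in 1:5) {
    row <- list(cancer = cz, dep = dep)
    for (sx in c("M", "F")) {
      s <- summary[summary$cancer == cz & summary$sex == sx &
                     summary$dep == dep, ]
      pre <- if (sx == "M") "males_" else "females_"
      if (nrow(s) == 1L) {
        row[[paste0(pre, "n")]] <- s$N_2013
        row[[paste0(pre, "mean")]] <- round(s$mean_LEL, 2)
        row[[paste0(pre, "total")]] <- round(s$total_years_lost)
      } else {
        row[[paste0(pre, "n")]] <- NA
        row[[paste0(pre, "mean")]] <- NA
        row[[paste0(pre, "total")]] <- NA
      }
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row)
  }
  totals <- do.call(rbind, rows)
  tpath <- file.path(dir, "table_totals.csv")
  utils::write.csv(totals, tpath, row.names = FALSE, na = "")
  c(summary_full = full, table_means = mpath, table_totals = tpath)
}
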