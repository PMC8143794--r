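# Reproducible multi-stage runs over the package's analysis surface. Each
# stage reads the previous stage's TSV/epoch artifacts from the output
# directory, so runs can be split across invocations; a JSON manifest records
# seeds, parameters and file digests.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; all stage seeds derive from it by fixed offsets.
#' @param n_subjects,n_blocks,trials_per_block Simulation sizes.
#' @param n_perm Permutations for the `permute` stage.
#' @param n_parcels Parcels for the `decode` stage.
#' @param grid,ridge,decode Stage parameter objects ([build_window_grid()],
#'   [ridge_config()], [decode_config()]).
#' @param effects,noise,behav Generator specifications.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_subjects = 3, n_blocks = 1,
                            trials_per_block = 128, n_perm = 100,
                            n_parcels = 12,
                            grid = build_window_grid(),
                            ridge = ridge_config(seed = seed),
                            decode = decode_config(seed = seed),
                            effects = effect_spec(),
                            noise = noise_spec(),
                            behav = behav_coefficients()) {
  structure(
    list(
      out_dir = out_dir, seed = seed, n_subjects = n_subjects,
      n_blocks = n_blocks, trials_per_block = trials_per_block,
      n_perm = n_perm, n_parcels = n_parcels, grid = grid, ridge = ridge,
      decode = decode, effects = effects, noise = noise, behav = behav
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields of [pipeline_config()] may be overridden from a file; nested
#' stage parameters accept the fields of [ridge_config()],
#' [build_window_grid()] and [decode_config()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param out_dir Output directory (overrides any value in the file).
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  args <- raw[intersect(names(raw), c(
    "seed", "n_subjects", "n_blocks", "trials_per_block", "n_perm", "n_parcels"
  ))]
  args$out_dir <- out_dir %||% raw$out_dir %||% "."
  if (!is.null(raw$grid)) args$grid <- do.call(build_window_grid, raw$grid)
  if (!is.null(raw$ridge)) args$ridge <- do.call(ridge_config, raw$ridge)
  if (!is.null(raw$decode)) args$decode <- do.call(decode_config, raw$decode)
  do.call(pipeline_config, args)
}

pipeline_stages <- function() {
  c(
    "simulate", "design_check", "fit_glm", "permute", "peaks", "trace",
    "behav", "decode"
  )
}

stage_path <- function(config, name) file.path(config$out_dir, name)

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s' requires missing artifact '%s'", stage, path),
      call. = FALSE)
  }
  path
}

read_subject_tables <- function(config, stage) {
  files <- sort(Sys.glob(file.path(config$out_dir, "trials_sub*.tsv")))
  if (!length(files)) {
    stop(sprintf("stage '%s' requires missing artifact '%s'",
      stage, file.path(config$out_dir, "trials_sub*.tsv")), call. = FALSE)
  }
  purrr::map(files, read_trial_table)
}

write_stage_tsv <- function(x, path, config) {
  write_trial_table_comment <- sprintf("seed=%d", config$seed)
  writeLines(paste0("# ", write_trial_table_comment), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order: `simulate`,
#' `design_check`, `fit_glm`, `permute`, `peaks`, `trace`, `behav`, `decode`.
#' Stages exchange TSV/epoch artifacts through `config$out_dir`, so a later
#' call can consume an earlier call's outputs; a missing dependency raises an
#' error naming the absent artifact. A `manifest.json` recording versions,
#' seeds, parameters and output digests is (re)written after every run.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of stage names (default: all).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, stages = pipeline_stages()) {
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in stages) {
    message(sprintf("[choicetrace] stage=%s seed=%d", st, config$seed))
    switch(st,
      simulate = {
        dat <- simulate_rs_dataset(
          config$n_subjects, config$n_blocks * config$trials_per_block,
          effects = config$effects, noise = config$noise,
          coef = config$behav, seed = config$seed
        )
        for (d in dat) {
          d$trials$subject <- d$subject
          trials_out <- d$trials[, trial_table_columns()]
          write_trial_table(
            trials_out,
            file.path(config$out_dir, sprintf("trials_%s.tsv", d$subject)),
            comment = sprintf("seed=%d subject=%s", config$seed, d$subject)
          )
          write_epochs(
            d$epochs,
            file.path(config$out_dir, sprintf("epochs_%s.txt", d$subject))
          )
        }
      },
      design_check = {
        tables <- read_subject_tables(config, st)
        trials <- tables[[1]]
        design <- code_rs_regressors(trials)
        write_stage_tsv(
          design_correlations(design),
          file.path(config$out_dir, "design_correlations.tsv"), config
        )
        counts <- dplyr::count(
          tibble::tibble(condition = condition_label(trials)), .data$condition
        )
        write_stage_tsv(
          counts, file.path(config$out_dir, "condition_counts.tsv"), config
        )
      },
      fit_glm = {
        tables <- read_subject_tables(config, st)
        series <- purrr::imap_dfr(tables, function(trials, i) {
          sid <- sprintf("sub%02d", i)
          ep <- read_epochs(require_artifact(
            file.path(config$out_dir, sprintf("epochs_%s.txt", sid)), st
          ))
          keep <- !is.na(trials$ts_correct) & trials$ts_correct == 1
          ep$data <- ep$data[keep, , drop = FALSE]
          fit_subsampled_glm(
            ep, code_rs_regressors(trials[keep, ]),
            grid = config$grid, config = config$ridge, subject = sid
          )
        })
        write_stage_tsv(
          series, file.path(config$out_dir, "coefficients.tsv"), config
        )
      },
      permute = {
        tables <- read_subject_tables(config, st)
        eps <- list()
        designs <- list()
        for (i in seq_along(tables)) {
          sid <- sprintf("sub%02d", i)
          ep <- read_epochs(require_artifact(
            file.path(config$out_dir, sprintf("epochs_%s.txt", sid)), st
          ))
          keep <- !is.na(tables[[i]]$ts_correct) & tables[[i]]$ts_correct == 1
          ep$data <- ep$data[keep, , drop = FALSE]
          eps[[i]] <- ep
          designs[[i]] <- code_rs_regressors(tables[[i]][keep, ])
        }
        obs_path <- require_artifact(
          file.path(config$out_dir, "coefficients.tsv"), st
        )
        series <- readr::read_tsv(obs_path, comment = "#", progress = FALSE,
          show_col_types = FALSE)
        grp <- group_series(list(
          series |>
            dplyr::group_by(.data$window_center_ms, .data$regressor) |>
            dplyr::summarise(coef = mean(.data$coef), .groups = "drop")
        ))
        null <- permutation_null(eps, designs,
          grid = config$grid,
          config = config$ridge, n_perm = config$n_perm,
          seed = config$seed + 11L
        )
        write_stage_tsv(
          permutation_pvalues(grp, null),
          file.path(config$out_dir, "pvalues.tsv"), config
        )
      },
      peaks = {
        obs_path <- require_artifact(
          file.path(config$out_dir, "coefficients.tsv"), st
        )
        series <- readr::read_tsv(obs_path, comment = "#", progress = FALSE,
          show_col_types = FALSE)
        peaks <- dplyr::bind_rows(
          loo_peak_times(series, "rel_adapt"),
          loo_peak_times(series, "resp_adapt")
        )
        write_stage_tsv(peaks, file.path(config$out_dir, "peaks.tsv"), config)
      },
      trace = {
        obs_path <- require_artifact(
          file.path(config$out_dir, "coefficients.tsv"), st
        )
        series <- readr::read_tsv(obs_path, comment = "#", progress = FALSE,
          show_col_types = FALSE) |>
          dplyr::group_by(.data$window_center_ms, .data$regressor) |>
          dplyr::summarise(coef = mean(.data$coef), .groups = "drop")
        trace <- build_choice_trace(series,
          input_regressor = c("rel_adapt", "irrel_adapt")
        )
        write_stage_tsv(trace, file.path(config$out_dir, "choice_trace.tsv"),
          config)
      },
      behav = {
        tables <- read_subject_tables(config, st)
        trials <- purrr::imap_dfr(tables, function(t, i) {
          t$subject <- sprintf("sub%02d", i)
          t
        })
        res <- fit_behav_regressions(trials, min_trials = 20)
        write_stage_tsv(res$group, file.path(config$out_dir, "behav_group.tsv"),
          config)
      },
      decode = {
        tables <- read_subject_tables(config, st)
        trials <- tables[[1]]
        loadings <- default_loadings(config$n_parcels,
          seed = config$seed + 23L
        )
        enc_effects <- effect_spec(
          regressor = encoding_regressors(),
          shape = c("half_gaussian_sustained", rep("gaussian_bump", 3)),
          onset_ms = c(8, 108, 108, 275),
          peak_ms = c(150, 429.5, 429.5, 531.1),
          width_ms = c(150, 300, 300, 300),
          amplitude = c(0.5, 1, 1, 0.8)
        )
        parcels <- simulate_parcel_epochs(
          code_encoding_regressors(trials), loadings, enc_effects,
          noise = config$noise, seed = config$seed + 29L
        )
        res <- decode_relevant_irrelevant(parcels, trials,
          config = config$decode
        )
        write_stage_tsv(res$by_context,
          file.path(config$out_dir, "decoding.tsv"), config)
      }
    )
  }
  manifest <- list(
    package = "choicetrace",
    package_version = as.character(utils::packageVersion("choicetrace")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    parameters = list(
      n_subjects = config$n_subjects, n_blocks = config$n_blocks,
      trials_per_block = config$trials_per_block, n_perm = config$n_perm,
      n_parcels = config$n_parcels,
      grid = config$grid[c("step_ms", "half_width_ms")],
      lambda_grid = config$ridge$lambda_grid,
      n_subsamples = config$ridge$n_subsamples,
      subsample_fraction = config$ridge$subsample_fraction
    ),
    stages_run = stages,
    outputs = {
      files <- setdiff(list.files(config$out_dir), "manifest.json")
      as.list(stats::setNames(
        unname(tools::md5sum(file.path(config$out_dir, files))), files
      ))
    }
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}
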