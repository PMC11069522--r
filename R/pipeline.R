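# End-to-end orchestration: simulate -> preprocess -> fit -> report, with a
# JSON run manifest tying outputs to seeds, digests and the package version.

.manifest_append <- function(dir, stage, files, seed = NULL, extra = list()) {
  path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  files <- files[file.exists(files)]
  digests <- as.list(unname(tools::md5sum(files)))
  names(digests) <- basename(files)
  manifest[[length(manifest) + 1]] <- c(list(
    stage = stage, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("zibgaze")),
    seed = seed, outputs = digests), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a synthetic experiment to disk
#'
#' Runs [generate_experiment()] and writes the bundle as plain files:
#' `personality.csv`, `weights.csv`, `gaze.csv` (gaze fidelity only),
#' `masks/<image_id>.png/.json`, `ground_truth.json`, `dataset.json`
#' (design metadata) and a run manifest.
#'
#' @param config An [experiment_config()].
#' @param seed Root seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
pipeline_simulate <- function(config = experiment_config(), seed = 1,
                              out_dir = "dataset") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  bundle <- generate_experiment(config, seed = seed)
  files <- c(
    write_personality(bundle$personality, file.path(out_dir, "personality.csv")),
    write_weight_table(bundle$weights, file.path(out_dir, "weights.csv")),
    write_ground_truth(bundle$truth, file.path(out_dir, "ground_truth.json")))
  if (!is.null(bundle$gaze))
    files <- c(files, write_gaze(bundle$gaze, file.path(out_dir, "gaze.csv")))
  for (img in names(bundle$masks))
    files <- c(files, write_mask(bundle$masks[[img]],
                                 file.path(out_dir, "masks", img)))
  meta <- file.path(out_dir, "dataset.json")
  jsonlite::write_json(
    list(fidelity = config$fidelity, width = config$width,
         height = config$height, screen = config$screen,
         duration_s = config$duration_s, sample_rate_hz = config$sample_rate_hz,
         jitter_sd = config$jitter_sd, participants = config$participants,
         images_per_impression = config$images_per_impression,
         impressions = config$impressions, conditions = config$conditions,
         trials_per_condition = config$trials_per_condition, seed = seed),
    meta, auto_unbox = TRUE, digits = NA)
  files <- c(files, meta)
  .manifest_append(out_dir, "simulate", files, seed = seed)
  invisible(out_dir)
}

#' Preprocess a dataset directory into a region-weight table
#'
#' Weight-fidelity datasets pass through (`weights.csv` is copied); for gaze
#' fidelity the gaze streams are pushed through the full preprocessing chain
#' against the stored masks.
#'
#' @param dataset_dir Directory written by [pipeline_simulate()] (or laid out
#'   the same way).
#' @param out_file Output CSV path; default `weights_processed.csv` inside
#'   `dataset_dir`.
#' @param sigma Density-map Gaussian SD in pixels.
#' @return Invisibly, `out_file`.
#' @export
pipeline_preprocess <- function(dataset_dir,
                                out_file = file.path(dataset_dir,
                                                     "weights_processed.csv"),
                                sigma = 10) {
  meta_path <- file.path(dataset_dir, "dataset.json")
  if (!file.exists(meta_path))
    stop("missing resource: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (identical(meta$fidelity, "gaze")) {
    gaze <- read_gaze(file.path(dataset_dir, "gaze.csv"))
    img_ids <- unique(gaze$image_id)
    masks <- lapply(img_ids, function(img) {
      p <- file.path(dataset_dir, "masks", img)
      if (!file.exists(paste0(p, ".png")))
        stop("missing resource: mask for image ", img, call. = FALSE)
      read_mask(p)
    })
    names(masks) <- img_ids
    bundle <- list(gaze = gaze, masks = masks,
                   config = list(width = meta$width, height = meta$height,
                                 screen = meta$screen))
    tab <- build_weight_table(bundle, sigma = sigma)
  } else {
    tab <- read_weight_table(file.path(dataset_dir, "weights.csv"))
  }
  write_weight_table(tab, out_file)
  .manifest_append(dirname(out_file), "preprocess", out_file)
  invisible(out_file)
}

#' Fit the ZIB model over a set of cells
#'
#' Fits one model per distinct (condition, impression, region) cell present
#' in the (optionally scope-filtered) weight table and writes each posterior
#' as `<condition>_<impression>_<region>.csv/.json`.
#'
#' @param weights_file Region-weight CSV.
#' @param personality_file Personality CSV.
#' @param out_dir Output directory for posterior files.
#' @param scope Optional named list with any of `condition`, `impression`,
#'   `region` to filter the cells fitted.
#' @param config An [mcmc_config()].
#' @param backend Sampler backend, see [fit_zib()].
#' @param quiet Suppress progress.
#' @return Invisibly, the vector of posterior path prefixes.
#' @export
pipeline_fit <- function(weights_file, personality_file, out_dir = "fits",
                         scope = NULL, config = mcmc_config(),
                         backend = "jags", quiet = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  weights <- read_weight_table(weights_file)
  personality <- read_personality(personality_file)
  if (!is.null(scope)) {
    scope <- as.list(scope)
    for (f in intersect(names(scope), c("condition", "impression", "region")))
      weights <- weights[weights[[f]] %in% scope[[f]], , drop = FALSE]
  }
  if (nrow(weights) == 0) stop("no data in the requested scope", call. = FALSE)
  cells <- unique(weights[, c("condition", "impression", "region")])
  prefixes <- character(0)
  files <- character(0)
  for (k in seq_len(nrow(cells))) {
    cell <- cells[k, ]
    fit <- fit_zib(weights, personality, scope = as.list(cell),
                   config = config, backend = backend, quiet = quiet)
    prefix <- file.path(out_dir, paste(cell$condition, cell$impression,
                                       cell$region, sep = "_"))
    files <- c(files, write_posterior(fit, prefix))
    prefixes <- c(prefixes, prefix)
    if (!quiet)
      message(sprintf("fitted %s (%d draws)", basename(prefix), n_draws(fit)))
  }
  .manifest_append(out_dir, "fit", files, seed = config$seed,
                   extra = list(cells = nrow(cells), backend = backend))
  invisible(prefixes)
}

#' Report on a directory of posterior fits
#'
#' Reads every posterior in `fit_dir`, writes a per-fit convergence report
#' (JSON), the significance table (CSV), and, for every (condition,
#' impression) with all six regions fitted, the trait-sweep curves for
#' `sweep_trait` (CSV, optional plots); when both conditions are present the
#' restricted-minus-free difference sweep is written as well.
#'
#' @param fit_dir Directory of posterior files from [pipeline_fit()].
#' @param out_dir Report output directory.
#' @param sweep_trait Trait swept in the simulation curves.
#' @param plots Also write PNG panels for the sweeps.
#' @param mass HDI mass.
#' @return Invisibly, `out_dir`.
#' @export
pipeline_report <- function(fit_dir, out_dir = file.path(fit_dir, "report"),
                            sweep_trait = "conscientiousness", plots = FALSE,
                            mass = 0.95) {
  prefixes <- sub("\\.json$", "",
                  list.files(fit_dir, pattern = "\\.json$", full.names = TRUE))
  prefixes <- prefixes[file.exists(paste0(prefixes, ".csv"))]
  if (length(prefixes) == 0) stop("no posterior files in ", fit_dir,
                                  call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- lapply(prefixes, read_posterior)
  conv <- lapply(fits, function(f) {
    cc <- check_convergence(f)
    list(model_id = .fit_model_id(f), chains = attr(cc, "chains"),
         max_rhat = attr(cc, "max_rhat"), passed = attr(cc, "passed"),
         rhat = stats::setNames(as.list(cc$rhat), cc$parameter))
  })
  conv_path <- file.path(out_dir, "convergence.json")
  jsonlite::write_json(conv, conv_path, auto_unbox = TRUE, digits = NA)
  sig <- significance_table(fits, mass = mass)
  sig_path <- file.path(out_dir, "significance.csv")
  utils::write.csv(as.data.frame(sig), sig_path, row.names = FALSE)
  files <- c(conv_path, sig_path)

  scopes <- data.frame(
    condition = vapply(fits, function(f) f$scope$condition, character(1)),
    impression = vapply(fits, function(f) f$scope$impression, character(1)),
    region = vapply(fits, function(f) f$scope$region, character(1)))
  sweeps <- list()
  for (cond in unique(scopes$condition)) {
    for (imp in unique(scopes$impression[scopes$condition == cond])) {
      sel <- which(scopes$condition == cond & scopes$impression == imp)
      if (!setequal(scopes$region[sel], .REGIONS)) next
      sw <- trait_sweep(fits[sel], sweep_trait, mass = mass)
      sweeps[[paste(cond, imp)]] <- sw
      files <- c(files, export_sweep(
        sw, file.path(out_dir, paste(cond, imp, sweep_trait, sep = "_")),
        plot = plots))
    }
  }
  for (imp in unique(scopes$impression)) {
    r <- sweeps[[paste("restricted", imp)]]
    f <- sweeps[[paste("free", imp)]]
    if (!is.null(r) && !is.null(f))
      files <- c(files, export_sweep(
        condition_difference(r, f, mass = mass),
        file.path(out_dir, paste("diff", imp, sweep_trait, sep = "_")),
        plot = plots))
  }
  .manifest_append(out_dir, "report", files)
  invisible(out_dir)
}

#' Run the whole pipeline
#'
#' simulate -> preprocess -> fit -> report under one root seed, into
#' `out_dir/dataset`, `out_dir/fits`, `out_dir/report`.
#'
#' @param config An [experiment_config()].
#' @param seed Root seed; stage seeds derive from it.
#' @param out_dir Root output directory.
#' @param mcmc An [mcmc_config()]; its seed is replaced by a seed derived
#'   from `seed`.
#' @param scope Optional scope filter for the fitting stage.
#' @param sweep_trait Trait for the report sweeps.
#' @param backend Sampler backend.
#' @return Invisibly, `out_dir`.
#' @export
pipeline_run <- function(config = experiment_config(), seed = 1,
                         out_dir = "zibgaze_run", mcmc = mcmc_config(),
                         scope = NULL, sweep_trait = "conscientiousness",
                         backend = "jags") {
  ds <- file.path(out_dir, "dataset")
  pipeline_simulate(config, seed = seed, out_dir = ds)
  wf <- pipeline_preprocess(ds)
  mcmc$seed <- (as.numeric(seed) * 7919 + 1) %% 2147483647
  pipeline_fit(wf, file.path(ds, "personality.csv"),
               out_dir = file.path(out_dir, "fits"), scope = scope,
               config = mcmc, backend = backend)
  pipeline_report(file.path(out_dir, "fits"),
                  out_dir = file.path(out_dir, "report"),
                  sweep_trait = sweep_trait)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the pipeline functions, used by the
#' `inst/cli.R` Rscript wrapper: `simulate`, `preprocess`, `fit`, `report`,
#' `all`. Flags are `--key value` pairs mirroring the function arguments
#' (`--seed`, `--out`, `--participants`, `--images-per-impression`,
#' `--fidelity`, `--weights`, `--personality`, `--scope
#' condition=...,impression=...,region=...`, `--chains`, `--iterations`,
#' `--warmup`, `--thin`, `--trait`, `--backend`).
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status: 0 ok, 1 usage error, 2 runtime error.
#' @export
zibgaze_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cli.R <simulate|preprocess|fit|report|all> [--flag value ...]")
  if (length(args) == 0) { message(usage); return(1L) }
  cmd <- args[1]
  rest <- args[-1]
  if (length(rest) %% 2 != 0) { message(usage); return(1L) }
  opts <- list()
  if (length(rest))
    opts <- stats::setNames(as.list(rest[seq(2, length(rest), 2)]),
                            sub("^--", "", rest[seq(1, length(rest), 2)]))
  num <- function(key, default) if (is.null(opts[[key]])) default
    else as.numeric(opts[[key]])
  chr <- function(key, default) if (is.null(opts[[key]])) default
    else opts[[key]]
  parse_scope <- function(s) {
    if (is.null(s)) return(NULL)
    kv <- strsplit(strsplit(s, ",")[[1]], "=")
    stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  }
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cfg <- experiment_config(
          participants = num("participants", 42),
          images_per_impression = num("images-per-impression", 10),
          fidelity = chr("fidelity", "weights"))
        pipeline_simulate(cfg, seed = num("seed", 1),
                          out_dir = chr("out", "dataset"))
        0L
      },
      preprocess = {
        pipeline_preprocess(chr("dataset", "dataset"))
        0L
      },
      fit = {
        pipeline_fit(chr("weights", file.path("dataset", "weights_processed.csv")),
                     chr("personality", file.path("dataset", "personality.csv")),
                     out_dir = chr("out", "fits"),
                     scope = parse_scope(opts[["scope"]]),
                     config = mcmc_config(chains = num("chains", 4),
                                          iterations = num("iterations", 2000),
                                          warmup = num("warmup", 1000),
                                          thin = num("thin", 1),
                                          seed = num("seed", 1)),
                     backend = chr("backend", "jags"), quiet = FALSE)
        0L
      },
      report = {
        pipeline_report(chr("fits", "fits"), out_dir = chr("out", "report"),
                        sweep_trait = chr("trait", "conscientiousness"))
        0L
      },
      all = {
        cfg <- experiment_config(
          participants = num("participants", 42),
          images_per_impression = num("images-per-impression", 10),
          fidelity = chr("fidelity", "weights"))
        pipeline_run(cfg, seed = num("seed", 1),
                     out_dir = chr("out", "zibgaze_run"),
                     mcmc = mcmc_config(chains = num("chains", 4),
                                        iterations = num("iterations", 2000),
                                        warmup = num("warmup", 1000),
                                        thin = num("thin", 1)),
                     scope = parse_scope(opts[["scope"]]),
                     sweep_trait = chr("trait", "conscientiousness"),
                     backend = chr("backend", "jags"))
        0L
      },
      { message("unknown command: ", cmd, "\n", usage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 2L })
  status
}
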