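# File interfaces: personality / gaze / weight CSVs, mask PNG + JSON sidecar,
# ground-truth JSON, posterior draw CSV + metadata, YAML model configuration.

#' @rdname zib_io
#' @param personality,path,table,gaze See details per function.
#' @name zib_io
NULL

#' Read and write the package's file formats
#'
#' Plain-format interfaces: personality tables and gaze streams as CSV,
#' region masks as 8-bit PNG label images (0 = background, 1..6 = regions in
#' [face_regions()] order) with a JSON sidecar carrying the code map,
#' region-weight tables as CSV with named regions, ground truth as JSON, and
#' posterior draws as long-format CSV plus a JSON metadata sidecar.
#'
#' @param personality A personality table.
#' @param path File path (for masks and posteriors, a prefix without
#'   extension).
#' @return Readers return the object; writers return the path(s) invisibly.
#' @name zib_io
#' @export
write_personality <- function(personality, path) {
  utils::write.csv(personality[, c("participant_id", .TRAITS)], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname zib_io
#' @export
read_personality <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("participant_id", .TRAITS), names(out))
  if (length(missing))
    stop("personality file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out$participant_id <- as.character(out$participant_id)
  out
}

#' @rdname zib_io
#' @export
write_gaze <- function(gaze, path) {
  utils::write.csv(gaze[, c("participant_id", "image_id", "condition",
                            "impression", "t", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname zib_io
#' @export
read_gaze <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$participant_id <- as.character(out$participant_id)
  out$image_id <- as.character(out$image_id)
  out
}

#' @rdname zib_io
#' @param table A region-weight table.
#' @export
write_weight_table <- function(table, path) {
  utils::write.csv(table[, c("participant_id", "image_id", "condition",
                             "impression", "region", "G")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname zib_io
#' @export
read_weight_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$participant_id <- as.character(out$participant_id)
  out$image_id <- as.character(out$image_id)
  out
}

#' @rdname zib_io
#' @param mask A `region_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  png_path <- paste0(path, ".png")
  json_path <- paste0(path, ".json")
  png::writePNG(mask$labels / 255, png_path)
  jsonlite::write_json(
    list(image_id = mask$image_id, width = mask$width, height = mask$height,
         codes = c(background = 0, stats::setNames(1:6, .REGIONS))),
    json_path, auto_unbox = TRUE)
  invisible(c(png_path, json_path))
}

#' @rdname zib_io
#' @export
read_mask <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- round(png::readPNG(paste0(path, ".png")) * 255)
  storage.mode(labels) <- "integer"
  structure(list(image_id = meta$image_id, width = meta$width,
                 height = meta$height, labels = labels),
            class = "region_mask")
}

#' @rdname zib_io
#' @param truth A `zib_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "zib_truth"))
  out <- list(seed = truth$seed,
              params = lapply(truth$params, unclass),
              # named lists keep the participant/image names in JSON
              effects = lapply(truth$effects, function(e) lapply(e, as.list)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname zib_io
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(raw$params, function(p)
    zib_params(p$alpha_bern, unlist(p$beta_bern), p$alpha_beta,
               unlist(p$beta_beta), p$phi, p$sigma_subj_bern,
               p$sigma_pic_bern, p$sigma_subj_beta, p$sigma_pic_beta))
  effects <- lapply(raw$effects, function(e) lapply(e, unlist))
  structure(list(params = params, effects = effects, seed = raw$seed),
            class = "zib_truth")
}

.fit_model_id <- function(fit) {
  paste(fit$scope$condition, fit$scope$impression, fit$scope$region, sep = "|")
}

#' @rdname zib_io
#' @param fit A `zib_fit`.
#' @export
write_posterior <- function(fit, path) {
  stopifnot(inherits(fit, "zib_fit"))
  csv_path <- paste0(path, ".csv")
  json_path <- paste0(path, ".json")
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    d <- fit$draws[[ch]]
    data.frame(model_id = .fit_model_id(fit),
               parameter = rep(colnames(d), each = nrow(d)),
               chain = ch, draw = rep(seq_len(nrow(d)), ncol(d)),
               value = as.vector(d), stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(scope = fit$scope, config = unclass(fit$config),
         prior = unclass(fit$prior), backend = fit$backend,
         parameters = fit$parameters, participants = fit$participants,
         images = fit$images, n_obs = fit$n_obs, n_pos = fit$n_pos,
         data_digest = fit$data_digest),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}

#' @rdname zib_io
#' @export
read_posterior <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  pnames <- meta$parameters
  draws <- lapply(sort(unique(long$chain)), function(ch) {
    d <- long[long$chain == ch, ]
    m <- matrix(NA_real_, max(d$draw), length(pnames),
                dimnames = list(NULL, pnames))
    for (p in pnames) m[, p] <- d$value[d$parameter == p]
    m
  })
  cfg <- mcmc_config(meta$config$chains, meta$config$iterations,
                     meta$config$warmup, meta$config$thin, meta$config$seed)
  prior <- zib_prior(meta$prior$fixed_sd, meta$prior$scale_shape,
                     meta$prior$scale_rate, meta$prior$phi_rate)
  structure(list(draws = draws, parameters = pnames,
                 scope = as.list(meta$scope), config = cfg, prior = prior,
                 backend = meta$backend, participants = meta$participants,
                 images = meta$images, n_obs = meta$n_obs,
                 n_pos = meta$n_pos, data_digest = meta$data_digest),
            class = "zib_fit")
}

#' @rdname zib_io
#' @param config Model/sampler configuration list (or `mcmc_config`).
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(lapply(config, function(x)
    if (is.list(x) || is.function(x)) NULL else x), path)
  invisible(path)
}

#' @rdname zib_io
#' @export
read_model_config <- function(path) yaml::read_yaml(path)
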