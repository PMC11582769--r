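#' Read or write signaling parameters as JSON/YAML
#'
#' Documents are keyed by the parameter symbol names; `dose_map` is stored
#' as a nominal-to-effective mapping.
#'
#' @param params `sig_params`.
#' @param path Output path (`.json`, `.yml`/`.yaml`).
#' @return `write_sig_params` the path, invisibly; `read_sig_params` a
#'   `sig_params`.
#' @export
write_sig_params <- function(params, path) {
  num <- vapply(params, function(v) is.numeric(v) && length(v) == 1,
                logical(1))
  doc <- c(params[num],
           list(model_id = params$model_id,
                greb1_consumption = params$greb1_consumption,
                dose_map = as.list(params$dose_map)))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML output")
    writeLines(yaml::as.yaml(doc), path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_sig_params
#' @export
read_sig_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML input")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  dm <- unlist(doc$dose_map)
  args <- doc[setdiff(names(doc), c("dose_map", "model_id",
                                    "greb1_consumption", "stim_cap",
                                    grep("^s_", names(doc), value = TRUE)))]
  do.call(sig_params, c(list(model_id = doc$model_id), args,
                        list(dose_map = dm,
                             greb1_consumption = isTRUE(doc$greb1_consumption))))
}

#' Write a trajectory as a long-format CSV
#'
#' @param traj `sig_traj` or any wide data.frame with a `time` column.
#' @param path Output CSV path.
#' @param model,dose Optional annotation columns.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, model = attr(traj, "model_id"),
                                 dose = NA) {
  vars <- setdiff(names(traj), "time")
  long <- data.frame(
    time = rep(traj$time, length(vars)),
    variable = rep(vars, each = nrow(traj)),
    value = unlist(traj[vars], use.names = FALSE),
    model = if (is.null(model)) NA else model,
    dose = dose)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a protocol definition from a JSON/YAML config file
#'
#' Recognized fields: `dose_nM`, `knockdown`, `e2_culture`, `starvation_h`,
#' `exposure_h`, `knockdown_h`, `n_cells`, `seed`.
#'
#' @param path Config path.
#' @param params `sig_params` for the dose translation.
#' @return List `protocol` ([protocol()]), `n_cells`, `seed`.
#' @export
read_protocol_config <- function(path, params = sig_params("III")) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML input")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- doc[intersect(names(doc),
                        c("dose_nM", "knockdown", "e2_culture",
                          "starvation_h", "exposure_h", "knockdown_h"))]
  if (!is.null(args$knockdown) && !length(args$knockdown))
    args$knockdown <- NULL
  list(protocol = do.call(protocol, c(args, list(params = params))),
       n_cells = if (is.null(doc$n_cells)) 100L else doc$n_cells,
       seed = if (is.null(doc$seed)) 1L else doc$seed)
}

#' Serialize a signaling fit with provenance
#'
#' @param fit `sig_fit`.
#' @param path JSON output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  doc <- list(model_id = fit$model_id,
              cost = fit$cost,
              coef = as.list(coef(fit)),
              dose_map = as.list(fit$params$dose_map),
              clusters = fit$clusters,
              starts = fit$starts,
              provenance = list(n_starts = fit$config$n_starts,
                                seed = fit$config$seed,
                                max_iter = fit$config$max_iter,
                                fixed = fit$config$fixed))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
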