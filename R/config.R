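# Run configuration: serialization, validation, hashing.

#' Assemble a run configuration
#'
#' A serializable bundle of everything one simulation/analysis run needs:
#' model parameters, dendritic modulation, stimulation protocol and
#' durations, analysis thresholds, and the master seed.  Every field has a
#' default taken from the active fixture; the configuration hash is embedded
#' in all file outputs.
#'
#' @param params a \code{\link{model_params}}.
#' @param mod a \code{\link{dendritic_modulation}}.
#' @param protocol list with \code{t_pre}, \code{K_obs}, \code{t_post},
#'   \code{g0}, \code{stim_mode}.
#' @param analysis list with \code{f_max}, \code{K_min}.
#' @param seed integer master seed.
#' @return an object of class \code{"run_config"}.
#' @export
run_config <- function(params = NULL, mod = NULL,
                       protocol = list(), analysis = list(), seed = 1) {
  fx <- reference_params("nonlinear_ref")
  if (is.null(params)) params <- fx$params
  if (is.null(mod)) mod <- fx$mod
  proto <- utils::modifyList(
    list(t_pre = 50, K_obs = 50, t_post = 20, g0 = 100,
         stim_mode = "random"), protocol)
  ana <- utils::modifyList(list(f_max = 0.1, K_min = 20), analysis)
  structure(list(model = params, modulation = mod, protocol = proto,
                 analysis = ana, seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (hash", config_hash(x), ")\n")
  print(x$model)
  print(x$modulation)
  cat(sprintf("  protocol: t_pre=%g K_obs=%d t_post=%g g0=%d stim=%s\n",
              x$protocol$t_pre, x$protocol$K_obs, x$protocol$t_post,
              x$protocol$g0, x$protocol$stim_mode))
  cat(sprintf("  analysis: f_max=%g K_min=%d; seed=%d\n",
              x$analysis$f_max, x$analysis$K_min, x$seed))
  invisible(x)
}

config_to_list <- function(cfg) {
  list(model = unclass(cfg$model),
       modulation = unclass(cfg$modulation),
       protocol = cfg$protocol, analysis = cfg$analysis, seed = cfg$seed)
}

config_from_list <- function(lst) {
  need <- c("model", "modulation", "protocol", "analysis", "seed")
  miss <- setdiff(need, names(lst))
  if (length(miss))
    stop("config: missing field(s): ", paste(miss, collapse = ", "))
  m <- lst$model
  params <- do.call(model_params,
                    m[intersect(names(m),
                                names(formals(model_params)))])
  md <- lst$modulation
  mod <- if (isTRUE(md$linear)) dendritic_modulation(linear = TRUE)
  else dendritic_modulation(md$theta_b, md$theta_s, md$s_sat)
  run_config(params, mod, protocol = lst$protocol,
             analysis = lst$analysis, seed = lst$seed)
}

#' Save / load a run configuration (YAML or JSON by file extension)
#'
#' @param cfg a \code{\link{run_config}}.
#' @param path file path ending in \code{.yaml}/\code{.yml} or
#'   \code{.json}.
#' @return \code{load_config} returns a validated \code{"run_config"};
#'   round-tripping is idempotent.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lst <- config_to_list(cfg)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("save_config: unknown extension (use .yaml or .json): ", path)
  invisible(path)
}

#' @rdname save_config
#' @param path file path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  config_from_list(lst)
}

#' Configuration hash
#'
#' MD5 of the canonical JSON serialization; embedded in output files so
#' results can be traced back to their exact configuration.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return character scalar (32 hex digits).
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config_to_list(cfg), auto_unbox = TRUE,
                              digits = 12), tmp)
  unname(tools::md5sum(tmp))
}
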