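#' Derive per-component seeds from a global seed
#'
#' Deterministic counter-based expansion of one global seed into
#' independent sub-seeds for trials, calibration runs and fixtures, so a
#' single \code{--seed} reproduces every random draw of a run without seed
#' collisions between components.
#'
#' @param seed Global integer seed.
#' @param stream Integer stream index (vectorised).
#' @return Integer seed(s) in \code{[1, 2^31 - 2]}.
#' @export
expand_seed <- function(seed, stream) {
  m <- 2147483647               # 2^31 - 1 (Mersenne prime modulus)
  s <- (as.numeric(seed) %% m) + 1
  out <- vapply(as.numeric(stream), function(st) {
    x <- (s * 48271 + st * 16807 + 1) %% m
    # one multiplicative mixing round to decorrelate adjacent streams
    x <- (x * 69621) %% m
    if (x == 0) 1 else x
  }, numeric(1))
  as.integer(out)
}

#' Read a run configuration (JSON or YAML)
#'
#' @param path File path; format chosen by extension (\code{.json},
#'   \code{.yaml}/\code{.yml}).
#' @return A nested list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext, " (use JSON or YAML)",
         call. = FALSE)
  }
}

#' Write a fully resolved run configuration beside its outputs
#'
#' @param config Nested list.
#' @param path Output path (written as JSON).
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  config$tool_version <- as.character(utils::packageVersion("coopna"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Build cWB parameters from a configuration list
#'
#' Maps the \code{model} section of a run configuration onto
#' [cwb_params()]; unknown keys raise an error naming the key.
#'
#' @param model Named list: optional \code{wb} sub-list (keys of
#'   [wb_params()]), optional \code{coop} sub-list (keys of
#'   [coop_gate_params()]), plus \code{p}, \code{kappa}, \code{q_noncoop},
#'   \code{coop_kinetics}.
#' @return A [cwb_params()] object.
#' @export
config_to_params <- function(model) {
  if (is.null(model)) return(cwb_params())
  check_keys <- function(lst, allowed, where) {
    bad <- setdiff(names(lst), allowed)
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  check_keys(model, c("wb", "coop", "p", "kappa", "q_noncoop",
                      "coop_kinetics", "mu"), "model")
  wb <- do.call(wb_params, as.list(model$wb %||% list()))
  coop_cfg <- as.list(model$coop %||% list())
  check_keys(coop_cfg, c("v_half", "k", "q", "tau_m", "K", "J"), "model$coop")
  coop <- do.call(coop_gate_params, coop_cfg)
  if (!is.null(model$mu)) coop <- set_coop_mu(coop, model$mu)
  args <- list(wb = wb, coop = coop)
  for (key in c("p", "kappa", "q_noncoop", "coop_kinetics"))
    if (!is.null(model[[key]])) args[[key]] <- model[[key]]
  do.call(cwb_params, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory to CSV
#'
#' Columns: \code{t_ms, v_mV, h, n, m_c, h_c, i_uA_cm2}.
#'
#' @param traj A \code{cwb_trajectory}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
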