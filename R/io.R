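# Serialization: network archives (JSON, one named array per group /
# connection), run configuration (YAML), spike logs and sweep results (CSV).

BN_ARCHIVE_VERSION <- 1L

#' Save a network to a JSON archive
#'
#' The archive is a documented, text-only container: the group parameter
#' table, one named weight matrix per connection (with its wiring flags),
#' the pool layout, and run metadata. A simple content checksum guards
#' against corruption.
#'
#' @param net A `bn_network`.
#' @param path File path to write (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  conns <- lapply(net$conns, function(cn) {
    list(
      source = cn$source, target = cn$target, sign = cn$sign,
      plastic = cn$plastic, supervised = cn$supervised, delay = cn$delay,
      dim = dim(cn$W),
      # full-precision decimal strings so doubles round-trip bit-exactly
      weights = sprintf("%.17g", as.numeric(cn$W))
    )
  })
  groups <- lapply(net$groups, function(g) {
    g[c(
      "name", "module", "axon_type", "grid", "n", "train_only",
      "threshold", "leak", "s_plus", "s_minus"
    )]
  })
  checksum <- sum(vapply(
    net$conns, function(cn) sum(cn$W) + length(cn$W),
    numeric(1)
  ))
  obj <- list(
    format = "neuroburst-network", version = BN_ARCHIVE_VERSION,
    speed = net$speed, binarized = net$binarized,
    target_letter = net$target_letter,
    groups = groups, connections = conns,
    checksum = checksum
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a network from a JSON archive
#'
#' Round-trips [save_network()]: weights, parameters and wiring are
#' restored exactly. A version mismatch or checksum failure raises an
#' explicit error.
#'
#' @param path Archive path.
#' @return A `bn_network`.
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "neuroburst-network")) {
    stop("not a neuroburst network archive: ", path, call. = FALSE)
  }
  if (obj$version != BN_ARCHIVE_VERSION) {
    stop(
      "archive version ", obj$version, " is not supported (expected ",
      BN_ARCHIVE_VERSION, ")",
      call. = FALSE
    )
  }
  net <- build_network(
    speed = obj$speed,
    target_letter = obj$target_letter
  )
  for (nm in names(obj$connections)) {
    rec <- obj$connections[[nm]]
    if (is.null(net$conns[[nm]])) {
      stop("archive connection ", nm, " is unknown to this build", call. = FALSE)
    }
    net$conns[[nm]]$W <- matrix(as.numeric(rec$weights), rec$dim[1], rec$dim[2])
  }
  for (nm in names(obj$groups)) {
    g <- obj$groups[[nm]]
    for (f in c("threshold", "leak", "s_plus", "s_minus")) {
      net$groups[[nm]][[f]] <- g[[f]]
    }
    net$groups[[nm]]$train_only <- g$train_only
  }
  net$binarized <- isTRUE(obj$binarized)
  checksum <- sum(vapply(
    net$conns, function(cn) sum(cn$W) + length(cn$W),
    numeric(1)
  ))
  if (!isTRUE(all.equal(checksum, obj$checksum))) {
    stop("archive checksum mismatch: the file appears corrupted", call. = FALSE)
  }
  net
}

#' Write a tick-indexed spike log as CSV
#'
#' @param spikes A tibble with columns `tick`, `group`, `neuron` (as
#'   returned by [network_tick()] or accumulated by the caller).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_log <- function(spikes, path) {
  utils::write.csv(spikes, path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' A fully serializable description of a run: plasticity constants,
#' training schedule, experiment grids and seeds. A run is reproducible
#' from its configuration alone.
#'
#' @param seed Master seed; per-component sub-seeds are derived from it.
#' @return A nested list of class `bn_run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(
    list(
      seed = as.integer(seed),
      plasticity = unclass(plasticity_config()),
      rewards = unclass(reward_schedule()),
      training = list(
        n_presentations = 400L, epochs = 3L, anneal_horizon = 400L
      ),
      environment = list(speed = 10L, delay = 10L),
      experiments = list(
        motion_levels = seq(0, 0.45, by = 0.03),
        object_levels = seq(0, 0.25, by = 0.01),
        two_object_levels = seq(0, 0.12, by = 0.02),
        n_per_level = 100L
      )
    ),
    class = "bn_run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `bn_run_config` (for writing).
#' @return `read_run_config()` returns a `bn_run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merged <- utils::modifyList(unclass(default_run_config()), cfg)
  merged$seed <- as.integer(merged$seed)
  structure(merged, class = "bn_run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
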