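config_sections <- c("population", "transmission", "fitness", "protocol", "grid")

# YAML 1.1 implicit typing turns the bare key `N` into boolean FALSE; undo it.
fix_n_key <- function(x) {
  if (!is.null(names(x))) names(x)[names(x) == "FALSE"] <- "N"
  x
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    abort(sprintf("config: unknown key(s) under `%s`: %s",
                  where, paste(unknown, collapse = ", ")))
  }
}

#' Read a simulation configuration file
#'
#' Parses a YAML configuration with sections `population` (`N`, `sh`),
#' `transmission` (either a scalar `mu` or a `groups` list of
#' `{fraction, mu}` entries), `fitness` (`median`, `cv`, optional `mode`),
#' `protocol` (all [sim_protocol()] fields) and optionally `grid` (axis
#' vectors for [run_grid()]). Omitted protocol fields take the standard
#' defaults (`p0 = 0.4`, 10,000 generations, burn-in 500, 25 replicates);
#' omitted `sh` and `cv` default to 0. Unknown keys are rejected with their
#' key path.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `params` ([model_params()]), `protocol`
#'   ([sim_protocol()]) and `grid` (tibble or `NULL`).
#' @seealso [write_sim_config()]
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config: no such file: %s", path))
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, config_sections, "<top level>")
  pop <- fix_n_key(cfg$population %||% list())
  check_keys(pop, c("N", "sh"), "population")
  if (is.null(pop$N)) abort("config: `population.N` is required.")

  tr <- cfg$transmission %||% list()
  check_keys(tr, c("mu", "groups"), "transmission")
  transmission <- if (!is.null(tr$groups)) {
    groups <- purrr::map_dfr(tr$groups, function(g) {
      check_keys(g, c("fraction", "mu"), "transmission.groups")
      tibble(fraction = g$fraction, mu = g$mu)
    })
    transmission_profile(mu = groups$mu, fraction = groups$fraction)
  } else if (!is.null(tr$mu)) {
    transmission_profile(tr$mu)
  } else {
    abort("config: `transmission` needs `mu` or `groups`.")
  }

  fit <- cfg$fitness %||% list()
  check_keys(fit, c("median", "cv", "mode"), "fitness")
  if (is.null(fit$median)) abort("config: `fitness.median` is required.")
  fitness <- fitness_spec(fit$median, cv = fit$cv %||% 0, mode = fit$mode)

  params <- model_params(
    N = pop$N, transmission = transmission, fitness = fitness,
    sh = pop$sh %||% 0
  )

  pr <- cfg$protocol %||% list()
  check_keys(pr, c("p0", "generations", "burn_in", "n_reps", "base_seed"),
             "protocol")
  defaults <- sim_protocol()
  protocol <- sim_protocol(
    p0 = pr$p0 %||% defaults$p0,
    generations = pr$generations %||% defaults$generations,
    burn_in = pr$burn_in %||% defaults$burn_in,
    n_reps = pr$n_reps %||% defaults$n_reps,
    base_seed = pr$base_seed %||% defaults$base_seed
  )

  grid <- NULL
  if (!is.null(cfg$grid)) {
    axes <- fix_n_key(cfg$grid)
    check_keys(axes, c("N", "mu", "fitness", "sh", "cv", "low_transmitters"),
               "grid")
    # mixed int/double YAML sequences parse as lists; flatten each axis
    axes <- lapply(axes, function(v) if (is.list(v)) unlist(v) else v)
    grid <- do.call(param_grid, axes)
  }

  list(params = params, protocol = protocol, grid = grid)
}

#' Write a simulation configuration file
#'
#' Serialises a parameter/protocol pair to YAML such that
#' [read_sim_config()] reproduces the identical objects.
#'
#' @param params A [model_params()].
#' @param protocol A [sim_protocol()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(params, protocol, path) {
  cfg <- list(
    population = list(N = params$N, sh = params$sh),
    transmission = list(
      groups = purrr::pmap(params$transmission$groups,
                           function(fraction, mu) list(fraction = fraction, mu = mu))
    ),
    fitness = list(mode = params$fitness$mode, median = params$fitness$median,
                   cv = params$fitness$cv),
    protocol = list(
      p0 = protocol$p0, generations = protocol$generations,
      burn_in = protocol$burn_in, n_reps = protocol$n_reps,
      base_seed = protocol$base_seed
    )
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

format_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_csv_with_header <- function(df, path, meta) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(sprintf("# %s: %s", key, meta[[key]]), con)
  }
  out <- df
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], format_num)
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

params_meta <- function(params) {
  list(
    package = paste0("symdrift ", as.character(packageVersion("symdrift"))),
    N = params$N,
    sh = format_num(params$sh),
    transmission_groups = paste(
      sprintf("%s:%s", format_num(params$transmission$groups$fraction),
              format_num(params$transmission$groups$mu)),
      collapse = ";"
    ),
    fitness = sprintf("%s median=%s cv=%s", params$fitness$mode,
                      format_num(params$fitness$median),
                      format_num(params$fitness$cv))
  )
}

#' Write a trajectory to CSV
#'
#' Deterministic column order (`generation, p, I, f_t`), floating-point
#' values at 17 significant digits (so doubles round-trip exactly), and
#' `#`-prefixed metadata header lines carrying full parameter and seed
#' provenance.
#'
#' @param traj A [simulate_trajectory()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  params <- attr(traj, "params")
  meta <- c(
    params_meta(params),
    list(
      seed = attr(traj, "seed"),
      absorbed_at = ifelse(is.na(attr(traj, "absorbed_at")), "NA",
                           attr(traj, "absorbed_at"))
    )
  )
  out <- as_tibble(traj)[, c("generation", "p", "I", "f_t")]
  out$seed <- attr(traj, "seed")
  write_csv_with_header(out, path, meta)
}

#' Write replicate or grid summaries to CSV
#'
#' @param records A tibble of summary rows ([tidy()] of a replicate set, or
#'   a [run_grid()] result); an empty tibble yields a header-only file.
#' @param path Output path.
#' @param meta Optional named list of extra `#` header fields.
#' @return `path`, invisibly.
#' @export
write_summary <- function(records, path, meta = list()) {
  meta <- c(
    list(package = paste0("symdrift ",
                          as.character(packageVersion("symdrift")))),
    meta
  )
  records <- dplyr::select(as_tibble(records),
                           -dplyr::any_of("replicates"))
  write_csv_with_header(records, path, meta)
}

#' Read back a CSV written by this package
#'
#' @param path File written by [write_trajectory()] or [write_summary()].
#' @return A tibble; the `#` metadata header is attached as attribute
#'   `meta` (named character vector).
#' @export
read_sim_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- NULL
  if (length(meta_lines)) {
    kv <- sub("^# ", "", meta_lines)
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*: ?", "", kv)
    meta <- setNames(vals, keys)
  }
  df <- as_tibble(utils::read.csv(path, comment.char = "#"))
  attr(df, "meta") <- meta
  df
}

#' Build a run manifest
#'
#' A manifest records everything needed to reproduce a replicate set
#' bit-exactly: package version, the fully resolved parameter set and
#' protocol, the base seed and every derived per-replicate seed, a
#' timestamp, and the output file inventory.
#'
#' @param params A [model_params()].
#' @param protocol A [sim_protocol()].
#' @param outputs Character vector of output paths produced by the run.
#' @return A list of class `symdrift_manifest`.
#' @seealso [write_manifest()], [replay_manifest()]
#' @export
run_manifest <- function(params, protocol, outputs = character()) {
  structure(
    list(
      package = "symdrift",
      version = as.character(packageVersion("symdrift")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      population = list(N = params$N, sh = params$sh),
      transmission = list(
        fraction = params$transmission$groups$fraction,
        mu = params$transmission$groups$mu
      ),
      fitness = list(mode = params$fitness$mode,
                     median = params$fitness$median, cv = params$fitness$cv),
      protocol = unclass(protocol),
      replicate_seeds = derive_seeds(protocol$base_seed, protocol$n_reps),
      outputs = outputs
    ),
    class = "symdrift_manifest"
  )
}

#' @rdname run_manifest
#' @param manifest A `symdrift_manifest`.
#' @param path JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "symdrift_manifest")
}

#' Replay a manifest
#'
#' Rebuilds the parameter objects recorded in a manifest and reruns the
#' replicate set; with an unchanged package version the result is
#' bit-identical to the original run.
#'
#' @param manifest A `symdrift_manifest` (possibly read back from JSON).
#' @return A `symdrift_replicates` object.
#' @export
replay_manifest <- function(manifest) {
  params <- model_params(
    N = manifest$population$N,
    transmission = transmission_profile(
      mu = manifest$transmission$mu,
      fraction = manifest$transmission$fraction
    ),
    fitness = fitness_spec(manifest$fitness$median, manifest$fitness$cv,
                           manifest$fitness$mode),
    sh = manifest$population$sh
  )
  protocol <- do.call(sim_protocol, manifest$protocol[
    c("p0", "generations", "burn_in", "n_reps", "base_seed")
  ])
  run_replicates(params, protocol)
}
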