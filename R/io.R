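#' Write per-generation statistics as TSV
#'
#' Tab-separated, '.' decimal, UTF-8; doubles are written with `%.17g` so the
#' file round-trips bit-exactly through [read_stats()]. One row per recorded
#' generation (generation 0 included), header row first.
#'
#' @param stats the `stats` data.frame of a run.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats <- function(stats, path) {
  write_tsv_precise(stats, path)
  invisible(path)
}

#' Read statistics written by [write_stats()]
#'
#' @param path input path.
#' @return A `data.frame`.
#' @export
read_stats <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  for (j in seq_along(df))  # all-NA numeric columns parse as logical
    if (is.logical(df[[j]]) && all(is.na(df[[j]]))) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Write a run manifest
#'
#' JSON sidecar recording the resolved configuration, seed, package version,
#' wall-clock bounds and output paths. Re-running with the recorded
#' configuration and seed reproduces the outputs bit-identically (wall-time
#' fields aside).
#'
#' @param config the resolved [sim_config()].
#' @param outputs named list/vector of output file paths.
#' @param path manifest path.
#' @param started,finished POSIXct timestamps.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, outputs, path,
                           started = Sys.time(), finished = Sys.time()) {
  cfg <- unclass(config)
  cfg$optimum <- cfg$optimum$target  # sigma2 already a top-level field
  manifest <- list(
    config = cfg,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("grnevolve")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# flag -> sim_config argument translation table
cli_flag_map <- c(
  "--pop-size" = "N", "--genes" = "n", "--region-length" = "L",
  "--mu" = "mu", "--sigma2" = "sigma2", "--generations" = "generations",
  "--step-cap" = "step_cap", "--optimum" = "optimum",
  "--neutral-mask" = "neutral_mask", "--recombination" = "recombination_model",
  "--recomb-prob" = "recombination_prob", "--seed" = "seed",
  "--init-strength-bits" = "init_strength_bits",
  "--type-bit-prob" = "type_bit_prob",
  "--initial-expression" = "initial_expression",
  "--genotype-identity" = "genotype_identity",
  "--on-zero-fitness" = "on_zero_fitness")

#' Resolve a simulation configuration from CLI flags and a config file
#'
#' Flags use `--flag value` pairs (see the translation table in the source;
#' e.g. `--pop-size`, `--genes`, `--mu`, `--optimum 1111111111`,
#' `--neutral-mask 0000011111` with 1 marking neutral genes). `file` may be a
#' YAML or JSON file whose keys are [sim_config()] argument names (plus
#' `neutral_mask`, and the aliases `pop_size`/`genes`/`region_length` for
#' `N`/`n`/`L`, which YAML 1.1 would otherwise parse as booleans); CLI flags
#' override file values. Unknown flags or keys and out-of-range values raise
#' an error naming the offending key.
#'
#' @param args character vector of CLI tokens (flag/value pairs).
#' @param file optional YAML/JSON configuration file.
#' @return A [sim_config()].
#' @export
parse_config <- function(args = character(), file = NULL) {
  vals <- list()
  if (!is.null(file)) {
    vals <- if (grepl("\\.json$", file, ignore.case = TRUE))
      jsonlite::read_json(file, simplifyVector = TRUE)
    else yaml::read_yaml(file)
    # YAML 1.1 resolves bare N/n/y/Y keys to booleans; insist on the aliases
    if (any(names(vals) %in% c("TRUE", "FALSE")))
      stop("configuration key parsed as a boolean (YAML treats bare N/n as ",
           "logical); use 'pop_size'/'genes' or quote the key", call. = FALSE)
    aliases <- c(pop_size = "N", genes = "n", region_length = "L")
    hit <- names(vals) %in% names(aliases)
    names(vals)[hit] <- aliases[names(vals)[hit]]
    bad <- setdiff(names(vals), c(unname(cli_flag_map), "optimum"))
    if (length(bad) > 0L)
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  i <- 1L
  while (i <= length(args)) {
    flag <- args[i]
    if (!flag %in% names(cli_flag_map))
      stop("unknown flag: ", flag, call. = FALSE)
    if (i + 1L > length(args))
      stop("flag ", flag, " is missing its value", call. = FALSE)
    vals[[cli_flag_map[[flag]]]] <- args[i + 1L]
    i <- i + 2L
  }

  num_keys <- c("mu", "sigma2", "recombination_prob", "type_bit_prob")
  int_keys <- c("N", "n", "L", "generations", "step_cap", "seed")
  if (is.character(vals$type_bit_prob))  # flag form: "cis,trans" or one value
    vals$type_bit_prob <- strsplit(vals$type_bit_prob, ",", fixed = TRUE)[[1L]]
  for (k in intersect(names(vals), num_keys)) vals[[k]] <- as.numeric(vals[[k]])
  for (k in intersect(names(vals), int_keys)) vals[[k]] <- as.integer(vals[[k]])
  for (k in intersect(names(vals), c("optimum", "initial_expression",
                                     "neutral_mask"))) {
    v <- vals[[k]]
    if (is.character(v) && length(v) == 1L)
      vals[[k]] <- as.integer(strsplit(v, "", fixed = TRUE)[[1L]])
  }
  mask <- vals$neutral_mask
  vals$neutral_mask <- NULL
  if (!is.null(mask)) {
    if (is.null(vals$optimum)) {
      n <- if (!is.null(vals$n)) vals$n else length(mask)
      vals$optimum <- rep(1L, n)
    }
    if (length(mask) != length(vals$optimum))
      stop("neutral_mask length must match the optimum length", call. = FALSE)
    vals$optimum[mask == 1L] <- NA_integer_
  }
  do.call(sim_config, vals)
}

#' Command-line entry point
#'
#' Subcommands: `run` (forward simulation; writes a stats TSV, a JSON
#' manifest, and optionally periodic genome snapshots), `robustness` (run with
#' branch probes; additionally writes a probe TSV) and `buffering` (the
#' regulatory-vs-baseline time-to-optimum scan). Invoked by the
#' `exec/grnevolve` script as `grnevolve <subcommand> [flags]`.
#'
#' @param args character vector of CLI tokens (without the program name).
#' @return Invisibly, the main result object.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: grnevolve <run|robustness|buffering> [--flag value ...]",
         call. = FALSE)
  cmd <- args[1L]
  args <- args[-1L]

  take <- function(args, flag, default = NULL) {
    i <- match(flag, args)
    if (is.na(i)) return(list(value = default, args = args))
    if (i + 1L > length(args))
      stop("flag ", flag, " is missing its value", call. = FALSE)
    list(value = args[i + 1L], args = args[-c(i, i + 1L)])
  }
  t_out <- take(args, "--out", "stats.tsv"); args <- t_out$args
  t_cfgf <- take(args, "--config"); args <- t_cfgf$args
  t_snap <- take(args, "--snapshot-every"); args <- t_snap$args
  t_int <- take(args, "--interval", "500"); args <- t_int$args
  t_bm <- take(args, "--branch-mutations", "15"); args <- t_bm$args
  t_grid <- take(args, "--mu-grid"); args <- t_grid$args
  t_rep <- take(args, "--replicates", "20"); args <- t_rep$args

  started <- Sys.time()
  out_path <- t_out$value

  if (cmd == "buffering") {
    config <- parse_config(args, t_cfgf$value)
    grid <- as.numeric(strsplit(t_grid$value %||% "0.01,0.1,1", ",")[[1L]])
    res <- run_buffering(grid, as.integer(t_rep$value), config,
                         seed = config$seed %||% 1L)
    write_tsv_precise(res, out_path)
    write_manifest(config, c(table = out_path),
                   paste0(out_path, ".manifest.json"), started, Sys.time())
    message("wrote ", out_path)
    return(invisible(res))
  }

  config <- parse_config(args, t_cfgf$value)
  snap_dir <- if (!is.null(t_snap$value))
    paste0(sub("\\.tsv$", "", out_path), ".snapshots")
  sim <- if (cmd == "robustness") {
    run_simulation(config, robustness_interval = as.integer(t_int$value),
                   branch_mutations = as.integer(t_bm$value),
                   snapshot_every = if (!is.null(t_snap$value))
                     as.integer(t_snap$value),
                   snapshot_dir = snap_dir)
  } else if (cmd == "run") {
    run_simulation(config,
                   snapshot_every = if (!is.null(t_snap$value))
                     as.integer(t_snap$value),
                   snapshot_dir = snap_dir)
  } else {
    stop("unknown subcommand: ", cmd, call. = FALSE)
  }
  write_stats(sim$stats, out_path)
  outputs <- c(stats = out_path)
  if (cmd == "robustness") {
    rob_path <- paste0(sub("\\.tsv$", "", out_path), ".robustness.tsv")
    write_tsv_precise(sim$robustness, rob_path)
    outputs <- c(outputs, robustness = rob_path)
  }
  if (!is.null(t_snap$value)) outputs <- c(outputs, snapshots = snap_dir)
  write_manifest(config, outputs, paste0(out_path, ".manifest.json"),
                 started, Sys.time())
  message("wrote ", paste(outputs, collapse = ", "))
  invisible(sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
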