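# keys accepted in plain-text configs; everything else is rejected
.config_keys <- c("preset", "model", "N", "snapshots", "rtol", "atol",
                  "dn", "dm", "du", "gamma", "eta", "alpha", "beta",
                  "mu1", "mu2", "theta", "xi", "rho", "epsilon")

.param_names <- c("dn", "dm", "du", "gamma", "eta", "alpha", "beta",
                  "mu1", "mu2", "theta", "xi", "rho", "epsilon")

#' Load a plain-text run configuration
#'
#' Parses `key = value` lines (`#` comments and blank lines ignored) into
#' a fully validated run specification. A `preset` key seeds the variant,
#' parameters and grid order from [invasion_presets()]; any explicit key
#' overrides the preset value. Recognised keys: `preset`, `model`
#' (variant name), `N`, `snapshots` (comma-separated times), `rtol`,
#' `atol`, and every model parameter (`dn`, `dm`, `du`, `gamma`, `eta`,
#' `alpha`, `beta`, `mu1`, `mu2`, `theta`, `xi`, `rho`, `epsilon`).
#'
#' @param path Path to a config file, or the config text itself (any
#'   string containing a newline or `=` is treated as inline text).
#' @return A list of class `invasion_config`: `variant`, `params`, `N`,
#'   `snapshot_times`, `settings`.
#' @examples
#' load_config("preset = fig1")
#' load_config("preset = fig1\ngamma = 0.02")
#' @export
load_config <- function(path) {
  txt <- if (length(path) == 1L && !grepl("[=\n]", path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(paste(path, collapse = "\n"), "\n", fixed = TRUE))
  }
  txt <- trimws(sub("#.*$", "", txt))
  txt <- txt[nzchar(txt)]
  kv <- list()
  for (line in txt) {
    if (!grepl("=", line, fixed = TRUE)) {
      stop("malformed config line (expected key = value): `", line, "`",
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    if (!key %in% .config_keys) {
      stop("unknown configuration key: `", key, "`", call. = FALSE)
    }
    if (key %in% names(kv)) stop("duplicate configuration key: `", key,
                                 "`", call. = FALSE)
    kv[[key]] <- val
  }

  num <- function(key, value) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) stop("non-numeric value for key `", key, "`: ", value,
                       call. = FALSE)
    v
  }

  variant <- "basic"
  pargs <- list()
  N <- 30L
  snaps <- c(0, 1, 2, 10, 20)
  rtol <- 1e-8
  atol <- 1e-10
  if (!is.null(kv$preset)) {
    pre <- preset(kv$preset)
    variant <- pre$variant
    pargs <- unclass(pre$params)
    N <- pre$N
  }
  if (!is.null(kv$model)) variant <- invasion_variant(kv$model)
  for (key in intersect(names(kv), .param_names)) {
    pargs[[key]] <- num(key, kv[[key]])
  }
  if (!is.null(kv$N)) {
    N <- num("N", kv$N)
    if (N < 1 || N != round(N)) stop("`N` must be a positive integer",
                                     call. = FALSE)
    N <- as.integer(N)
  }
  if (!is.null(kv$snapshots)) {
    snaps <- unname(vapply(trimws(strsplit(kv$snapshots, ",")[[1L]]),
                           function(s) num("snapshots", s), numeric(1)))
  }
  if (!is.null(kv$rtol)) rtol <- num("rtol", kv$rtol)
  if (!is.null(kv$atol)) atol <- num("atol", kv$atol)

  params <- tryCatch(do.call(invasion_params, pargs), error = function(e) {
    stop("invalid parameter configuration: ", conditionMessage(e),
         call. = FALSE)
  })
  .check_params_variant(params, variant)
  structure(
    list(variant = variant, params = params, N = N,
         snapshot_times = snaps,
         settings = integrator_settings(rel_tol = rtol, abs_tol = atol)),
    class = "invasion_config"
  )
}

#' Serialise a run configuration to config text
#'
#' Inverse of [load_config()]: the returned text reloads to an identical
#' run specification.
#'
#' @param config An `invasion_config`.
#' @return A single string of `key = value` lines.
#' @export
serialize_config <- function(config) {
  stopifnot(inherits(config, "invasion_config"))
  p <- unclass(config$params)
  lines <- c(
    paste("model =", config$variant),
    paste("N =", config$N),
    paste("snapshots =", paste(format(config$snapshot_times, digits = 17),
                               collapse = ",")),
    paste("rtol =", format(config$settings$rel_tol, digits = 17)),
    paste("atol =", format(config$settings$abs_tol, digits = 17)),
    vapply(names(p), function(k) {
      paste(k, "=", format(p[[k]], digits = 17))
    }, character(1))
  )
  paste(lines, collapse = "\n")
}

.fmt <- function(x) sprintf("%.17g", x)   # repr-round-trip doubles

#' Write simulation snapshots to CSV
#'
#' Long format, header `time,x,n,f,m,u`, one row per (snapshot time,
#' node), sorted by time then position; the `u` column is written as 0
#' for three-field variants. Numbers are formatted with 17 significant
#' digits so re-importing reproduces the in-memory values bit-exactly.
#'
#' @param result An `invasion_result`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_csv <- function(result, path) {
  stopifnot(inherits(result, "invasion_result"))
  nt <- length(result$times)
  P <- length(result$x)
  u <- if ("u" %in% names(result$fields)) result$fields$u
       else matrix(0, nt, P)
  rows <- c("time,x,n,f,m,u")
  for (i in seq_len(nt)) {
    rows <- c(rows, paste(
      .fmt(result$times[i]), .fmt(result$x),
      .fmt(result$fields$n[i, ]), .fmt(result$fields$f[i, ]),
      .fmt(result$fields$m[i, ]), .fmt(u[i, ]), sep = ","))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Re-import a snapshot CSV
#'
#' @param path A file written by [export_csv()].
#' @return A data frame with columns `time, x, n, f, m, u`.
#' @export
import_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Per-snapshot diagnostics
#'
#' For each snapshot: Clenshaw-Curtis total tumour mass, field minima,
#' and the tumour cluster count on a 1001-point uniform evaluation grid.
#'
#' @param result An `invasion_result`.
#' @return Data frame with columns
#'   `time, total_mass_n, min_n, min_f, min_m, clusters_n`.
#' @export
diagnostics_report <- function(result) {
  stopifnot(inherits(result, "invasion_result"))
  grid <- cgl_grid(result$metadata$N)
  do.call(rbind, lapply(seq_along(result$times), function(i) {
    n <- result$fields$n[i, ]
    data.frame(
      time = result$times[i],
      total_mass_n = total_mass(grid, n),
      min_n = min(n),
      min_f = min(result$fields$f[i, ]),
      min_m = min(result$fields$m[i, ]),
      clusters_n = count_clusters(
        profile_on_uniform_grid(result, "n", result$times[i]))
    )
  }))
}

#' Run a configured simulation and write its outputs
#'
#' Executes the spectral solver for a run specification, writes
#' `snapshots.csv` and `diagnostics.csv` into `out_dir`, optionally runs
#' the finite-difference reference solver and writes a per-field
#' max-abs discrepancy table `discrepancy.csv`, and appends one
#' structured log line to `run.log`.
#'
#' @param config An `invasion_config` (from [load_config()]) or a preset
#'   name.
#' @param out_dir Output directory (created if missing).
#' @param oracle_M Optional integer: if given, also run
#'   [fd_reference_solve()] with this many uniform points and write the
#'   discrepancy report.
#' @return Invisibly, a list with the `invasion_result` and the paths of
#'   the files written.
#' @export
run_simulation <- function(config, out_dir, oracle_M = NULL) {
  if (is.character(config)) config <- load_config(paste0("preset = ",
                                                         config))
  stopifnot(inherits(config, "invasion_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- cgl_grid(config$N)
  result <- solve_invasion(config$variant, config$params, grid,
                           snapshot_times = config$snapshot_times,
                           settings = config$settings)
  paths <- c(snapshots = file.path(out_dir, "snapshots.csv"),
             diagnostics = file.path(out_dir, "diagnostics.csv"))
  export_csv(result, paths[["snapshots"]])
  diag <- diagnostics_report(result)
  utils::write.csv(diag, paths[["diagnostics"]], row.names = FALSE)

  if (!is.null(oracle_M)) {
    ref <- fd_reference_solve(config$variant, config$params, oracle_M,
                              config$snapshot_times, config$settings)
    fields <- names(result$fields)
    disc <- do.call(rbind, lapply(result$times, function(tt) {
      row <- data.frame(time = tt)
      for (fl in fields) {
        row[[paste0("max_abs_", fl)]] <- compare_solutions(result, ref,
                                                           fl, tt)
      }
      row
    }))
    paths[["discrepancy"]] <- file.path(out_dir, "discrepancy.csv")
    utils::write.csv(disc, paths[["discrepancy"]], row.names = FALSE)
  }

  logline <- sprintf(
    "variant=%s N=%d rtol=%g atol=%g steps=%s params[%s] snapshots=%s",
    config$variant, config$N, config$settings$rel_tol,
    config$settings$abs_tol, result$metadata$n_steps,
    paste(sprintf("%s=%g", names(unclass(config$params)),
                  unlist(unclass(config$params))), collapse = " "),
    paste(config$snapshot_times, collapse = ","))
  paths[["log"]] <- file.path(out_dir, "run.log")
  cat(logline, "\n", file = paths[["log"]], append = TRUE, sep = "")

  invisible(list(result = result, files = paths))
}
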