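## Serialization, fixtures, run manifests and config loading.
## Environments round-trip through a small JSON schema; front curves and
## indent series use CSV with units embedded in the column names; all
## floating output is written with 9 significant digits.

FO_SCHEMA_VERSION <- 1L

#' Serialize an environment to JSON
#'
#' Schema: `schema_version`, `domain_mm`, `obstacles` (list of `kind`,
#' `vertices_mm`, scalar fields), `metadata` (including any generator seed).
#'
#' @param env an `fo_env`
#' @param path output file; when `NULL` the JSON string is returned
#' @export
env_to_json <- function(env, path = NULL) {
  obs <- lapply(env$obstacles, function(ob) {
    list(kind = ob$kind,
         vertices_mm = unname(apply(ob$vertices, 1, function(r) signif(r, 9),
                                    simplify = FALSE)),
         w_half_mm = ob$w_half, h_half_mm = ob$h_half,
         y_maxwidth_mm = ob$y_maxwidth, r_mm = ob$r,
         L_proj_half_mm = ob$L_proj_half, tilt_deg = ob$tilt)
  })
  x <- list(schema_version = FO_SCHEMA_VERSION,
            domain_mm = env$domain, obstacles = obs,
            rho = env$rho, metadata = env$metadata)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Load an environment from JSON
#' @param path file written by [env_to_json()]
#' @return an `fo_env`
#' @export
env_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(x$schema_version) || x$schema_version > FO_SCHEMA_VERSION)
    fo_stop("config_error", "unsupported environment schema version")
  obstacles <- lapply(x$obstacles, function(ob) {
    v <- do.call(rbind, lapply(ob$vertices_mm, unlist))
    new_obstacle(v, ob$kind,
                 w_half = ob$w_half_mm %||% NA_real_,
                 h_half = ob$h_half_mm %||% NA_real_,
                 y_maxwidth = ob$y_maxwidth_mm %||% NA_real_,
                 r = ob$r_mm %||% NA_real_,
                 L_proj_half = ob$L_proj_half_mm %||% NA_real_,
                 tilt = ob$tilt_deg %||% NA_real_)
  })
  environment_make(unlist(x$domain_mm), obstacles,
                   metadata = x$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a front curve to CSV (columns x_mm, y_mm, d_mm)
#' @param front an `fo_front`
#' @param path output file
#' @export
write_front_csv <- function(front, path) {
  df <- data.frame(x_mm = signif(front$x, 9), y_mm = signif(front$y, 9),
                   d_mm = signif(attr(front, "d"), 9))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an indent series to CSV (columns d_mm, delta_mm, w_half_mm)
#' @param series an `fo_indent_series`
#' @param path output file
#' @export
write_indent_csv <- function(series, path) {
  df <- data.frame(d_mm = signif(series$d, 9), delta_mm = signif(series$delta, 9),
                   w_half_mm = signif(attr(series, "w_half"), 9))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an indent series written by [write_indent_csv()]
#' @param path CSV file
#' @export
read_indent_csv <- function(path) {
  df <- read.csv(path)
  indent_series(df$d_mm, df$delta_mm, df$w_half_mm[1])
}

#' Standard fixture set
#'
#' Builds the printed study configurations — the four rhombi with
#' `(w, h)` in `{0.9, 1.2}^2` mm, the PDE and Eden two-obstacle pairs, and
#' the default single-obstacle Eden geometry — plus miniature variants (all
#' dimensions divided by 4) for fast checks.  With `dir` given, each
#' environment is also written as JSON.
#'
#' @param dir optional output directory for JSON files
#' @return named list of `fo_env` objects / eden configs
#' @export
make_fixtures <- function(dir = NULL) {
  rhombus_env <- function(w, h, shrink = 1) {
    dom <- c(2 * (w + 5 * w) / shrink, 16 / shrink)
    environment_make(dom, list(make_rhombus(w / shrink, h / shrink,
                                            c(dom[1] / 2, 4 / shrink))))
  }
  combos <- list(c(0.9, 0.9), c(0.9, 1.2), c(1.2, 0.9), c(1.2, 1.2))
  fx <- list()
  for (wh in combos) {
    fx[[sprintf("rhombus_w%.1f_h%.1f", wh[1], wh[2])]] <-
      rhombus_env(wh[1], wh[2])
    fx[[sprintf("mini_rhombus_w%.1f_h%.1f", wh[1], wh[2])]] <-
      rhombus_env(wh[1], wh[2], shrink = 4)
  }
  fx[["two_obstacle_pde"]] <- make_two_obstacle_config("pde")
  fx[["two_obstacle_eden"]] <- make_two_obstacle_config("eden", R = 80)
  fx[["mini_two_obstacle_eden"]] <- make_two_obstacle_config("eden", R = 20)
  fx[["eden_single"]] <- eden_config(W = 600L, R = 80L, config = "single")
  fx[["mini_eden_single"]] <- eden_config(W = 150L, R = 20L, config = "single")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(fx)) {
      if (inherits(fx[[nm]], "fo_env"))
        env_to_json(fx[[nm]], file.path(dir, paste0(nm, ".json")))
    }
  }
  fx
}

#' Load and validate a run configuration
#'
#' JSON config with engine-specific defaults filled in; unknown keys are
#' rejected.  Recognized keys: `engine` (`eikonal`/`fkpp`/`eden`), `env`
#' (path to an environment JSON), `D_eff`, `k_hat`, `u_thresh`, `a_grid`,
#' `v`, `a_eik`, `y0_front`, `t_end`, `W`, `R`, `config`, `seed`, `out`.
#'
#' @param path JSON file
#' @return validated config list with defaults applied
#' @export
load_config <- function(path) {
  if (!file.exists(path)) fo_stop("config_error", "config file does not exist")
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("engine", "env", "D_eff", "k_hat", "u_thresh", "a_grid", "v",
             "a_eik", "y0_front", "t_end", "W", "R", "config", "seed", "out",
             "schema_version")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    fo_stop("config_error", paste("unknown config keys:", paste(bad, collapse = ", ")))
  if (is.null(cfg$engine) || !cfg$engine %in% c("eikonal", "fkpp", "eden"))
    fo_stop("config_error", "engine must be one of eikonal, fkpp, eden")
  if (cfg$engine == "fkpp") {
    cfg$u_thresh <- cfg$u_thresh %||% 0.05
    if (!is.null(cfg$D_eff) && !is.null(cfg$k_hat))
      cfg$a_grid <- cfg$a_grid %||% (0.15 * sqrt(cfg$D_eff / cfg$k_hat))
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

#' Save a config (round-trips through [load_config()])
#' @param cfg config list
#' @param path output file
#' @export
save_config <- function(cfg, path) {
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}

#' Run manifest with output checksums
#'
#' Records engine, parameters, seed(s), package version, timestamps and an
#' inventory of output files with md5 checksums, so that a stochastic run can
#' be re-executed and verified bit for bit.
#'
#' @param engine engine id
#' @param params named list of parameters (seeds included)
#' @param files character vector of output files
#' @param path optional JSON output path
#' @export
run_manifest <- function(engine, params, files = character(0), path = NULL) {
  inv <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  m <- list(engine = engine, params = params,
            package_version = as.character(utils::packageVersion("frontobstacles")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            outputs = inv)
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
    return(invisible(m))
  }
  m
}
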