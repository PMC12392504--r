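#' Load a run configuration
#'
#' Reads a YAML configuration with sections \code{model}, \code{pattern},
#' \code{ensemble} and \code{inference}.  Absent model keys fall back to the
#' default parameter set; unknown keys in any section are rejected so typos
#' never pass silently.  Model keys use the conventional parameter names
#' (\code{gamma}, \code{lambda}, \code{kappa}, \code{R0}, \code{eta},
#' \code{M}, \code{alpha}, \code{mu_beta}, \code{sigma_beta}, \code{sigma},
#' \code{s0}, \code{tau_f} [s], \code{tau_chi} [s], \code{tau_s} [min],
#' \code{tau} [min], \code{ell}); numerics keys (\code{dx}, \code{dt},
#' \code{pad}, \code{record_every}) live in the model section too.
#'
#' @param path path to a YAML file.
#' @return a \code{pf_config}: list with \code{params} (\code{pf_params}),
#'   \code{pattern} (\code{pf_pattern}), \code{ensemble}, \code{inference}
#'   and provenance (file md5 hash).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known_sections <- c("model", "pattern", "ensemble", "inference")
  unknown <- setdiff(names(cfg), known_sections)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))

  model <- cfg$model %||% list()
  model_map <- c(gamma = "gamma", lambda = "lambda", kappa = "kappa", R0 = "R0",
                 eta = "eta", M = "M", alpha = "alpha", mu_beta = "mu_beta",
                 sigma_beta = "sigma_beta", sigma = "sigma_patch", s0 = "s0",
                 tau_f = "tau_f", tau_chi = "tau_chi", tau_s = "tau_s",
                 tau = "tau", ell = "ell", no_filopodia = "no_filopodia",
                 c0 = "c0", dx = "dx", dt = "dt", pad = "pad",
                 record_every = "record_every")
  unknown <- setdiff(names(model), names(model_map))
  if (length(unknown))
    stop("unknown model key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(model, model_map[names(model)])
  params <- do.call(model_params, args)

  pat <- cfg$pattern %||% list(kind = "two_state")
  pat_known <- c("kind", "basin", "bridge", "rect", "polygons", "w_chi")
  unknown <- setdiff(names(pat), pat_known)
  if (length(unknown))
    stop("unknown pattern key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(pat$polygons))
    pat$polygons <- lapply(pat$polygons, function(p) matrix(unlist(p), ncol = 2, byrow = TRUE))
  pattern <- do.call(pattern_spec, pat)

  ens <- cfg$ensemble %||% list()
  ens_known <- c("n_runs", "hours", "seed")
  unknown <- setdiff(names(ens), ens_known)
  if (length(unknown))
    stop("unknown ensemble key(s): ", paste(unknown, collapse = ", "))
  inf <- cfg$inference %||% list()
  inf_known <- c("dt_sample", "n_x", "n_v", "min_count", "bootstrap")
  unknown <- setdiff(names(inf), inf_known)
  if (length(unknown))
    stop("unknown inference key(s): ", paste(unknown, collapse = ", "))

  structure(list(params = params, pattern = pattern,
                 ensemble = utils::modifyList(list(n_runs = 20, hours = 12, seed = 1), ens),
                 inference = utils::modifyList(
                   list(dt_sample = 10, n_x = 36, n_v = 30, min_count = 20,
                        bootstrap = 0), inf),
                 config_hash = unname(tools::md5sum(path)), path = path),
            class = "pf_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes a YAML file that \code{\link{load_config}} round-trips
#' losslessly.
#'
#' @param config a \code{pf_config} (or list with the same fields).
#' @param path output path.
#' @return the path, invisibly.
#' @export
save_config <- function(config, path) {
  p <- config$params
  model <- list(gamma = p$gamma, lambda = p$lambda, kappa = p$kappa, R0 = p$R0,
                eta = p$eta, M = p$M, alpha = p$alpha, mu_beta = p$mu_beta,
                sigma_beta = p$sigma_beta, sigma = p$sigma_patch, s0 = p$s0,
                tau_f = p$tau_f, tau_chi = p$tau_chi, tau_s = p$tau_s,
                tau = p$tau, ell = p$ell, c0 = p$c0,
                no_filopodia = p$no_filopodia,
                dx = p$dx, dt = p$dt, pad = p$pad, record_every = p$record_every)
  pat <- config$pattern
  pattern <- list(kind = pat$kind, basin = pat$basin, bridge = pat$bridge,
                  rect = pat$rect, w_chi = pat$w_chi)
  if (!is.null(pat$polygons))
    pattern$polygons <- lapply(pat$polygons, function(m) as.list(as.data.frame(t(m))))
  yaml::write_yaml(list(model = model, pattern = pattern,
                        ensemble = config$ensemble, inference = config$inference),
                   path)
  invisible(path)
}

#' Deterministic hash of a parameter set
#'
#' md5 of the canonical JSON serialisation; used as a provenance guard when
#' merging trajectory sets.
#'
#' @param params a \code{pf_params}.
#' @return hex string.
#' @export
params_hash <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  core <- params[sort(names(params))]
  writeLines(jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a trajectory set to disk
#'
#' Flat CSV (columns run, t_min, x_um, y_um, area_um2, perim_um) plus a
#' JSON sidecar (\code{<path>.meta.json}) carrying per-run seeds and flags,
#' the parameter hash and the package version — enough to regenerate the
#' set bit-identically.
#'
#' @param set a \code{pf_trajectory_set}.
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
write_trajectories <- function(set, path) {
  fmt <- function(x) ifelse(is.na(x), NA, sprintf("%.17g", x))  # full precision
  df <- do.call(rbind, lapply(seq_along(set$runs), function(i) {
    tr <- set$runs[[i]]
    data.frame(run = i, t_min = fmt(tr$t_min), x_um = fmt(tr$x_um),
               y_um = fmt(tr$y_um), area_um2 = fmt(tr$area_um2),
               perim_um = fmt(tr$perim_um))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    package = "cellhop",
    version = as.character(utils::packageVersion("cellhop")),
    params_hash = set$params_hash,
    seeds = set$seeds,
    ok = set$ok,
    flags = lapply(set$runs, function(tr) {
      fl <- attr(tr, "flags")
      if (is.null(fl)) list(ruptured = FALSE, escaped = FALSE, failed = FALSE) else fl
    }))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".meta.json"))
  invisible(path)
}

#' Read a trajectory set written by \code{\link{write_trajectories}}
#'
#' @param path CSV path.
#' @return a \code{pf_trajectory_set}.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path)
  need <- c("run", "t_min", "x_um")
  if (!all(need %in% names(df)))
    stop("corrupt or foreign trajectory file: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path, simplifyVector = TRUE) else NULL
  for (nm in setdiff(names(df), "run")) df[[nm]] <- as.numeric(df[[nm]])
  runs <- lapply(split(df, df$run), function(d) {
    tr <- data.frame(t_min = d$t_min, x_um = d$x_um,
                     y_um = d$y_um %||% 0,
                     area_um2 = d$area_um2 %||% NA_real_,
                     perim_um = d$perim_um %||% NA_real_)
    class(tr) <- c("pf_trajectory", "data.frame")
    tr
  })
  runs <- runs[order(as.integer(names(runs)))]
  if (!is.null(meta)) {
    for (i in seq_along(runs)) {
      attr(runs[[i]], "seed") <- meta$seeds[i]
      fl <- meta$flags[i, , drop = TRUE]
      attr(runs[[i]], "flags") <- list(ruptured = isTRUE(fl$ruptured),
                                       escaped = isTRUE(fl$escaped),
                                       failed = isTRUE(fl$failed))
    }
  }
  set <- trajectory_set(unname(runs))
  if (!is.null(meta$params_hash)) set$params_hash <- meta$params_hash
  set
}

#' Merge two trajectory sets
#'
#' Refuses to merge sets produced under different parameter hashes.
#'
#' @param a,b \code{pf_trajectory_set}s.
#' @return the combined set.
#' @export
merge_trajectory_sets <- function(a, b) {
  if (!is.na(a$params_hash) && !is.na(b$params_hash) &&
      a$params_hash != b$params_hash)
    stop("refusing to merge trajectory sets with different parameter hashes")
  out <- trajectory_set(c(a$runs, b$runs), params = a$params, pattern = a$pattern)
  out$params_hash <- a$params_hash
  out
}
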