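# Config-driven pipeline: wham -> samples -> density -> capacity, with
# optional map and combination-search stages.

#' Read and validate a pipeline configuration
#'
#' YAML with flat per-module sections. Required keys: `paths` (frame-table
#' CSV), `meta` (metadata CSV), `interfaces` (increasing positions). Optional:
#' `stride`, `cv`/`cvs`, `queries` (list of `{lam_c, lam_r}`), `sg`
#' (settings overrides), `map` (`{lc_min, lc_max, lr_min, lr_max, n}`),
#' `optimize` (`{cvs, n_terms, iterations}`), `seed`, `out_dir`. All
#' referenced files must exist at validation time.
#'
#' @param file path to the YAML config.
#' @return The validated config list (class `ppa_config_file`).
#' @export
read_run_config <- function(file) {
  if (!file.exists(file))
    ppa_error(sprintf("config file '%s' does not exist", file), "ppa_io_error")
  cfg <- yaml::read_yaml(file)
  for (key in c("paths", "meta", "interfaces"))
    if (is.null(cfg[[key]]))
      ppa_error(sprintf("config lacks required key '%s'", key),
                "ppa_value_error")
  base <- dirname(normalizePath(file))
  for (key in c("paths", "meta")) {
    f <- cfg[[key]]
    if (!file.exists(f) && file.exists(file.path(base, f)))
      cfg[[key]] <- file.path(base, f)
    if (!file.exists(cfg[[key]]))
      ppa_error(sprintf("config key '%s' references missing file '%s'",
                        key, f), "ppa_io_error")
  }
  if (any(diff(as.numeric(cfg$interfaces)) <= 0))
    ppa_error("interfaces must be strictly increasing", "ppa_value_error")
  cfg$config_file <- normalizePath(file)
  class(cfg) <- "ppa_config_file"
  cfg
}

#' Run the analysis pipeline from a configuration
#'
#' Reads the path ensemble, validates it, optionally subsamples the MC
#' chain, assigns WHAM weights, assembles flux and rate when a `[0-]`
#' ensemble is present, and computes density estimates and predictive
#' capacities for every configured (query, CV) pair. Stage progress is
#' logged to standard error; results are written under `out_dir`
#' (`results.json` plus one density CSV per query/CV) and returned. Outputs
#' embed the config file's MD5 hash, the seed and the package version; no
#' stage runs before the whole config has validated.
#'
#' @param config a config list from [read_run_config()], or a file path.
#' @param out_dir output directory; defaults to the config's `out_dir`.
#' @return Invisibly, the result bundle (list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  say <- function(...) message(sprintf(...))

  t0 <- Sys.time()
  interfaces <- ppa_interfaces(as.numeric(config$interfaces))
  paths <- read_path_table(config$paths, config$meta)
  say("read %d paths from %s", length(paths), config$paths)
  validate_paths(paths, interfaces)
  if (!is.null(config$stride) && config$stride > 1L) {
    paths <- subsample_chain(paths, config$stride)
    say("subsampled MC chain at stride %d -> %d paths", config$stride,
        length(paths))
  }
  paths <- wham_weights(paths, interfaces)
  say("assigned WHAM weights")

  ens <- vapply(paths, `[[`, "", "ensemble")
  curve <- crossing_curve(paths, seq(interfaces$lam_A, interfaces$lam_B,
                                     length.out = 400L),
                          lam_A = interfaces$lam_A)
  utils::write.csv(as.data.frame(curve),
                   file.path(out_dir, "crossing_curve.csv"), row.names = FALSE)
  rate <- NULL
  if (any(ens == "0-")) {
    flux <- flux_estimate(paths[ens == "0-"], paths[ens == "0+"])
    rate <- rate_estimate(flux, curve)
    say("flux %.6g ns^-1, rate %.6g ns^-1", rate$flux_ns, rate$rate_ns)
  }

  sgs <- do.call(sg_settings, config$sg %||% list())
  cvs <- config$cvs %||% config$cv %||% cv_names_of(paths[[1L]])
  queries <- config$queries %||%
    list(list(lam_c = interfaces$lam_A, lam_r = interfaces$lam_B))
  capacities <- list()
  for (q in queries) {
    query <- ppa_query(q$lam_c, q$lam_r, lam_A = interfaces$lam_A)
    s <- build_sample_set(paths, query, cvs)
    say("query (%.4g, %.4g): %d samples", q$lam_c, q$lam_r, nrow(s))
    for (cv in cvs) {
      d <- estimate_densities(s, sgs, cv = cv)
      utils::write.csv(
        data.frame(cv = d$grid, r = d$r, u = d$u, t = d$t),
        file.path(out_dir, sprintf("density_%s_%g_%g.csv", cv,
                                   q$lam_c, q$lam_r)),
        row.names = FALSE)
      cap <- capacity_from_samples(s, sgs, cv = cv)
      capacities[[length(capacities) + 1L]] <-
        list(cv = cv, lam_c = q$lam_c, lam_r = q$lam_r,
             p_bar = cap$p_bar, overlap = cap$overlap,
             capacity = cap$capacity, n_samples = cap$n_samples)
    }
  }

  map_df <- NULL
  if (!is.null(config$map)) {
    mp <- config$map
    map <- ppa_scan(paths, mp$cv %||% cvs[[1L]],
                    seq(mp$lc_min, mp$lc_max, length.out = mp$n %||% 30L),
                    seq(mp$lr_min, mp$lr_max, length.out = mp$n %||% 30L),
                    sgs, n_min = mp$n_min %||% 200L,
                    lam_A = interfaces$lam_A)
    map_df <- as.data.frame(map)
    utils::write.csv(map_df, file.path(out_dir, "ppa_map.csv"),
                     row.names = FALSE)
    say("scanned %d x %d (lc, lr) grid", length(map$lc), length(map$lr))
  }

  combo <- NULL
  if (!is.null(config$optimize)) {
    op <- config$optimize
    query <- ppa_query(op$lam_c %||% interfaces$lam_A,
                       op$lam_r %||% interfaces$lam_B,
                       lam_A = interfaces$lam_A)
    s <- build_sample_set(paths, query, op$cvs %||% cvs)
    ac <- anneal_combo(s, op$cvs %||% cvs, op$n_terms %||% 2L,
                       anneal_settings(seed = seed,
                                       max_iterations = op$iterations),
                       sgs)
    combo <- list(terms = as.list(ac$combo$terms),
                  normalized_coefficients = as.list(ac$normalized_coefficients),
                  capacity = ac$result$capacity, p_bar = ac$result$p_bar,
                  overlap = ac$result$overlap)
    say("best combination: %s (capacity %.4f)",
        paste(sprintf("%+.3f %s", ac$combo$terms, names(ac$combo$terms)),
              collapse = " "), ac$result$capacity)
  }

  results <- list(
    package = "pathppa",
    version = as.character(utils::packageVersion("pathppa")),
    seed = seed,
    config_hash = if (!is.null(config$config_file))
      unname(tools::md5sum(config$config_file)) else NA_character_,
    interfaces = interfaces$lambdas,
    n_paths = length(paths),
    rate = if (!is.null(rate))
      list(flux_ns = rate$flux_ns,
           total_crossing_prob = rate$total_crossing_prob,
           rate_ns = rate$rate_ns),
    capacities = capacities,
    combo = combo)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("pipeline finished in %.1f s; results in %s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")), out_dir)
  invisible(results)
}
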