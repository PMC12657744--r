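#' Pipeline run configuration
#'
#' @param wave_pairs list of length-2 character vectors naming the
#'   (predictor, outcome) waves to analyze; default: all consecutive pairs
#'   of the panel's waves.
#' @param fit a [fit_config()].
#' @param boot a [bootstrap_config()]; set `n_boot = 0` to skip the
#'   bootstrap stage.
#' @param impute an [impute_config()].
#' @param seed global seed; stage seeds are derived from it and recorded in
#'   the manifest.
#' @param run_bootstrap run [bootstrap_edges()] per wave pair.
#' @param run_casedrop run [casedrop_stability()] per wave pair.
#' @return A list of class `clpn_run_config`.
#' @export
run_config <- function(wave_pairs = NULL, fit = fit_config(),
                       boot = bootstrap_config(), impute = impute_config(),
                       seed = 1L, run_bootstrap = FALSE,
                       run_casedrop = FALSE) {
  structure(list(wave_pairs = wave_pairs, fit = fit, boot = boot,
                 impute = impute, seed = as.integer(seed),
                 run_bootstrap = run_bootstrap,
                 run_casedrop = run_casedrop),
            class = "clpn_run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates descriptives, imputation, per-wave-pair network estimation,
#' centrality, optional bootstrap stages, and cross-network comparison, and
#' writes a report bundle (CSV/JSON plus a manifest with versions, seeds
#' and a config hash) to `out_dir`. Re-running with an identical panel and
#' config reproduces identical numeric outputs.
#'
#' @param panel a [panel_dataset()] (may contain missing values) or a path
#'   to a long-layout CSV readable with `codebook`.
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param codebook needed when `panel` is a file path.
#' @return Invisibly, a list with the fitted `networks`, `centrality`
#'   tables, `comparison`, `descriptives`, optional `bootstraps` and
#'   `casedrop`, and the `manifest`.
#' @export
run_pipeline <- function(panel, config = run_config(), out_dir,
                         codebook = NULL) {
  if (is.character(panel)) {
    if (is.null(codebook)) stop("codebook required when panel is a path")
    panel <- read_panel(panel, "long", codebook)
  }
  pairs <- config$wave_pairs %||%
    lapply(seq_len(length(panel$waves) - 1L),
           function(i) panel$waves[c(i, i + 1L)])
  for (pr in pairs) {
    bad <- setdiff(pr, panel$waves)
    if (length(bad))
      stop("config references missing wave(s): ",
           paste(bad, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message("descriptives: ", length(panel$persons), " persons, ",
          length(panel$waves), " waves")
  desc <- endorsement(panel)
  utils::write.csv(desc, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  completed <- panel
  if (anyNA(panel$responses)) {
    icfg <- config$impute
    icfg$seed <- icfg$seed %||% (config$seed + 101L)
    message("imputing ", sum(is.na(panel$responses)), " missing cells")
    completed <- chained_impute(panel, icfg)
  }
  fit_cfg <- config$fit
  fit_cfg$seed <- fit_cfg$seed %||% (config$seed + 202L)
  nets <- list()
  cents <- list()
  boots <- list()
  drops <- list()
  for (pr in pairs) {
    tag <- paste0(pr[1], "_", pr[2])
    net <- fit_clpn(completed, pr[1], pr[2], fit_cfg)
    message("network ", tag, ": ", count_nonzero(net),
            " cross-lagged edges nonzero")
    nets[[tag]] <- net
    export_network(net, file.path(out_dir, paste0("net_", tag, ".csv")),
                   "edge_list_csv")
    export_network(net, file.path(out_dir, paste0("net_", tag, ".graphml")),
                   "graphml")
    ct <- expected_influence(net)
    cents[[tag]] <- ct
    utils::write.csv(ct, file.path(out_dir,
                                   paste0("centrality_", tag, ".csv")),
                     row.names = FALSE)
    if (config$run_bootstrap && config$boot$n_boot > 0) {
      bcfg <- config$boot
      bcfg$seed <- bcfg$seed %||% (config$seed + 303L)
      boots[[tag]] <- bootstrap_edges(completed, pr[1], pr[2], fit_cfg,
                                      bcfg)
      utils::write.csv(
        cbind(edge = colnames(boots[[tag]]$edge_draws),
              lower = as.vector(boots[[tag]]$ci_lower),
              upper = as.vector(boots[[tag]]$ci_upper)),
        file.path(out_dir, paste0("edge_ci_", tag, ".csv")),
        row.names = FALSE)
    }
    if (config$run_casedrop && config$boot$n_boot > 0) {
      bcfg <- config$boot
      bcfg$seed <- bcfg$seed %||% (config$seed + 404L)
      drops[[tag]] <- casedrop_stability(completed, pr[1], pr[2],
                                         fit_cfg, bcfg)
    }
  }
  comparison <- if (length(nets) >= 2L) compare_networks(nets) else NULL
  if (!is.null(comparison))
    jsonlite::write_json(
      list(nonzero_counts = as.list(comparison$nonzero_counts),
           edge_correlation = comparison$edge_correlation,
           centrality_correlations = comparison$centrality_correlations,
           top_edges = comparison$top_edges),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE,
      digits = NA)
  cfg_json <- jsonlite::serializeJSON(config)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "clpnet",
    package_version = as.character(utils::packageVersion("clpnet")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = unname(tools::md5sum(tmp)),
    wave_pairs = pairs,
    n_persons = length(panel$persons),
    created = "see file mtime")
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(networks = nets, centrality = cents,
                 comparison = comparison, descriptives = desc,
                 bootstraps = boots, casedrop = drops,
                 manifest = manifest, completed_panel = completed))
}
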