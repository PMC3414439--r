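run_config_defaults <- function() {
  list(rank_matrix = NULL, metadata = NULL, gmt = NULL,
       signature_up = NULL, signature_down = NULL,
       alpha_pathway = 0.01, alpha_drug = 0.01,
       n_perm = 10000L,
       thresholds = list(single_pos = 0, single_neg = 0,
                         pair_pos = 0.5, pair_neg = -0.5),
       orientation = "reverse", mode = "both",
       pair_universe = "significant_singles",
       min_overlap = 3L, restrict_ranks = FALSE,
       seed = 1L, out_dir = "comboscreen_out")
}

#' Read and validate a screening run configuration
#'
#' YAML file with the keys of the default configuration (unknown keys are an
#' error, so typos never pass silently); an empty or missing-key file falls
#' back to the defaults. \code{overrides} (e.g. from command-line flags) take
#' precedence over file values.
#'
#' @param path YAML file, or NULL for pure defaults
#' @param overrides named list overriding file values
#' @return validated configuration list of class \code{run_config}
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    if (!is.null(user$thresholds)) {
      bad <- setdiff(names(user$thresholds), names(cfg$thresholds))
      if (length(bad)) stop("unknown threshold key(s): ", paste(bad, collapse = ", "))
      cfg$thresholds[names(user$thresholds)] <- user$thresholds
      user$thresholds <- NULL
    }
    cfg[names(user)] <- user
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  if (cfg$alpha_pathway <= 0 || cfg$alpha_pathway >= 1 ||
      cfg$alpha_drug <= 0 || cfg$alpha_drug >= 1)
    stop("alpha values must lie in (0, 1)")
  if (!(cfg$thresholds$pair_pos > 0 && cfg$thresholds$pair_neg < 0))
    stop("pair thresholds must satisfy pair_pos > 0 > pair_neg")
  if (!cfg$orientation %in% c("reverse", "mimic"))
    stop("orientation must be 'reverse' or 'mimic'")
  if (!cfg$mode %in% c("both", "single", "pair"))
    stop("mode must be 'both', 'single' or 'pair'")
  cfg$n_perm <- as.integer(cfg$n_perm)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full screening pipeline from a configuration
#'
#' Loads the compendium, pathway GMT and signature GRP pair named in the
#' configuration, runs \code{\link{combo_screen}}, writes all output tables
#' to \code{out_dir} and a run log (configuration, seed, package version)
#' alongside them. Identical configurations produce byte-identical outputs.
#'
#' @param config a \code{run_config} from \code{\link{read_run_config}}
#' @return the \code{\link{combo_screen}} result, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  compendium <- stage("load compendium",
                      read_rank_matrix(config$rank_matrix, config$metadata))
  pathways <- stage("load pathways", read_gmt(config$gmt))
  signature <- stage("load signature",
                     read_signature(config$signature_up, config$signature_down))
  screen <- stage("screen", combo_screen(
    compendium, signature, pathways,
    alpha_pathway = config$alpha_pathway, alpha_drug = config$alpha_drug,
    n_perm = config$n_perm, mode = config$mode,
    orientation = config$orientation, pair_universe = config$pair_universe,
    thresholds = config$thresholds,
    min_overlap = config$min_overlap, restrict_ranks = config$restrict_ranks,
    seed = config$seed))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(screen, config$out_dir)
  log_lines <- c(
    paste0("comboscreen ", as.character(utils::packageVersion("comboscreen"))),
    paste0("seed: ", config$seed),
    paste0("config: ", yaml::as.yaml(unclass(config))))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  message(paste(log_lines[1:2], collapse = " | "))
  invisible(screen)
}
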