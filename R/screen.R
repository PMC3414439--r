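#' Screen a compendium for single-drug and drug-pair candidates
#'
#' Runs the four-step screening procedure end to end:
#' \enumerate{
#'   \item select disease-relevant pathways by hypergeometric
#'     over-representation of the signature (raw \code{p < alpha_pathway});
#'   \item compute the KS connectivity score of the (pathway-restricted,
#'     oriented) signature against every profile, normalised per pathway;
#'   \item score single molecules and molecule pairs — a pair's profiles
#'     pooled as one set — by the set-level KS statistic over each pathway's
#'     ES-ranked profile list, with subset-permutation p-values;
#'   \item rank candidates by the number of significant pathways whose score
#'     exceeds the positive threshold (0 for singles, +0.5 for pairs).
#' }
#'
#' With \code{orientation = "reverse"} (the default) the signature's up and
#' down lists are swapped before scoring, so molecules that oppose the
#' disease expression state surface at positive scores.
#'
#' @param compendium a \code{\link{rank_compendium}}
#' @param signature an \code{\link{expr_signature}} of the disease state
#' @param pathways named list of pathway member vectors
#' @param alpha_pathway pathway-selection threshold (default 0.01)
#' @param alpha_drug drug-set significance threshold (default 0.01)
#' @param n_perm permutations per null (default 10000)
#' @param mode \code{"both"}, \code{"single"} or \code{"pair"}
#' @param orientation \code{"reverse"} (default) or \code{"mimic"}
#' @param pair_universe \code{"significant_singles"} (default: only pair up
#'   molecules significant in at least one selected pathway) or \code{"all"}
#' @param pair_filter optional molecule subset both pair members must belong
#'   to (e.g. approved drugs)
#' @param thresholds named list with entries \code{single_pos},
#'   \code{single_neg}, \code{pair_pos}, \code{pair_neg}; the counting
#'   thresholds of step 4
#' @param min_overlap low-overlap exclusion threshold for selected pathways
#' @param restrict_ranks re-rank within pathway members before KS scoring
#' @param seed RNG seed for the permutation streams
#' @return object of class \code{combo_screen}: \code{enrichment},
#'   \code{connectivity}, \code{single_scores}, \code{pair_scores},
#'   \code{single_ranking}, \code{pair_ranking}, \code{config}
#' @export
combo_screen <- function(compendium, signature, pathways,
                         alpha_pathway = 0.01, alpha_drug = 0.01,
                         n_perm = 10000L,
                         mode = c("both", "single", "pair"),
                         orientation = c("reverse", "mimic"),
                         pair_universe = c("significant_singles", "all"),
                         pair_filter = NULL,
                         thresholds = list(single_pos = 0, single_neg = 0,
                                           pair_pos = 0.5, pair_neg = -0.5),
                         min_overlap = 3L, restrict_ranks = FALSE,
                         seed = 1L) {
  stopifnot(inherits(compendium, "rank_compendium"),
            inherits(signature, "expr_signature"))
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  pair_universe <- match.arg(pair_universe)
  config <- list(alpha_pathway = alpha_pathway, alpha_drug = alpha_drug,
                 n_perm = n_perm, mode = mode, orientation = orientation,
                 pair_universe = pair_universe, thresholds = thresholds,
                 min_overlap = min_overlap,
                 restrict_ranks = restrict_ranks, seed = seed)

  enrichment <- select_pathways(signature, pathways, probe_ids(compendium),
                                alpha = alpha_pathway, min_overlap = min_overlap)
  keep <- enrichment$pathway_id[enrichment$selected & !enrichment$low_overlap]
  empty_scores <- data.frame(key = character(), pathway_id = character(),
                             set_size = integer(), set_es = numeric(),
                             p_value = numeric(), n_permutations = integer(),
                             significant = logical())
  out <- list(enrichment = enrichment, connectivity = NULL,
              single_scores = empty_scores, pair_scores = empty_scores,
              single_ranking = NULL, pair_ranking = NULL, config = config)
  class(out) <- "combo_screen"
  if (!length(keep)) {
    message("no pathway passed alpha = ", alpha_pathway,
            " (or all were low-overlap); downstream outputs are empty")
    out$connectivity <- pathway_connectivity(compendium, signature, pathways[character(0)])
    return(out)
  }
  oriented <- if (orientation == "reverse") reverse_signature(signature) else signature
  out$connectivity <- pathway_connectivity(compendium, oriented, pathways[keep],
                                           restrict_ranks = restrict_ranks)

  mols <- molecules(compendium)
  single_keys <- lapply(mols, drug_set_key)
  if (mode %in% c("both", "single") || pair_universe == "significant_singles") {
    out$single_scores <- score_drug_sets(compendium, out$connectivity,
                                         single_keys, n_perm = n_perm,
                                         alpha = alpha_drug, seed = seed)
    if (mode %in% c("both", "single"))
      out$single_ranking <- rank_candidates(out$single_scores, mode = "single",
                                            alpha = alpha_drug,
                                            pos_threshold = thresholds$single_pos,
                                            neg_threshold = thresholds$single_neg)
  }
  if (mode %in% c("both", "pair")) {
    eligible <- if (pair_universe == "significant_singles") {
      sig <- out$single_scores[out$single_scores$significant, , drop = FALSE]
      unique(sig$key)
    } else mols
    if (!is.null(pair_filter)) eligible <- intersect(eligible, pair_filter)
    if (length(eligible) >= 2L) {
      pair_keys <- enumerate_pairs(eligible)
      out$pair_scores <- score_drug_sets(compendium, out$connectivity,
                                         pair_keys, n_perm = n_perm,
                                         alpha = alpha_drug, seed = seed + 1L)
      out$pair_ranking <- rank_candidates(out$pair_scores, mode = "pair",
                                          alpha = alpha_drug,
                                          pos_threshold = thresholds$pair_pos,
                                          neg_threshold = thresholds$pair_neg)
    } else {
      message("fewer than 2 eligible molecules for pairing; pair outputs empty")
    }
  }
  out
}

#' @export
print.combo_screen <- function(x, ...) {
  sel <- sum(x$enrichment$selected & !x$enrichment$low_overlap)
  cat("combo_screen: ", sel, "/", nrow(x$enrichment),
      " pathways selected (alpha = ", x$config$alpha_pathway, ")\n", sep = "")
  if (!is.null(x$single_ranking) && nrow(x$single_ranking)) {
    cat("top single molecules:\n")
    print(utils::head(x$single_ranking[, c("rank", "key", "n_positive")], 5),
          row.names = FALSE)
  }
  if (!is.null(x$pair_ranking) && nrow(x$pair_ranking)) {
    cat("top pairs:\n")
    print(utils::head(x$pair_ranking[, c("rank", "key", "n_positive")], 5),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.combo_screen <- function(object, ...) {
  cat("Pathway enrichment:\n")
  print(object$enrichment, row.names = FALSE)
  cat("\nDrug-set scores: ", nrow(object$single_scores), " single / ",
      nrow(object$pair_scores), " pair rows\n", sep = "")
  if (!is.null(object$pair_ranking)) {
    cat("\nPair ranking:\n")
    print(utils::head(object$pair_ranking, 15), row.names = FALSE)
  }
  invisible(object)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write screening outputs as deterministic TSV tables
#'
#' Writes the enrichment, connectivity, per-(key, pathway) score and ranking
#' tables. Outputs are fully determined by the screen object (which is itself
#' seed-deterministic), so repeated writes are byte-identical.
#'
#' @param screen a \code{\link{combo_screen}} result
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_results <- function(screen, dir) {
  stopifnot(inherits(screen, "combo_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(enrichment = file.path(dir, "pathway_enrichment.tsv"),
             connectivity = file.path(dir, "connectivity.tsv"),
             single_scores = file.path(dir, "single_scores.tsv"),
             pair_scores = file.path(dir, "pair_scores.tsv"),
             single_ranking = file.path(dir, "single_ranking.tsv"),
             pair_ranking = file.path(dir, "pair_ranking.tsv"))
  write_tsv(screen$enrichment, files["enrichment"])
  write_tsv(screen$connectivity %||% data.frame(), files["connectivity"])
  write_tsv(screen$single_scores, files["single_scores"])
  write_tsv(screen$pair_scores, files["pair_scores"])
  empty_rank <- data.frame(rank = integer(), key = character(),
                           n_positive = integer(), n_negative = integer(),
                           positive_pathways = character(),
                           negative_pathways = character(),
                           sum_abs_es = numeric())
  write_tsv(screen$single_ranking %||% empty_rank, files["single_ranking"])
  write_tsv(screen$pair_ranking %||% empty_rank, files["pair_ranking"])
  invisible(files)
}
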