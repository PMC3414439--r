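#' Generate a synthetic pathway collection
#'
#' Draws reproducible pathway gene sets over a probe universe
#' \code{p0001..pNNNN}. With \code{overlap = 0} the sets are pairwise
#' disjoint (an error if the universe is too small); with \code{overlap > 0}
#' that fraction of each set is drawn from the whole universe, so sets may
#' share members.
#'
#' @param n_pathways number of sets
#' @param size_range length-2 integer vector (min, max) of set sizes
#' @param universe number of probes in the universe
#' @param overlap fraction of each set drawn without disjointness (default 0)
#' @param seed RNG seed
#' @return named list of member vectors (pathway ids \code{PW01..}), with a
#'   \code{"description"} attribute; the probe universe is kept in the
#'   \code{"universe"} attribute
#' @export
gen_pathways <- function(n_pathways, size_range = c(10L, 30L), universe = 1000L,
                         overlap = 0, seed = 1L) {
  stopifnot(n_pathways >= 1L, length(size_range) == 2L)
  if (size_range[2L] > universe) stop("max pathway size exceeds the universe")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  probes <- sprintf("p%04d", seq_len(universe))
  size_seq <- seq.int(size_range[1L], size_range[2L])
  sizes <- size_seq[sample.int(length(size_seq), n_pathways, replace = TRUE)]
  if (overlap <= 0 && sum(sizes) > universe)
    stop("disjoint sets need ", sum(sizes), " probes but universe has ", universe)
  free <- probes
  sets <- vector("list", n_pathways)
  for (i in seq_len(n_pathways)) {
    n_shared <- round(overlap * sizes[i])
    own <- sample(free, sizes[i] - n_shared)
    free <- setdiff(free, own)
    shared <- if (n_shared > 0) sample(setdiff(probes, own), n_shared) else character(0)
    sets[[i]] <- sort(c(own, shared))
  }
  names(sets) <- sprintf("PW%02d", seq_len(n_pathways))
  attr(sets, "description") <- setNames(
    sprintf("synthetic signaling pathway %d", seq_len(n_pathways)), names(sets))
  attr(sets, "universe") <- probes
  sets
}

#' Specification of a planted drug-pathway signal
#'
#' Declares that every instance of one molecule shifts a fraction
#' (\code{strength}) of the disease signature's probes within one pathway to
#' the rank extremes. Direction \code{"reverse"} plants a therapeutic-like
#' profile: disease-up probes go to the bottom ranks (down-regulated by the
#' treatment) and disease-down probes to the top; \code{"mimic"} does the
#' opposite.
#'
#' @param molecule_name molecule carrying the signal
#' @param pathway_id pathway in which the signal lives
#' @param direction \code{"reverse"} or \code{"mimic"}
#' @param strength fraction of signature-within-pathway probes shifted, in (0,1]
#' @param n_instances number of the molecule's instances planted (default all)
#' @return a \code{plant_spec} list
#' @export
plant_spec <- function(molecule_name, pathway_id, direction = c("reverse", "mimic"),
                       strength = 1, n_instances = NULL) {
  direction <- match.arg(direction)
  if (strength <= 0 || strength > 1) stop("strength must be in (0, 1]")
  structure(list(molecule_name = molecule_name, pathway_id = pathway_id,
                 direction = direction, strength = strength,
                 n_instances = n_instances),
            class = "plant_spec")
}

#' Generate a synthetic rank-profile compendium
#'
#' Unplanted instances carry uniformly random rank permutations (the simplest
#' exchangeable null, matching the permutation test's assumptions). For a
#' planted instance, a \code{strength} fraction of the disease signature's
#' probes inside the planted pathway receive large latent-score offsets (with
#' jitter of standard deviation \code{noise}) before ranking, which pushes
#' them to the rank extremes while keeping every column a valid permutation.
#'
#' Instance ids are assigned in seeded random order across molecules
#' (accession-style numbering), so that lexicographic id order carries no
#' information about molecule identity.
#'
#' @param universe number of probes
#' @param molecule_names character vector of molecule names
#' @param instances_per_molecule profiles per molecule (default 5)
#' @param pathways pathway collection (needed to resolve plants)
#' @param plants list of \code{\link{plant_spec}}s (default none)
#' @param disease_signature \code{\link{expr_signature}} the plants act on
#'   (required when \code{plants} is non-empty)
#' @param noise jitter sd on planted latent scores (default 0.05)
#' @param seed RNG seed
#' @return a \code{\link{rank_compendium}}
#' @export
gen_compendium <- function(universe = 1000L, molecule_names,
                           instances_per_molecule = 5L,
                           pathways = NULL, plants = list(),
                           disease_signature = NULL,
                           noise = 0.05, seed = 1L) {
  stopifnot(length(molecule_names) >= 1L, instances_per_molecule >= 1L)
  if (length(plants)) {
    if (is.null(pathways) || is.null(disease_signature))
      stop("plants need both a pathway collection and a disease signature")
    bad_mol <- setdiff(vapply(plants, `[[`, "", "molecule_name"), molecule_names)
    if (length(bad_mol)) stop("plant references unknown molecule(s): ",
                              paste(bad_mol, collapse = ", "))
    bad_pw <- setdiff(vapply(plants, `[[`, "", "pathway_id"), names(pathways))
    if (length(bad_pw)) stop("plant references unknown pathway(s): ",
                             paste(bad_pw, collapse = ", "))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  probes <- sprintf("p%04d", seq_len(universe))
  n_inst <- length(molecule_names) * instances_per_molecule
  inst_num <- sample.int(n_inst)          # accession-style scattered ids
  inst_ids <- sprintf("inst%04d", inst_num)
  mol_of <- rep(molecule_names, each = instances_per_molecule)
  cells <- c("MCF7", "PC3", "HL60", "A549", "SKMEL5")
  meta <- data.frame(instance_id = inst_ids,
                     molecule_name = mol_of,
                     cell_line = sample(cells, n_inst, replace = TRUE),
                     dose = paste0(sample(c(1, 10, 100), n_inst, replace = TRUE), "uM"),
                     batch = paste0("b", sample.int(8, n_inst, replace = TRUE)),
                     stringsAsFactors = FALSE)
  plant_by_mol <- split(plants, vapply(plants, `[[`, "", "molecule_name"))
  ranks <- matrix(0L, nrow = universe, ncol = n_inst,
                  dimnames = list(probes, inst_ids))
  inst_seq_in_mol <- stats::ave(seq_len(n_inst), mol_of, FUN = seq_along)
  for (j in seq_len(n_inst)) {
    score <- stats::runif(universe)
    for (pl in plant_by_mol[[mol_of[j]]] %||% list()) {
      if (!is.null(pl$n_instances) && inst_seq_in_mol[j] > pl$n_instances) next
      memb <- pathways[[pl$pathway_id]]
      up_t <- intersect(disease_signature$up, memb)
      down_t <- intersect(disease_signature$down, memb)
      up_t <- up_t[seq_len(ceiling(pl$strength * length(up_t)))]
      down_t <- down_t[seq_len(ceiling(pl$strength * length(down_t)))]
      s <- if (pl$direction == "reverse") -1 else 1
      # reverse: disease-up probes sink (low score -> bottom ranks),
      #          disease-down probes surface (high score -> rank 1 side)
      score[match(up_t, probes)] <- score[match(up_t, probes)] +
        s * 2 + stats::rnorm(length(up_t), 0, noise)
      score[match(down_t, probes)] <- score[match(down_t, probes)] -
        s * 2 + stats::rnorm(length(down_t), 0, noise)
    }
    ranks[, j] <- rank(-score, ties.method = "first")
  }
  rank_compendium(ranks, meta)
}

#' Generate a disease signature concentrated in chosen pathways
#'
#' Draws \code{round(purity * size)} probes from the union of the perturbed
#' pathways' members and the remainder from the background universe, then
#' splits the signature into up/down lists per \code{up_fraction}.
#'
#' @param pathways pathway collection from \code{\link{gen_pathways}} (its
#'   \code{"universe"} attribute supplies the background)
#' @param perturbed pathway ids the signature is drawn from
#' @param up_fraction fraction of signature probes assigned to the up list
#'   (default 0.5); 0 or 1 produces a one-sided signature with a warning
#' @param size total signature size
#' @param purity fraction drawn from perturbed pathways (default 0.9)
#' @param seed RNG seed
#' @return an \code{\link{expr_signature}}
#' @export
gen_disease_signature <- function(pathways, perturbed, up_fraction = 0.5,
                                  size = 100L, purity = 0.9, seed = 1L) {
  if (size < 1L) stop("signature size must be >= 1")
  missing_pw <- setdiff(perturbed, names(pathways))
  if (length(missing_pw)) stop("unknown perturbed pathway(s): ",
                               paste(missing_pw, collapse = ", "))
  universe <- attr(pathways, "universe")
  if (is.null(universe)) universe <- sort(unique(unlist(pathways)))
  pool <- sort(unique(unlist(pathways[perturbed])))
  bg <- setdiff(universe, pool)
  n_path <- min(round(purity * size), length(pool))
  n_bg <- size - n_path
  if (n_bg > length(bg)) stop("signature size infeasible for this universe")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  members <- c(sample(pool, n_path), if (n_bg > 0) sample(bg, n_bg))
  members <- sample(members)            # shuffle before the up/down split
  n_up <- round(up_fraction * length(members))
  expr_signature(up = members[seq_len(n_up)],
                 down = members[setdiff(seq_along(members), seq_len(n_up))],
                 label = paste0("synthetic:", paste(perturbed, collapse = "+")))
}

#' The pair-recovery fixture
#'
#' Canonical end-to-end test scenario: 20 molecules over a 1,000-probe
#' universe and 10 disjoint pathways; molecule \code{drugA} reverses the
#' disease signature inside pathway PW01 and \code{drugB} inside PW02, and
#' the disease signature is drawn from those two pathways. With reverse
#' orientation the pair \{drugA, drugB\} should come out as the top-ranked
#' combination. Ten instances per molecule are used so that a pair set with
#' only one planted member still reaches permutation significance (see the
#' methods vignette for the power argument).
#'
#' @param seed RNG seed (default 7)
#' @param n_molecules number of molecules (default 20)
#' @param instances_per_molecule profiles per molecule (default 10)
#' @param n_pathways number of pathways (default 10)
#' @param universe probe-universe size (default 1000)
#' @return list with \code{compendium}, \code{pathways}, \code{signature},
#'   \code{planted_pair}
#' @export
pair_recovery_fixture <- function(seed = 7L, n_molecules = 20L,
                                  instances_per_molecule = 10L,
                                  n_pathways = 10L, universe = 1000L) {
  pathways <- gen_pathways(n_pathways, size_range = c(20L, 40L),
                           universe = universe, seed = seed)
  signature <- gen_disease_signature(pathways, perturbed = c("PW01", "PW02"),
                                     up_fraction = 0.5, size = 60L,
                                     purity = 0.95, seed = seed + 1L)
  mols <- c("drugA", "drugB", sprintf("cmpd%02d", seq_len(n_molecules - 2L)))
  plants <- list(plant_spec("drugA", "PW01", "reverse", strength = 1),
                 plant_spec("drugB", "PW02", "reverse", strength = 1))
  compendium <- gen_compendium(universe = universe, molecule_names = mols,
                               instances_per_molecule = instances_per_molecule,
                               pathways = pathways, plants = plants,
                               disease_signature = signature,
                               noise = 0.05, seed = seed + 2L)
  list(compendium = compendium, pathways = pathways, signature = signature,
       planted_pair = drug_set_key(c("drugA", "drugB")))
}

#' Extract a differential-expression signature from two expression matrices
#'
#' Simple two-group screen: per-probe Welch t-test plus a fold-change filter
#' on the ratio of group means. Probes with mean ratio >= \code{fc_threshold}
#' (inclusive) and p < \code{p_threshold} form the up list; ratio <=
#' 1/\code{fc_threshold} with p < \code{p_threshold} the down list.
#'
#' @param expr_case,expr_ctrl numeric matrices sharing rownames (probes),
#'   columns are replicates (>= 2 each)
#' @param fc_threshold fold-change cut (default 2)
#' @param p_threshold p-value cut (default 0.05)
#' @param label signature label
#' @return an \code{\link{expr_signature}} (possibly empty lists; a warning
#'   is raised if either side is empty)
#' @export
extract_signature <- function(expr_case, expr_ctrl, fc_threshold = 2,
                              p_threshold = 0.05, label = "two-group") {
  if (ncol(expr_case) < 2L || ncol(expr_ctrl) < 2L)
    stop("need >= 2 replicates per group")
  if (!identical(rownames(expr_case), rownames(expr_ctrl)))
    stop("case and control matrices must share probe rows")
  pvals <- vapply(seq_len(nrow(expr_case)), function(i) {
    stats::t.test(expr_case[i, ], expr_ctrl[i, ])$p.value
  }, 0)
  ratio <- rowMeans(expr_case) / rowMeans(expr_ctrl)
  up <- rownames(expr_case)[ratio >= fc_threshold & pvals < p_threshold]
  down <- rownames(expr_case)[ratio <= 1 / fc_threshold & pvals < p_threshold]
  if (!length(up) && !length(down))
    return(structure(list(up = character(0), down = character(0), label = label),
                     class = "expr_signature"))
  expr_signature(up, down, label = label)
}

#' Generate a dose-response table from known median-effect parameters
#'
#' The noiseless table satisfies fa/fu = (D/Dm)^m exactly; with
#' \code{noise_sigma > 0} the fa/fu ratio is multiplied by lognormal noise
#' \code{exp(N(0, noise_sigma))}.
#'
#' @param Dm median-effect dose
#' @param m slope
#' @param doses dose ladder (>= 2 distinct positive doses)
#' @param noise_sigma sd of the log-scale noise (default 0)
#' @param seed RNG seed
#' @param drug_label label for the table
#' @return a \code{\link{dose_response}}
#' @export
gen_dose_response <- function(Dm, m, doses, noise_sigma = 0, seed = 1L,
                              drug_label = "synthetic") {
  if (Dm <= 0 || m == 0) stop("need Dm > 0 and m != 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ratio <- (doses / Dm)^m
  if (noise_sigma > 0) ratio <- ratio * exp(stats::rnorm(length(doses), 0, noise_sigma))
  suppressWarnings(dose_response(doses, ratio / (1 + ratio), drug_label = drug_label))
}

#' Generate a fixed-ratio combination table with a target combination index
#'
#' Analytic Loewe construction: at effect level fa the additive total dose of
#' a combination mixing fraction \code{ratio_a} of drug A satisfies the
#' additivity isobole \code{ratio_a*D/D_A(fa) + (1-ratio_a)*D/D_B(fa) = 1}.
#' The generated combination reaches each effect at \code{ci_target} times
#' that additive dose, so \code{ci_target = 1} is exactly additive and
#' \code{ci_target = 0.5} is strongly synergistic. For each requested total
#' dose the implied effect level is solved numerically (the dose-effect map
#' is strictly monotone).
#'
#' @param fit_a,fit_b \code{\link{median_effect}} fits of the single agents
#' @param ratio_a fraction of drug A in the combination dose, in (0,1)
#' @param ci_target target combination index (> 0, default 1)
#' @param doses total-dose ladder
#' @param noise_sigma lognormal noise on fa/fu (default 0)
#' @param seed RNG seed
#' @return a \code{\link{dose_response}} of total dose vs fraction affected
#' @export
gen_combo_table <- function(fit_a, fit_b, ratio_a, ci_target = 1, doses,
                            noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(fit_a, "median_effect"), inherits(fit_b, "median_effect"))
  if (ci_target <= 0) stop("ci_target must be > 0")
  if (ratio_a <= 0 || ratio_a >= 1) stop("ratio_a must be in (0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dose_at <- function(fa) {
    ci_target / (ratio_a / dose_for_effect(fit_a, fa) +
                 (1 - ratio_a) / dose_for_effect(fit_b, fa))
  }
  fa_at <- vapply(doses, function(D) {
    f <- function(lg) dose_at(stats::plogis(lg)) - D
    root <- stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
    stats::plogis(root)
  }, 0)
  ratio <- fa_at / (1 - fa_at)
  if (noise_sigma > 0) ratio <- ratio * exp(stats::rnorm(length(doses), 0, noise_sigma))
  suppressWarnings(dose_response(doses, ratio / (1 + ratio),
                                 drug_label = sprintf("combo ci=%g", ci_target)))
}
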