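#' Key identifying a single molecule or an unordered molecule pair
#'
#' @param molecules character vector of 1 or 2 molecule names; a pair's two
#'   names must differ and the key is order-invariant (\{A,B\} == \{B,A\})
#' @return object of class \code{drug_set_key}
#' @export
drug_set_key <- function(molecules) {
  molecules <- as.character(molecules)
  if (!length(molecules) %in% 1:2)
    stop("a drug-set key holds 1 or 2 molecule names")
  if (length(molecules) == 2L && molecules[1L] == molecules[2L])
    stop("a pair's two molecule names must differ")
  structure(list(molecules = sort(molecules)), class = "drug_set_key")
}

#' @export
print.drug_set_key <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.drug_set_key <- function(x, ...) paste(x$molecules, collapse = " + ")

#' Collect every profile instance of a key's molecules
#'
#' Returns the union of all instances (all doses, all cell lines) of the
#' molecules in the key. Unknown molecule names raise an error listing
#' near-matches from the compendium.
#'
#' @param compendium a \code{\link{rank_compendium}}
#' @param key a \code{\link{drug_set_key}} (or character vector coerced to one)
#' @return character vector of instance ids
#' @export
collect_instances <- function(compendium, key) {
  stopifnot(inherits(compendium, "rank_compendium"))
  if (!inherits(key, "drug_set_key")) key <- drug_set_key(key)
  meta <- compendium$metadata
  known <- unique(meta$molecule_name)
  unknown <- setdiff(key$molecules, known)
  if (length(unknown)) {
    hints <- unlist(lapply(unknown, function(u) {
      agrep(u, known, max.distance = 0.3, value = TRUE, ignore.case = TRUE)
    }))
    stop("unknown molecule(s): ", paste(unknown, collapse = ", "),
         if (length(hints)) paste0(" (did you mean: ",
                                   paste(unique(hints), collapse = ", "), "?)"))
  }
  meta$instance_id[meta$molecule_name %in% key$molecules]
}

#' Set-level KS score of member instances within an ES ranking
#'
#' The same unweighted KS statistic as \code{\link{ks_score}}, applied to the
#' positions of a drug set's instances within one pathway's ES-descending
#' profile ranking. Positive scores mean the set's profiles concentrate among
#' the best-connected profiles.
#'
#' @param ordered_instances instance ids in descending-ES order for one pathway
#' @param member_instances instance ids belonging to the drug set
#' @return KS score in [-1, 1]
#' @export
drug_set_es <- function(ordered_instances, member_instances) {
  pos <- sort.int(match(unique(member_instances), ordered_instances))
  pos <- pos[!is.na(pos)]
  if (!length(pos)) stop("no member instance present in the ranked profile list")
  ks_score(pos, length(ordered_instances))
}

# Draw n_perm random size-t subsets of 1..m (columns sorted) and score them.
perm_null_scores <- function(m, t, n_perm) {
  P <- vapply(seq_len(n_perm),
              function(i) sort.int(sample.int(m, t)),
              integer(t))
  if (t == 1L) P <- matrix(P, nrow = 1L)
  ks_score_cols(P, m)
}

#' Permutation p-value for a set-level KS score
#'
#' Two-sided add-one permutation estimate: the null scores are
#' \code{\link{drug_set_es}} values of uniformly random subsets of the same
#' size, and \code{p = (#\{|null| >= |observed|\} + 1) / (n_perm + 1)}.
#' Reproducible given \code{seed}.
#'
#' @param ordered_instances instance ids in descending-ES order (only the
#'   count matters for the null)
#' @param set_size number of member instances
#' @param observed the observed set-level KS score
#' @param n_perm number of permutations (default 10000)
#' @param seed RNG seed
#' @return p-value in (0, 1]
#' @export
permutation_pvalue <- function(ordered_instances, set_size, observed,
                               n_perm = 10000L, seed = 1L) {
  m <- length(ordered_instances)
  if (set_size < 1L || set_size > m)
    stop("set_size must be in 1..", m)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  null <- perm_null_scores(m, set_size, n_perm)
  (sum(abs(null) >= abs(observed)) + 1) / (n_perm + 1)
}

#' Enumerate candidate molecule pairs
#'
#' @param molecule_names character vector of molecule names
#' @param filter optional subset of names to which both pair members are
#'   restricted (e.g. an approved-drug list)
#' @return list of \code{\link{drug_set_key}} pairs
#' @export
enumerate_pairs <- function(molecule_names, filter = NULL) {
  mols <- sort(unique(as.character(molecule_names)))
  if (!is.null(filter)) mols <- intersect(mols, filter)
  if (length(mols) < 2L) stop("need at least 2 eligible molecules to form pairs")
  cmb <- utils::combn(mols, 2L)
  lapply(seq_len(ncol(cmb)), function(j) drug_set_key(cmb[, j]))
}

#' Score drug sets (singles or pairs) across selected pathways
#'
#' For every (key, pathway) combination: ranks the pathway's evaluable
#' profiles by descending ES, computes the set-level KS score of the key's
#' instances, and attaches a two-sided subset-permutation p-value. The
#' permutation null depends only on the number of ranked profiles and the set
#' size, so null draws are shared across combinations of equal size (one
#' deterministic RNG stream seeded once per call).
#'
#' @param compendium a \code{\link{rank_compendium}}
#' @param connectivity output of \code{\link{pathway_connectivity}} for the
#'   pathways to score
#' @param keys list of \code{\link{drug_set_key}} objects
#' @param n_perm permutations per null (default 10000)
#' @param alpha significance level used for the \code{significant} flag
#'   (default 0.01)
#' @param seed RNG seed for the permutation stream
#' @return data.frame: \code{key}, \code{pathway_id}, \code{set_size},
#'   \code{set_es}, \code{p_value}, \code{n_permutations}, \code{significant};
#'   ordered by key then pathway
#' @export
score_drug_sets <- function(compendium, connectivity, keys,
                            n_perm = 10000L, alpha = 0.01, seed = 1L) {
  stopifnot(inherits(compendium, "rank_compendium"))
  if (!length(keys))
    return(data.frame(key = character(), pathway_id = character(),
                      set_size = integer(), set_es = numeric(),
                      p_value = numeric(), n_permutations = integer(),
                      significant = logical()))
  keys <- lapply(keys, function(k) if (inherits(k, "drug_set_key")) k else drug_set_key(k))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pids <- sort(unique(connectivity$pathway_id))
  members <- lapply(keys, function(k) collect_instances(compendium, k))
  key_labels <- vapply(keys, format, "")
  null_cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    sub <- connectivity[connectivity$pathway_id == pids[i], , drop = FALSE]
    ordered <- rank_profiles(sub)
    m <- length(ordered)
    es <- numeric(length(keys)); pv <- numeric(length(keys))
    sz <- integer(length(keys))
    for (k in seq_along(keys)) {
      memb <- intersect(members[[k]], ordered)
      if (!length(memb)) { es[k] <- NA; pv[k] <- NA; sz[k] <- 0L; next }
      sz[k] <- length(memb)
      es[k] <- drug_set_es(ordered, memb)
      ckey <- paste(m, sz[k], sep = "_")
      if (is.null(null_cache[[ckey]]))
        null_cache[[ckey]] <- abs(perm_null_scores(m, sz[k], n_perm))
      pv[k] <- (sum(null_cache[[ckey]] >= abs(es[k])) + 1) / (n_perm + 1)
    }
    rows[[i]] <- data.frame(key = key_labels, pathway_id = pids[i],
                            set_size = sz, set_es = es, p_value = pv,
                            n_permutations = as.integer(n_perm),
                            significant = !is.na(pv) & pv < alpha,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$key, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank drug-set candidates by pathway counts
#'
#' Counts, for each candidate, the pathways whose set-level score is strictly
#' above the positive threshold (0 for single molecules, +0.5 for pairs) and,
#' by default, significant at \code{alpha}; candidates are ranked by
#' descending count, ties broken by descending summed |set_es| over the
#' counted-eligible (significant) pathways, then by key name. Pathways below
#' the negative threshold (0 / -0.5) are listed as potential adverse matches.
#'
#' @param scores output of \code{\link{score_drug_sets}}
#' @param mode \code{"single"} or \code{"pair"}; sets the default thresholds
#' @param alpha significance level (default 0.01)
#' @param pos_threshold,neg_threshold override the mode's thresholds
#' @param require_significance only count pathways with \code{p < alpha}
#'   (default TRUE)
#' @return data.frame: \code{rank}, \code{key}, \code{n_positive},
#'   \code{n_negative}, \code{positive_pathways}, \code{negative_pathways}
#'   (comma-separated), \code{sum_abs_es}
#' @export
rank_candidates <- function(scores, mode = c("pair", "single"), alpha = 0.01,
                            pos_threshold = NULL, neg_threshold = NULL,
                            require_significance = TRUE) {
  mode <- match.arg(mode)
  if (is.null(pos_threshold)) pos_threshold <- if (mode == "pair") 0.5 else 0
  if (is.null(neg_threshold)) neg_threshold <- if (mode == "pair") -0.5 else 0
  n_mol <- lengths(strsplit(scores$key, " + ", fixed = TRUE))
  if (length(n_mol) && length(unique(n_mol)) > 1L)
    stop("mixed single/pair keys in one ranking")
  if (length(n_mol) && unique(n_mol) != (if (mode == "pair") 2L else 1L))
    stop("scores are not of mode '", mode, "'")
  keys <- unique(scores$key)
  rows <- lapply(keys, function(k) {
    sub <- scores[scores$key == k & !is.na(scores$set_es), , drop = FALSE]
    eligible <- if (require_significance) sub[!is.na(sub$p_value) & sub$p_value < alpha, , drop = FALSE] else sub
    pos <- eligible$pathway_id[eligible$set_es > pos_threshold]
    neg <- eligible$pathway_id[eligible$set_es < neg_threshold]
    data.frame(key = k,
               n_positive = length(pos),
               n_negative = length(neg),
               positive_pathways = paste(sort(pos), collapse = ","),
               negative_pathways = paste(sort(neg), collapse = ","),
               sum_abs_es = sum(abs(eligible$set_es)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_positive, -out$sum_abs_es, out$key), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
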