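#' Unweighted Kolmogorov-Smirnov enrichment score of tag positions
#'
#' Given the positions \code{V(1) < ... < V(t)} of \code{t} tagged items in a
#' ranked list of \code{n} items, computes
#' \deqn{a = \max_j (j/t - V(j)/n), \quad b = \max_j (V(j)/n - (j-1)/t)}
#' and returns \code{a} if \code{a >= b}, else \code{-b}. Positive scores
#' mean the tags concentrate near the top of the list, negative near the
#' bottom. The exact tie \code{a == b} returns the non-negative branch.
#'
#' @param positions strictly increasing integer positions in \code{1..n}
#' @param n total number of ranked items
#' @return a score in [-1, 1]
#' @export
ks_score <- function(positions, n) {
  t <- length(positions)
  if (t == 0L) stop("empty tag set: ks_score needs at least one position")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (positions[1L] < 1L || positions[t] > n)
    stop("positions must lie in 1..n")
  j <- seq_len(t)
  a <- max(j / t - positions / n)
  b <- max(positions / n - (j - 1) / t)
  if (a >= b) a else -b
}

# Sort each column of a matrix, keeping matrix shape even for one row.
sort_cols <- function(P) {
  if (nrow(P) == 1L) return(P)
  apply(P, 2L, sort.int)
}

# Vectorised ks_score over the columns of a position matrix (each column a
# sorted set of t positions out of n). Used by the permutation machinery.
ks_score_cols <- function(posmat, n) {
  t <- nrow(posmat)
  j <- seq_len(t)
  amat <- j / t - posmat / n
  bmat <- posmat / n - (j - 1) / t
  a <- amat[1L, ]; b <- bmat[1L, ]
  if (t > 1L) for (r in 2:t) {
    a <- pmax(a, amat[r, ])
    b <- pmax(b, bmat[r, ])
  }
  ifelse(a >= b, a, -b)
}

#' Connectivity score of a signature against one rank-ordered profile
#'
#' Restricts the signature's up and down lists to the members of one pathway
#' (then to probes present in the profile), computes the KS score of each tag
#' set against the full-length rank column, and combines them: the raw
#' enrichment score is \code{ks_up - ks_down} when the two scores disagree in
#' sign (or either is zero), and 0 when they agree — a profile must move the
#' up and down probes in opposite directions to count as connected.
#'
#' @param signature an \code{\link{expr_signature}}
#' @param pathway_members character vector of pathway probe ids, or NULL for
#'   no restriction
#' @param ranks_column named integer vector: rank of every probe in one
#'   profile (a permutation of \code{1..n}; names are probe ids)
#' @return list with \code{ks_up}, \code{ks_down}, \code{raw_es},
#'   \code{evaluable}; \code{evaluable} is FALSE when either restricted tag
#'   set is empty (scores are then NA)
#' @export
profile_es <- function(signature, pathway_members, ranks_column) {
  stopifnot(inherits(signature, "expr_signature"))
  n <- length(ranks_column)
  probes <- names(ranks_column)
  if (is.null(probes)) stop("ranks_column must be named by probe id")
  up <- signature$up; down <- signature$down
  if (!is.null(pathway_members)) {
    up <- intersect(up, pathway_members)
    down <- intersect(down, pathway_members)
  }
  up <- intersect(up, probes); down <- intersect(down, probes)
  if (length(up) == 0L || length(down) == 0L)
    return(list(ks_up = NA_real_, ks_down = NA_real_, raw_es = NA_real_,
                evaluable = FALSE))
  ks_up <- ks_score(sort.int(unname(ranks_column[up])), n)
  ks_down <- ks_score(sort.int(unname(ranks_column[down])), n)
  raw_es <- if (ks_up == 0 || ks_down == 0 || sign(ks_up) != sign(ks_down))
    ks_up - ks_down else 0
  list(ks_up = ks_up, ks_down = ks_down, raw_es = raw_es, evaluable = TRUE)
}

#' Per-sign normalisation of raw enrichment scores
#'
#' Positive raw scores are divided by the maximum positive score, negative
#' ones by the absolute value of the minimum; zeros stay zero. Applied per
#' pathway so that scores are comparable across pathways on a [-1, 1] scale.
#'
#' @param raw numeric vector of raw enrichment scores (NA allowed and kept)
#' @return normalised scores in [-1, 1]
#' @export
normalize_es <- function(raw) {
  out <- raw
  pos <- which(!is.na(raw) & raw > 0)
  neg <- which(!is.na(raw) & raw < 0)
  if (length(pos)) out[pos] <- raw[pos] / max(raw[pos])
  if (length(neg)) out[neg] <- raw[neg] / abs(min(raw[neg]))
  out
}

#' Connectivity scores of a signature against every profile, per pathway
#'
#' For each pathway, scores every instance of the compendium with
#' \code{\link{profile_es}} and normalises the raw scores per pathway with
#' \code{\link{normalize_es}}. Signature restriction is to the tag set only:
#' the KS statistic always runs against the full-length rank column, unless
#' \code{restrict_ranks = TRUE}, which re-ranks within the pathway's probes
#' (sensitivity-analysis mode).
#'
#' @param compendium a \code{\link{rank_compendium}}
#' @param signature an \code{\link{expr_signature}} (already oriented)
#' @param pathways named list of member vectors; scored pathways
#' @param restrict_ranks re-rank within pathway members before scoring
#' @return data.frame (long format): \code{pathway_id}, \code{instance_id},
#'   \code{ks_up}, \code{ks_down}, \code{raw_es}, \code{es}; non-evaluable
#'   profiles are omitted, and their count per pathway is kept in the
#'   \code{"n_not_evaluable"} attribute
#' @export
pathway_connectivity <- function(compendium, signature, pathways,
                                 restrict_ranks = FALSE) {
  stopifnot(inherits(compendium, "rank_compendium"))
  ranks <- compendium$ranks
  probes <- rownames(ranks)
  n_all <- nrow(ranks)
  res <- vector("list", length(pathways))
  qc <- integer(length(pathways))
  names(qc) <- names(pathways)
  for (i in seq_along(pathways)) {
    pid <- names(pathways)[i]
    memb <- intersect(pathways[[i]], probes)
    up <- intersect(signature$up, memb)
    down <- intersect(signature$down, memb)
    if (length(up) == 0L || length(down) == 0L) {
      qc[i] <- ncol(ranks)
      next
    }
    if (restrict_ranks) {
      sub <- ranks[memb, , drop = FALSE]
      sub <- apply(sub, 2L, rank, ties.method = "first")
      rownames(sub) <- memb
      n <- length(memb)
      up_pos <- sub[up, , drop = FALSE]
      down_pos <- sub[down, , drop = FALSE]
    } else {
      n <- n_all
      up_pos <- ranks[up, , drop = FALSE]
      down_pos <- ranks[down, , drop = FALSE]
    }
    ks_up <- ks_score_cols(sort_cols(up_pos), n)
    ks_down <- ks_score_cols(sort_cols(down_pos), n)
    raw <- ifelse(ks_up == 0 | ks_down == 0 | sign(ks_up) != sign(ks_down),
                  ks_up - ks_down, 0)
    res[[i]] <- data.frame(pathway_id = pid,
                           instance_id = colnames(ranks),
                           ks_up = ks_up, ks_down = ks_down,
                           raw_es = raw, es = normalize_es(raw),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(pathway_id = character(), instance_id = character(),
                      ks_up = numeric(), ks_down = numeric(),
                      raw_es = numeric(), es = numeric())
  rownames(out) <- NULL
  attr(out, "n_not_evaluable") <- qc
  out
}

#' Rank profiles by descending enrichment score
#'
#' Orders one pathway's evaluable profiles by descending normalised ES; ties
#' are broken by lexicographic instance id so the ordering is deterministic.
#'
#' @param es_table data.frame with columns \code{instance_id} and \code{es}
#'   (one pathway's rows of \code{\link{pathway_connectivity}} output)
#' @return character vector of instance ids, best-connected first
#' @export
rank_profiles <- function(es_table) {
  stopifnot(all(c("instance_id", "es") %in% names(es_table)))
  es_table$instance_id[order(-es_table$es, es_table$instance_id)]
}
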