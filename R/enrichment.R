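#' Upper-tail hypergeometric p-value for a set overlap
#'
#' Probability of drawing at least \code{overlap} pathway members when
#' \code{signature_size} probes are drawn without replacement from a universe
#' of \code{universe_size} probes of which \code{pathway_size} belong to the
#' pathway: P(X >= overlap) for X ~ Hypergeom.
#'
#' @param overlap observed intersection size
#' @param signature_size number of signature probes in the universe
#' @param pathway_size number of pathway probes in the universe
#' @param universe_size total probes
#' @return p-value in (0, 1]
#' @export
hypergeom_pvalue <- function(overlap, signature_size, pathway_size, universe_size) {
  stopifnot(length(overlap) == 1L)
  if (overlap < 0 || signature_size < 0 || pathway_size < 0 || universe_size < 1)
    stop("counts must be non-negative and universe_size >= 1")
  if (signature_size > universe_size || pathway_size > universe_size)
    stop("signature_size and pathway_size cannot exceed universe_size")
  if (overlap > min(signature_size, pathway_size))
    stop("overlap exceeds min(signature_size, pathway_size)")
  if (overlap == 0) return(1)
  stats::phyper(overlap - 1, pathway_size, universe_size - pathway_size,
                signature_size, lower.tail = FALSE)
}

#' Select disease-relevant pathways by over-representation of a signature
#'
#' Tests every pathway for over-representation of the signature (the union of
#' the up and down lists, restricted to the compendium universe first) with
#' the upper-tail hypergeometric test, and selects pathways with raw
#' \code{p < alpha}. Pathways whose overlap with the signature is below
#' \code{min_overlap} are flagged \code{low_overlap} and should be excluded
#' from downstream KS scoring, where a tag set needs a few members to be
#' meaningful.
#'
#' @param signature an \code{\link{expr_signature}}
#' @param pathways named list of member vectors (see \code{\link{read_gmt}})
#' @param universe character vector of all probe ids in the compendium
#' @param alpha selection threshold on the raw p-value (default 0.01)
#' @param min_overlap overlap below which a selected pathway is flagged
#'   low-overlap (default 3)
#' @param adjust apply Benjamini-Hochberg correction before thresholding
#'   (default \code{FALSE}: the raw-p cut is the method's convention)
#' @param mode \code{"joint"} tests up and down probes as one set (default);
#'   \code{"separate"} tests them separately and keeps the smaller p per
#'   pathway
#' @return data.frame with one row per pathway: \code{pathway_id},
#'   \code{name}, \code{overlap}, \code{signature_size}, \code{pathway_size},
#'   \code{universe_size}, \code{p_value}, \code{selected},
#'   \code{low_overlap}; ordered by ascending p then pathway_id
#' @export
select_pathways <- function(signature, pathways, universe, alpha = 0.01,
                            min_overlap = 3L, adjust = FALSE,
                            mode = c("joint", "separate")) {
  stopifnot(inherits(signature, "expr_signature"))
  mode <- match.arg(mode)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty probe universe")
  if (!length(pathways)) stop("empty pathway collection")
  sig_all <- c(signature$up, signature$down)
  dropped <- setdiff(sig_all, universe)
  if (length(dropped))
    warning(length(dropped), " signature probe(s) absent from the universe were dropped")
  if (length(dropped) > length(sig_all) / 2)
    warning("fewer than 50% of signature probes are present in the compendium; ",
            "check that signature and compendium share an identifier space")
  test_sets <- if (mode == "joint") {
    list(intersect(sig_all, universe))
  } else {
    list(intersect(signature$up, universe), intersect(signature$down, universe))
  }
  desc <- attr(pathways, "description")
  N <- length(universe)
  rows <- lapply(names(pathways), function(pid) {
    memb <- intersect(pathways[[pid]], universe)
    K <- length(memb)
    per_set <- vapply(test_sets, function(s) {
      k <- length(intersect(s, memb))
      p <- if (K == 0L || length(s) == 0L) 1 else
        hypergeom_pvalue(k, length(s), K, N)
      c(k, p)
    }, numeric(2))
    best <- which.min(per_set[2L, ])
    data.frame(pathway_id = pid,
               name = if (!is.null(desc) && pid %in% names(desc)) desc[[pid]] else pid,
               overlap = as.integer(per_set[1L, best]),
               signature_size = length(test_sets[[best]]),
               pathway_size = K,
               universe_size = N,
               p_value = per_set[2L, best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_cut <- if (adjust) stats::p.adjust(out$p_value, method = "BH") else out$p_value
  out$selected <- p_cut < alpha
  out$low_overlap <- out$overlap < min_overlap
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
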