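#' Construct a rank-profile compendium
#'
#' A compendium holds one column per treatment instance, each column a
#' rank-ordered list of all probe sets: rank 1 is the most up-regulated probe
#' in that treatment versus its control, rank \code{n} the most down-regulated.
#' Profiles are non-parametric: only the ranks are stored, never expression
#' values.
#'
#' @param ranks integer matrix, probes in rows (rownames = probe ids),
#'   instances in columns (colnames = instance ids). Every column must be a
#'   permutation of \code{1:nrow(ranks)}.
#' @param metadata data.frame with one row per instance and columns
#'   \code{instance_id}, \code{molecule_name}, \code{cell_line}, \code{dose},
#'   \code{batch}.
#' @return an object of class \code{rank_compendium} with elements
#'   \code{ranks} and \code{metadata}.
#' @export
rank_compendium <- function(ranks, metadata) {
  ranks <- as.matrix(ranks)
  if (!is.numeric(ranks)) stop("ranks must be a numeric (integer) matrix")
  storage.mode(ranks) <- "integer"
  n <- nrow(ranks); m <- ncol(ranks)
  if (n < 1L || m < 1L) stop("compendium needs at least one probe and one instance")
  if (is.null(rownames(ranks))) stop("ranks must carry probe ids as rownames")
  if (is.null(colnames(ranks))) stop("ranks must carry instance ids as colnames")
  if (anyDuplicated(rownames(ranks)))
    stop("duplicated probe_id: ", paste(unique(rownames(ranks)[duplicated(rownames(ranks))]), collapse = ", "))
  bad <- which(!apply(ranks, 2L, function(col) !anyNA(col) && all(sort.int(col) == seq_len(n))))
  if (length(bad))
    stop("column(s) not a permutation of 1..", n, ": ",
         paste(colnames(ranks)[bad], collapse = ", "))
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  need <- c("instance_id", "molecule_name", "cell_line", "dose", "batch")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$instance_id))
    stop("duplicated instance_id in metadata")
  absent <- setdiff(colnames(ranks), metadata$instance_id)
  if (length(absent))
    stop("metadata row missing for instance(s): ", paste(absent, collapse = ", "))
  if (any(!nzchar(metadata$molecule_name)) || anyNA(metadata$molecule_name))
    stop("molecule_name must be non-empty for every instance")
  metadata <- metadata[match(colnames(ranks), metadata$instance_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(ranks = ranks, metadata = metadata), class = "rank_compendium")
}

#' @export
print.rank_compendium <- function(x, ...) {
  cat("rank_compendium:", nrow(x$ranks), "probes x", ncol(x$ranks), "instances;",
      length(unique(x$metadata$molecule_name)), "molecules\n")
  invisible(x)
}

#' @export
dim.rank_compendium <- function(x) dim(x$ranks)

#' Probe and instance accessors
#' @param x a \code{rank_compendium}
#' @return character vector of identifiers
#' @export
probe_ids <- function(x) rownames(x$ranks)

#' @rdname probe_ids
#' @export
instance_ids <- function(x) colnames(x$ranks)

#' Molecules present in a compendium
#' @param x a \code{rank_compendium}
#' @return sorted unique molecule names
#' @export
molecules <- function(x) sort(unique(x$metadata$molecule_name))

#' Read a rank matrix and its instance metadata
#'
#' The rank matrix is a TSV whose first column is \code{probe_id} and whose
#' remaining columns are instance ids, with integer cells; the metadata TSV
#' has columns \code{instance_id}, \code{molecule_name}, \code{cell_line},
#' \code{dose}, \code{batch}. Both are validated into a
#' \code{\link{rank_compendium}}; any column that is not a permutation of
#' \code{1..n} is reported by name.
#'
#' @param path rank-matrix TSV
#' @param metadata_path metadata TSV
#' @return a \code{rank_compendium}
#' @export
read_rank_matrix <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(tab) >= 2L || names(tab)[1L] != "probe_id")
    stop("rank matrix must start with a 'probe_id' column followed by instance columns")
  mat <- tab[, -1L, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v) || any(v != as.integer(v)))
      stop("non-integer cell in column '", names(mat)[j], "' of ", path)
  }
  ranks <- as.matrix(mat)
  rownames(ranks) <- as.character(tab$probe_id)
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  rank_compendium(ranks, meta)
}

#' Write a compendium back to the TSV pair
#' @param x a \code{rank_compendium}
#' @param path rank-matrix TSV destination
#' @param metadata_path metadata TSV destination
#' @return invisibly, \code{x}
#' @export
write_rank_matrix <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "rank_compendium"))
  out <- data.frame(probe_id = rownames(x$ranks), x$ranks,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
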