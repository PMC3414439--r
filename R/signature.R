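#' Construct an expression signature
#'
#' A signature is a pair of probe-set identifier lists: probes up-regulated in
#' the state of interest and probes down-regulated. The two lists must be
#' disjoint and their union non-empty.
#'
#' @param up character vector of up-regulated probe ids
#' @param down character vector of down-regulated probe ids
#' @param label free-text label
#' @return object of class \code{expr_signature}
#' @export
expr_signature <- function(up, down, label = "") {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both))
    stop("probe(s) in both up and down lists: ", paste(both, collapse = ", "))
  if (length(up) + length(down) == 0L)
    stop("signature is empty")
  if (length(up) == 0L || length(down) == 0L)
    warning("signature has an empty ", if (length(up)) "down" else "up",
            " list; directional KS scoring needs both sides")
  structure(list(up = up, down = down, label = as.character(label)[1L]),
            class = "expr_signature")
}

#' @export
print.expr_signature <- function(x, ...) {
  cat("expr_signature", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      ": ", length(x$up), " up / ", length(x$down), " down probes\n", sep = "")
  invisible(x)
}

#' Swap the direction of a signature
#'
#' Exchanges the up and down lists. Used for reverse-orientation screening,
#' where molecules that oppose the disease state should surface at positive
#' connectivity scores.
#' @param x an \code{expr_signature}
#' @return the reversed signature
#' @export
reverse_signature <- function(x) {
  stopifnot(inherits(x, "expr_signature"))
  expr_signature(x$down, x$up, label = x$label)
}

read_grp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- trimws(lines)
  lines[!grepl("^#", lines) & nzchar(lines)]
}

#' Read a signature from a pair of GRP files
#'
#' GRP files carry one identifier per line; blank lines and lines starting
#' with '#' are ignored. An identifier present in both files is a hard error.
#'
#' @param up_path GRP file of up probes
#' @param down_path GRP file of down probes
#' @param label optional label (defaults to the up-file name)
#' @return an \code{expr_signature}
#' @export
read_signature <- function(up_path, down_path, label = basename(up_path)) {
  expr_signature(read_grp(up_path), read_grp(down_path), label = label)
}

#' Write a signature as a pair of GRP files
#' @param x an \code{expr_signature}
#' @param up_path,down_path destinations
#' @return invisibly, \code{x}
#' @export
write_signature <- function(x, up_path, down_path) {
  stopifnot(inherits(x, "expr_signature"))
  writeLines(x$up, up_path)
  writeLines(x$down, down_path)
  invisible(x)
}

#' Read a GMT pathway collection
#'
#' One tab-separated record per line: set name, description, then member
#' identifiers. Duplicate members within a line are collapsed. Returns the
#' conventional named-list-of-character-vectors representation (as used by
#' the GSEA family of tools), with per-set descriptions kept in the
#' \code{"description"} attribute.
#'
#' @param path GMT file
#' @return named list of member vectors; names are pathway ids
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicated pathway id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- ids
  attr(sets, "description") <- desc
  sets
}

#' Write a pathway collection as GMT
#' @param sets named list of member vectors (see \code{\link{read_gmt}})
#' @param path destination
#' @return invisibly, \code{sets}
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}
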