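# Fixed-width embedding containers and their on-disk format.

DIM_TAGS <- c("1D", "2D", "3D")

# Default embedding widths per entity kind and dimension tag.
DEFAULT_WIDTHS <- list(
  drug    = c("1D" = 100L, "2D" = 300L, "3D" = 512L),
  protein = c("1D" = 100L, "2D" = 768L, "3D" = 1280L)
)

#' Default embedding width for an entity kind and dimension tag
#'
#' Drugs default to 100/300/512 for 1D/2D/3D, proteins to 100/768/1280.
#'
#' @param entity_kind `"drug"` or `"protein"`.
#' @param dim_tag `"1D"`, `"2D"` or `"3D"`.
#' @export
default_width <- function(entity_kind = c("drug", "protein"),
                          dim_tag = c("1D", "2D", "3D")) {
  entity_kind <- match.arg(entity_kind)
  dim_tag <- match.arg(dim_tag)
  unname(DEFAULT_WIDTHS[[entity_kind]][dim_tag])
}

#' Construct an embedding set
#'
#' A mapping from entity id to a fixed-length real vector, tagged with the
#' entity kind (drug/protein) and the representation dimension (1D/2D/3D).
#'
#' @param vectors Numeric matrix, one row per entity, with rownames = ids.
#' @param entity_kind `"drug"` or `"protein"`.
#' @param dim_tag `"1D"`, `"2D"` or `"3D"`.
#' @return An object of class `embedding_set`.
#' @export
embedding_set <- function(vectors, entity_kind = c("drug", "protein"),
                          dim_tag = c("1D", "2D", "3D")) {
  entity_kind <- match.arg(entity_kind)
  dim_tag <- match.arg(dim_tag)
  if (!is.matrix(vectors) || !is.numeric(vectors) || is.null(rownames(vectors)))
    fdta_stop("vectors must be a numeric matrix with rownames as ids",
              "fusedta_format_error")
  if (anyDuplicated(rownames(vectors)))
    fdta_stop("duplicate id in embedding set", "fusedta_duplicate_error")
  if (any(!is.finite(vectors)))
    fdta_stop("embedding vectors must be finite", "fusedta_format_error")
  structure(list(vectors = vectors, entity_kind = entity_kind,
                 dim_tag = dim_tag, width = ncol(vectors)),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("Embedding set: %d %ss, %s, width %d\n",
              nrow(x$vectors), x$entity_kind, x$dim_tag, x$width))
  invisible(x)
}

#' Look up embedding vectors for a set of ids
#'
#' @param set An [embedding_set()].
#' @param ids Character vector of entity ids.
#' @return Numeric matrix with one row per requested id.
#' @export
embedding_vectors <- function(set, ids) {
  stopifnot(inherits(set, "embedding_set"))
  missing <- setdiff(ids, rownames(set$vectors))
  if (length(missing))
    fdta_stop(sprintf("no %s embedding (%s) for id '%s'",
                      set$entity_kind, set$dim_tag, missing[1L]),
              "fusedta_lookup_error")
  set$vectors[ids, , drop = FALSE]
}

#' Load an embedding set from a tab-separated file
#'
#' Format: one row per entity, `id<TAB>v1<TAB>...<TAB>vW`, constant width;
#' lines starting with `#` are comments. This is the adapter through which
#' externally precomputed embeddings (e.g. from large pretrained protein
#' models) enter the pipeline.
#'
#' @param path Input file.
#' @param entity_kind,dim_tag Tags for the resulting set.
#' @param strict_width If `TRUE`, warn when the file width differs from
#'   [default_width()] for this kind/tag.
#' @return An [embedding_set()].
#' @export
load_embeddings <- function(path, entity_kind = c("drug", "protein"),
                            dim_tag = c("1D", "2D", "3D"),
                            strict_width = FALSE) {
  entity_kind <- match.arg(entity_kind)
  dim_tag <- match.arg(dim_tag)
  if (!file.exists(path))
    fdta_stop(sprintf("no such file: %s", path), "fusedta_io_error")
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (!length(parts))
    fdta_stop(sprintf("no embedding rows in %s", path), "fusedta_format_error")
  w <- length(parts[[1L]]) - 1L
  if (w < 1L)
    fdta_stop(sprintf("line %d of %s has no vector values", lineno[1L], path),
              "fusedta_format_error")
  ragged <- which(lengths(parts) != w + 1L)
  if (length(ragged))
    fdta_stop(sprintf("ragged row at line %d of %s (expected %d values)",
                      lineno[ragged[1L]], path, w),
              "fusedta_format_error")
  ids <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(ids))
    fdta_stop(sprintf("duplicate id '%s' in %s", ids[duplicated(ids)][1L], path),
              "fusedta_duplicate_error")
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1L]), numeric(w)))
  m <- if (w == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (any(!is.finite(m))) {
    bad <- which(apply(!is.finite(m), 1L, any))[1L]
    fdta_stop(sprintf("non-numeric embedding value at line %d of %s",
                      lineno[bad], path),
              "fusedta_parse_error")
  }
  rownames(m) <- ids
  if (strict_width && w != default_width(entity_kind, dim_tag))
    fdta_warn(sprintf("width %d in %s differs from the default %d for %s %s",
                      w, path, default_width(entity_kind, dim_tag),
                      entity_kind, dim_tag),
              "fusedta_width_warning")
  embedding_set(m, entity_kind, dim_tag)
}

#' Load a protein embedding set (convenience wrapper)
#' @inheritParams load_embeddings
#' @export
load_protein_embeddings <- function(path, dim_tag = c("1D", "2D", "3D"),
                                    strict_width = FALSE) {
  load_embeddings(path, entity_kind = "protein", dim_tag = dim_tag,
                  strict_width = strict_width)
}

#' Write an embedding set to the tab-separated format
#'
#' Values are written at full double precision so a load round-trips exactly.
#'
#' @param set An [embedding_set()].
#' @param path Output path.
#' @export
write_embeddings <- function(set, path) {
  stopifnot(inherits(set, "embedding_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# entity_kind=%s dim_tag=%s width=%d",
                     set$entity_kind, set$dim_tag, set$width), con)
  rows <- apply(set$vectors, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(set$vectors), rows, sep = "\t"), con)
  invisible(path)
}
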