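#' Trinary network mask
#'
#' A network mask marks each connectome edge as positively predictive (+1),
#' negatively predictive (-1), or not predictive (0) of a behavior. It is the
#' unit of CPM models, overlap tests and computational lesioning.
#'
#' @param w Either a `p x p` symmetric integer matrix with entries in
#'   \{-1, 0, 1\} and zero diagonal, or a data frame with columns `i`, `j`
#'   (0-based parcel indices, `i < j`) and `w` (+1/-1).
#' @param p Parcel count; required when `w` is an edge list.
#' @param name Optional mask name.
#' @return An object of class `network_mask` with elements `w` (dense matrix),
#'   `name`, `p`, `n_pos`, `n_neg`.
#' @export
network_mask <- function(w, p = NULL, name = NULL) {
  if (is.data.frame(w)) {
    stopifnot(!is.null(p), all(c("i", "j", "w") %in% names(w)))
    if (nrow(w) && any(w$i >= w$j)) stop("edge list must satisfy i < j")
    if (nrow(w) && (any(w$i < 0) | any(w$j >= p)))
      stop("edge references a parcel outside [0, p)")
    m <- matrix(0L, p, p)
    if (nrow(w)) {
      idx <- cbind(w$i + 1L, w$j + 1L)
      m[idx] <- as.integer(w$w)
      m[idx[, 2:1, drop = FALSE]] <- as.integer(w$w)
    }
    w <- m
  }
  w <- as.matrix(w)
  p <- nrow(w)
  if (ncol(w) != p) stop("mask matrix must be square")
  if (any(w != t(w))) stop("mask matrix must be symmetric")
  if (any(diag(w) != 0)) stop("mask diagonal must be zero")
  if (!all(w %in% c(-1L, 0L, 1L))) stop("mask entries must be in {-1, 0, 1}")
  storage.mode(w) <- "integer"
  v <- ut_vec(w)
  structure(
    list(w = w, name = name, p = p,
         n_pos = sum(v == 1L), n_neg = sum(v == -1L)),
    class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  cat(sprintf("network_mask%s: %d parcels, %d positive / %d negative edges (of %d)\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$p, x$n_pos, x$n_neg, total_edges(x$p)))
  invisible(x)
}

#' Signed upper-triangle vector of a mask
#'
#' @param mask A `network_mask`.
#' @return Integer vector in [edge_table()] order with values -1/0/1.
#' @export
mask_vec <- function(mask) ut_vec(mask$w)

#' Edge list of a network mask
#'
#' @param mask A `network_mask`.
#' @return Data frame with columns `i`, `j` (0-based, `i < j`) and `w`.
#' @export
mask_edges <- function(mask) {
  et <- edge_table(mask$p)
  v <- mask_vec(mask)
  keep <- v != 0L
  data.frame(i = et$i[keep], j = et$j[keep], w = v[keep])
}

#' Read / write masks as long-format TSV
#'
#' Long format has columns `i`, `j`, `w` with 0-based parcel indices, `i < j`.
#'
#' @param path File path.
#' @param p Parcel count (read).
#' @param mask A `network_mask` (write).
#' @param name Optional name for the mask read.
#' @return `read_mask` returns a `network_mask`; `write_mask` the path,
#'   invisibly.
#' @export
read_mask <- function(path, p, name = NULL) {
  df <- utils::read.delim(path, sep = "\t")
  network_mask(df[, c("i", "j", "w")], p = p,
               name = if (is.null(name)) basename(path) else name)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  utils::write.table(mask_edges(mask), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read parcel-to-region labels
#'
#' @param path TSV with columns `parcel_id` (0-based), `region_name`, and
#'   optionally `hemisphere`.
#' @return Data frame of labels covering each parcel once.
#' @export
read_region_labels <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  stopifnot(all(c("parcel_id", "region_name") %in% names(df)))
  if (anyDuplicated(df$parcel_id)) stop("duplicate parcel_id in region labels")
  df
}

# Region name per parcel (1-based position = parcel_id + 1), erroring on gaps.
region_of_parcel <- function(region_labels, p) {
  out <- rep(NA_character_, p)
  out[region_labels$parcel_id + 1L] <- as.character(region_labels$region_name)
  if (anyNA(out)) stop("unlabeled parcel(s): ",
                       paste(which(is.na(out)) - 1L, collapse = ", "))
  out
}
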