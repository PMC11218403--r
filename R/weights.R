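#' Binary contiguity spatial weights
#'
#' Constructs a symmetric binary spatial-weights object from a list of
#' per-area neighbor index sets. Areas are identified by character ids;
#' neighbor sets are stored as integer indices into `ids`.
#'
#' @param neighbors list of integer vectors, one per area, giving the indices
#'   of that area's neighbors (1-based, no self-neighbors).
#' @param ids character vector of area identifiers; defaults to
#'   `as.character(seq_along(neighbors))`.
#' @return An object of class `spatial_weights` with elements `n`, `ids`,
#'   and `neighbors` (sorted integer vectors).
#' @examples
#' w <- spatial_weights(list(2L, c(1L, 3L), 2L))
#' w$neighbors
#' @export
spatial_weights <- function(neighbors, ids = as.character(seq_along(neighbors))) {
  n <- length(neighbors)
  if (length(ids) != n) stop("length(ids) must equal length(neighbors)")
  if (anyDuplicated(ids)) stop("area ids must be unique")
  neighbors <- lapply(neighbors, function(v) sort(unique(as.integer(v))))
  for (i in seq_len(n)) {
    v <- neighbors[[i]]
    if (length(v) && (min(v) < 1L || max(v) > n))
      stop("neighbor index out of range for area ", ids[i])
    if (i %in% v) stop("self-neighbor not allowed: area ", ids[i])
  }
  # symmetry check: j in w_i  <=>  i in w_j
  for (i in seq_len(n)) {
    for (j in neighbors[[i]]) {
      if (!(i %in% neighbors[[j]]))
        stop(sprintf("asymmetric adjacency: %s lists %s but not conversely",
                     ids[i], ids[j]))
    }
  }
  structure(list(n = n, ids = as.character(ids), neighbors = neighbors),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat("Binary contiguity weights:", x$n, "areas,",
      sum(deg) / 2, "edges (symmetric)\n")
  cat("degree range:", min(deg), "-", max(deg), "\n")
  invisible(x)
}

#' Dense adjacency matrix of a weights object
#'
#' @param w a `spatial_weights` object.
#' @return n x n binary (0/1) matrix, zero diagonal, symmetric.
#' @export
weights_matrix <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  W <- matrix(0, w$n, w$n, dimnames = list(w$ids, w$ids))
  for (i in seq_len(w$n)) W[i, w$neighbors[[i]]] <- 1
  W
}

#' Read a GAL spatial-weights file
#'
#' Parses the plain-text GAL exchange dialect: a header line containing the
#' number of areas (optionally preceded by a leading "0"), then for each
#' area a line `id degree` followed by a line of its neighbor ids.
#'
#' @param path path to a GAL file.
#' @return a `spatial_weights` object. Errors on asymmetric adjacency or
#'   unknown ids.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GAL file: ", path)
  hdr <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  # headers are either "n" or "0 n <shp> <id>"
  n <- if (length(hdr) == 1L) as.integer(hdr[1]) else as.integer(hdr[2])
  if (is.na(n) || n < 1L) stop("cannot parse GAL header: ", lines[[1]])
  ids <- character(n)
  nbr_ids <- vector("list", n)
  pos <- 2L
  for (k in seq_len(n)) {
    if (pos > length(lines)) stop("GAL file truncated at record ", k)
    rec <- strsplit(trimws(lines[[pos]]), "\\s+")[[1]]
    if (length(rec) != 2L) stop("malformed GAL record line: ", lines[[pos]])
    ids[k] <- rec[1]
    deg <- as.integer(rec[2])
    if (is.na(deg) || deg < 0L) stop("bad degree in GAL record: ", lines[[pos]])
    if (deg > 0L) {
      pos <- pos + 1L
      if (pos > length(lines)) stop("GAL file truncated after record ", ids[k])
      nb <- strsplit(trimws(lines[[pos]]), "\\s+")[[1]]
      if (length(nb) != deg)
        stop("GAL record for ", ids[k], " declares ", deg,
             " neighbors but lists ", length(nb))
      nbr_ids[[k]] <- nb
    } else {
      nbr_ids[[k]] <- character(0)
    }
    pos <- pos + 1L
  }
  if (anyDuplicated(ids)) stop("duplicate area ids in GAL file")
  idx <- stats::setNames(seq_len(n), ids)
  neighbors <- lapply(nbr_ids, function(nb) {
    unknown <- setdiff(nb, ids)
    if (length(unknown)) stop("unknown neighbor id in GAL file: ", unknown[1])
    unname(idx[nb])
  })
  # spatial_weights() enforces symmetry and no-self invariants
  spatial_weights(neighbors, ids)
}

#' Write a GAL spatial-weights file
#'
#' @param w a `spatial_weights` object.
#' @param path output file path.
#' @return `path`, invisibly. `read_gal(write_gal(w, path))` reproduces `w`.
#' @export
write_gal <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(w$n), con)
  for (i in seq_len(w$n)) {
    nb <- w$neighbors[[i]]
    writeLines(paste(w$ids[i], length(nb)), con)
    if (length(nb)) writeLines(paste(w$ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' Regular-lattice contiguity weights
#'
#' Rook contiguity joins cells sharing an edge; queen additionally joins
#' cells sharing only a corner. Cells are ordered row-major; ids are
#' `"r<row>c<col>"`.
#'
#' @param rows,cols lattice dimensions (each >= 2).
#' @param contiguity `"rook"` or `"queen"`.
#' @return a `spatial_weights` object over `rows * cols` areas.
#' @examples
#' w <- lattice_weights(3, 3, "rook")
#' lengths(w$neighbors)  # corners 2, edges 3, center 4
#' @export
lattice_weights <- function(rows, cols, contiguity = c("rook", "queen")) {
  contiguity <- match.arg(contiguity)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2L || cols < 2L) stop("rows and cols must each be >= 2")
  offs <- if (contiguity == "rook") {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5L, , drop = FALSE]
  }
  cell <- function(r, c) (r - 1L) * cols + c
  neighbors <- vector("list", rows * cols)
  ids <- character(rows * cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      rr <- r + offs[, 1]; cc <- c + offs[, 2]
      ok <- rr >= 1L & rr <= rows & cc >= 1L & cc <= cols
      neighbors[[cell(r, c)]] <- cell(rr[ok], cc[ok])
      ids[cell(r, c)] <- sprintf("r%dc%d", r, c)
    }
  }
  spatial_weights(neighbors, ids)
}

#' Connected components of a weights graph
#'
#' @param w a `spatial_weights` object.
#' @return integer vector of component labels (1-based).
#' @keywords internal
#' @export
weights_components <- function(w) {
  comp <- integer(w$n)
  cur <- 0L
  for (s in seq_len(w$n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      for (j in w$neighbors[[i]]) {
        if (comp[j] == 0L) { comp[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  comp
}

#' Restrict weights to a subset of areas
#'
#' Keeps only edges with both endpoints inside `keep`; used to compute
#' within-region decompositions.
#'
#' @param w a `spatial_weights` object.
#' @param keep integer indices of areas to retain.
#' @return a `spatial_weights` object over `length(keep)` areas.
#' @keywords internal
#' @export
subset_weights <- function(w, keep) {
  keep <- as.integer(keep)
  new_idx <- integer(w$n)
  new_idx[keep] <- seq_along(keep)
  neighbors <- lapply(w$neighbors[keep], function(nb) {
    nb <- nb[nb %in% keep]
    new_idx[nb]
  })
  spatial_weights(neighbors, w$ids[keep])
}
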