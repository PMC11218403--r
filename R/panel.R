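#' Balanced areal panel
#'
#' Container for a balanced N-area x T-year panel: a positive response
#' (resource counts or a density index), population and land area for
#' density construction, a region (province) partition, and K covariates.
#'
#' @param response N x T matrix of non-negative response values (rows =
#'   areas in `area_ids` order, columns = `years` order).
#' @param population N x T matrix of positive population counts (persons).
#' @param land_area length-N vector of positive areas (km^2).
#' @param region_of length-N vector of region labels, one per area.
#' @param covariates N x T x K array of covariate values (may be K = 0);
#'   `dimnames(covariates)[[3]]` carries unique covariate names.
#' @param area_ids,years identifiers; defaults taken from `response`
#'   dimnames or sequence.
#' @param covariate_group named character vector mapping each covariate name
#'   to `"socioeconomic"` or `"environmental"`; optional when K = 0.
#' @return An object of class `area_panel`.
#' @export
area_panel <- function(response, population, land_area, region_of,
                       covariates = NULL,
                       area_ids = rownames(response),
                       years = colnames(response),
                       covariate_group = NULL) {
  response <- as.matrix(response)
  population <- as.matrix(population)
  N <- nrow(response); T <- ncol(response)
  if (is.null(area_ids)) area_ids <- as.character(seq_len(N))
  if (is.null(years)) years <- seq_len(T)
  years <- as.integer(years)
  if (any(is.na(years))) stop("years must be integers")
  if (!identical(dim(population), dim(response)))
    stop("population and response dimensions differ")
  if (length(land_area) != N) stop("land_area must have one entry per area")
  if (length(region_of) != N) stop("region_of must have one entry per area")
  if (anyDuplicated(area_ids)) stop("area ids must be unique")
  if (anyDuplicated(years)) stop("years must be unique")
  if (any(!is.finite(response)) || any(response < 0))
    stop("response must be finite and >= 0")
  if (any(!is.finite(population)) || any(population <= 0))
    stop("population must be finite and > 0")
  if (any(!is.finite(land_area)) || any(land_area <= 0))
    stop("land_area must be finite and > 0")
  if (is.null(covariates)) covariates <- array(0, dim = c(N, T, 0))
  if (!identical(dim(covariates)[1:2], c(N, T)))
    stop("covariates array must be N x T x K")
  K <- dim(covariates)[3]
  cov_names <- dimnames(covariates)[[3]]
  if (K > 0) {
    if (is.null(cov_names)) cov_names <- paste0("X", seq_len(K))
    if (anyDuplicated(cov_names)) stop("covariate names must be unique")
    dimnames(covariates)[[3]] <- cov_names
    if (!is.null(covariate_group)) {
      missing_grp <- setdiff(cov_names, names(covariate_group))
      if (length(missing_grp))
        stop("no group assigned for covariate: ", missing_grp[1])
      bad <- setdiff(unique(covariate_group), c("socioeconomic", "environmental"))
      if (length(bad)) stop("unknown covariate group: ", bad[1])
      covariate_group <- covariate_group[cov_names]
    }
  }
  rownames(response) <- rownames(population) <- area_ids
  colnames(response) <- colnames(population) <- years
  dimnames(covariates)[[1]] <- area_ids
  dimnames(covariates)[[2]] <- as.character(years)
  structure(list(
    area_ids = as.character(area_ids),
    years = years,
    region_of = stats::setNames(as.character(region_of), area_ids),
    response = response,
    population = population,
    land_area = stats::setNames(as.numeric(land_area), area_ids),
    covariates = covariates,
    covariate_group = covariate_group
  ), class = "area_panel")
}

#' @export
print.area_panel <- function(x, ...) {
  cat("Balanced areal panel:", length(x$area_ids), "areas x",
      length(x$years), "years,", dim(x$covariates)[3], "covariates\n")
  cat("years:", min(x$years), "-", max(x$years),
      "| regions:", length(unique(x$region_of)), "\n")
  invisible(x)
}

#' @export
dim.area_panel <- function(x) {
  c(N = length(x$area_ids), T = length(x$years), K = dim(x$covariates)[3])
}

#' Read a long-format panel CSV
#'
#' Expects one row per (area, year). Default column names are `area_id`,
#' `region_id`, `year`, `beds`, `population`, `land_area`; every remaining
#' column is treated as a covariate. The panel must be balanced: a missing
#' (area, year) cell is an error naming the cell.
#'
#' @param path CSV file path.
#' @param schema named list overriding default column names (keys
#'   `area_id`, `region_id`, `year`, `response`, `population`, `land_area`).
#' @param covariate_group optional named vector mapping covariate columns to
#'   `"socioeconomic"`/`"environmental"`.
#' @return an `area_panel` with areas and years sorted canonically
#'   (areas lexicographic, years ascending).
#' @export
read_panel_csv <- function(path, schema = list(), covariate_group = NULL) {
  defaults <- list(area_id = "area_id", region_id = "region_id",
                   year = "year", response = "beds",
                   population = "population", land_area = "land_area")
  schema <- utils::modifyList(defaults, as.list(schema))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(schema, use.names = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  panel_from_long(df, schema, covariate_group)
}

# assemble an area_panel from a long data.frame (shared by CSV reader and tests)
panel_from_long <- function(df, schema, covariate_group = NULL) {
  aid <- as.character(df[[schema$area_id]])
  yr <- as.integer(df[[schema$year]])
  area_ids <- sort(unique(aid))
  years <- sort(unique(yr))
  N <- length(area_ids); T <- length(years)
  key <- paste(aid, yr, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate panel cell: ", gsub("\r", " / ", d))
  }
  full <- as.vector(outer(area_ids, years, paste, sep = "\r"))
  absent <- setdiff(full, key)
  if (length(absent))
    stop("unbalanced panel: missing cell for area/year ",
         gsub("\r", " / ", absent[1]))
  row_of <- match(full, key)  # row-major over (area, year) grid
  grid <- df[row_of, , drop = FALSE]
  shape <- function(col) matrix(as.numeric(grid[[col]]), N, T,
                                dimnames = list(area_ids, years))
  response <- shape(schema$response)
  population <- shape(schema$population)
  land_mat <- shape(schema$land_area)
  if (any(abs(land_mat - land_mat[, 1]) > 1e-9 * pmax(1, abs(land_mat[, 1]))))
    stop("land_area varies over years for some area; it must be constant")
  reg_mat <- matrix(as.character(grid[[schema$region_id]]), N, T)
  if (any(reg_mat != reg_mat[, 1]))
    stop("region assignment varies over years for some area")
  cov_cols <- setdiff(names(df), unlist(schema, use.names = FALSE))
  K <- length(cov_cols)
  covariates <- array(NA_real_, dim = c(N, T, K),
                      dimnames = list(area_ids, years, cov_cols))
  for (k in seq_len(K)) covariates[, , k] <- shape(cov_cols[k])
  area_panel(response, population, land_mat[, 1], reg_mat[, 1],
             covariates = covariates, area_ids = area_ids, years = years,
             covariate_group = covariate_group)
}

#' Write a panel to long-format CSV
#'
#' Inverse of [read_panel_csv()]: numeric fields survive a write/read
#' round trip exactly (values are printed with full precision).
#'
#' @param panel an `area_panel`.
#' @param path output CSV path.
#' @param schema column-name overrides as in [read_panel_csv()].
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path, schema = list()) {
  defaults <- list(area_id = "area_id", region_id = "region_id",
                   year = "year", response = "beds",
                   population = "population", land_area = "land_area")
  schema <- utils::modifyList(defaults, as.list(schema))
  N <- length(panel$area_ids); T <- length(panel$years)
  K <- dim(panel$covariates)[3]
  df <- data.frame(
    a = rep(panel$area_ids, times = T),
    r = rep(unname(panel$region_of), times = T),
    y = rep(panel$years, each = N),
    b = as.vector(panel$response),
    p = as.vector(panel$population),
    l = rep(unname(panel$land_area), times = T),
    stringsAsFactors = FALSE)
  names(df) <- c(schema$area_id, schema$region_id, schema$year,
                 schema$response, schema$population, schema$land_area)
  for (k in seq_len(K)) {
    df[[dimnames(panel$covariates)[[3]][k]]] <- as.vector(panel$covariates[, , k])
  }
  # format full precision so read.csv reproduces doubles bit-exactly
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Health resource density index (HRDI)
#'
#' Geometric mean of the resource rate per 1000 population and the resource
#' density per km^2: `sqrt((beds / (population/1000)) * (beds / land_area))`.
#' Scale-consistent: multiplying `beds` by c multiplies the index by c.
#'
#' @param beds non-negative resource counts (vector/matrix).
#' @param population positive population in persons (same shape).
#' @param land_area positive area in km^2 (recycled over columns if `beds`
#'   is a matrix and `land_area` a vector).
#' @return HRDI values, same shape as `beds`.
#' @examples
#' compute_hrdi(100, 50000, 200)  # 1
#' @export
compute_hrdi <- function(beds, population, land_area) {
  if (any(!is.finite(population)) || any(population <= 0))
    stop("population must be > 0")
  if (any(!is.finite(land_area)) || any(land_area <= 0))
    stop("land_area must be > 0")
  if (any(beds < 0)) stop("beds must be >= 0")
  if (is.matrix(beds) && !is.matrix(land_area))
    land_area <- matrix(land_area, nrow(beds), ncol(beds))
  sqrt((beds / (population / 1000)) * (beds / land_area))
}

#' Attach an HRDI response to a panel
#'
#' Replaces the panel's response (assumed to be raw resource counts) with
#' the HRDI computed cell-wise from population and land area.
#'
#' @param panel an `area_panel` whose response holds raw counts.
#' @return the panel with `response` replaced by HRDI values and an
#'   attribute `response_unit = "hrdi"`.
#' @export
panel_with_hrdi <- function(panel) {
  stopifnot(inherits(panel, "area_panel"))
  panel$response <- compute_hrdi(panel$response, panel$population,
                                 panel$land_area)
  dimnames(panel$response) <- list(panel$area_ids, panel$years)
  attr(panel, "response_unit") <- "hrdi"
  panel
}

#' Iterative VIF screening of a covariate table
#'
#' Computes each column's variance inflation factor VIF_k = 1/(1 - R^2_k),
#' with R^2_k from the OLS regression of column k on all other columns plus
#' an intercept. While any VIF exceeds `threshold`, the column with the
#' largest VIF is dropped (ties broken by input column order: the
#' later-listed column goes) and VIFs are recomputed.
#'
#' @param x numeric matrix or data.frame (rows = observations, columns =
#'   candidate covariates, K >= 2). Constant columns are an error.
#' @param threshold retain only columns whose final VIF is at or below this
#'   value (default 5).
#' @param standardize center/scale columns before screening (does not change
#'   VIFs; provided for symmetry with downstream modelling). Default FALSE.
#' @return list with `retained` (column names), `vif` (final VIFs of the
#'   retained columns), `dropped` (named numeric vector: VIF each column had
#'   when dropped, in drop order), and `history` (VIF table per iteration).
#' @export
vif_screen <- function(x, threshold = 5, standardize = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  if (ncol(x) < 2) stop("VIF screening needs at least 2 columns")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  if (standardize) x <- scale(x)
  vif_of <- function(m) {
    vapply(seq_len(ncol(m)), function(k) {
      if (ncol(m) == 1) return(1)
      fit <- stats::lm.fit(cbind(1, m[, -k, drop = FALSE]), m[, k])
      rss <- sum(fit$residuals^2)
      tss <- sum((m[, k] - mean(m[, k]))^2)
      r2 <- 1 - rss / tss
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  cur <- x
  dropped <- numeric(0)
  history <- list()
  repeat {
    v <- stats::setNames(vif_of(cur), colnames(cur))
    history[[length(history) + 1L]] <- v
    if (ncol(cur) <= 1 || max(v) <= threshold) break
    # later-listed column goes on (numerical) ties
    worst <- max(v)
    tied <- if (is.finite(worst)) which(v >= worst * (1 - 1e-9)) else
      which(!is.finite(v))
    k <- max(tied)
    dropped[colnames(cur)[k]] <- v[k]
    cur <- cur[, -k, drop = FALSE]
  }
  list(retained = colnames(cur),
       vif = stats::setNames(v, colnames(cur)),
       dropped = dropped,
       history = history)
}
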