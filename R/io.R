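#' Construct and validate a multi-species occupancy history
#'
#' An occupancy history is a 3-dimensional `patch x year x species` array with
#' entries in `{0, 1, NA}`. Years must be contiguous integers, and wherever
#' both the butterfly (M) and parasitoid (C) entries are observed, parasitoid
#' presence implies host presence.
#'
#' @param values numeric array (patch x year x species) of 0/1/NA entries, or a
#'   patch x year matrix for a single species.
#' @param patch_id,years,species dimension labels; taken from `dimnames(values)`
#'   when `NULL`.
#' @return the validated array, with complete dimnames, of class
#'   `"occupancy_history"`.
#' @export
occupancy_history <- function(values, patch_id = NULL, years = NULL,
                              species = NULL) {
  if (length(dim(values)) == 2L) {
    values <- array(values, dim = c(dim(values), 1L),
                    dimnames = c(dimnames(values), list(NULL)))
  }
  if (length(dim(values)) != 3L)
    stop("`values` must be a patch x year x species array")
  dn <- dimnames(values) %||% vector("list", 3L)
  patch_id <- as.character(patch_id %||% dn[[1]] %||% seq_len(dim(values)[1]))
  years <- as.integer(years %||% dn[[2]] %||% seq_len(dim(values)[2]))
  species <- as.character(species %||% dn[[3]] %||% SPECIES[seq_len(dim(values)[3])])
  if (length(years) > 1L && !all(diff(years) == 1L))
    stop("years must be strictly increasing and contiguous")
  if (!all(values %in% c(0, 1) | is.na(values)))
    stop("occupancy entries must be 0, 1 or NA")
  dimnames(values) <- list(patch_id, years, species)
  if (all(c("M", "C") %in% species)) {
    m <- values[, , "M", drop = FALSE]
    cc <- values[, , "C", drop = FALSE]
    bad <- !is.na(m) & !is.na(cc) & cc == 1 & m == 0
    if (any(bad))
      stop("invalid occupancy history: parasitoid present without host in ",
           sum(bad), " patch-year(s)")
  }
  class(values) <- c("occupancy_history", "array")
  values
}

#' @export
print.occupancy_history <- function(x, ...) {
  d <- dim(x)
  cat("<occupancy_history> ", d[1], " patches x ", d[2], " years (",
      dimnames(x)[[2]][1], "-", dimnames(x)[[2]][d[2]], ") x ",
      d[3], " species [", paste(dimnames(x)[[3]], collapse = ", "), "]\n",
      sep = "")
  cat("  NA entries: ", sum(is.na(x)), "\n", sep = "")
  invisible(x)
}

history_years <- function(history) as.integer(dimnames(history)[[2]])

#' Read a patch attribute table
#'
#' Expected columns: `patch_id`, `x_km`, `y_km`, `area_m2`, `road`,
#' `vs_score`, plus one `cover_pl_<year>` column per survey year giving the
#' host-plant (\emph{P. lanceolata}) cover in m2 (NA allowed). Coordinates are
#' in km; loaders of projected metre coordinates should divide by 1000 before
#' calling the pipeline.
#'
#' @param path CSV file path.
#' @return a validated `data.frame`.
#' @export
read_patches <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  validate_patches(x)
}

validate_patches <- function(x) {
  need <- c("patch_id", "x_km", "y_km", "area_m2", "road", "vs_score")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("patch table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$patch_id)) stop("duplicated patch_id values")
  if (!all(is.finite(x$x_km)) || !all(is.finite(x$y_km)))
    stop("patch coordinates must be finite")
  if (any(!is.finite(x$area_m2) | x$area_m2 <= 0))
    stop("patch areas must be positive")
  if (!all(x$vs_score %in% 0:3)) stop("vs_score must be an integer in 0..3")
  if (!all(x$road %in% 0:1)) stop("road must be a 0/1 flag")
  cov <- cover_columns(x)
  if (length(cov) && any(x[, cov] < 0, na.rm = TRUE))
    stop("cover values must be >= 0")
  x$patch_id <- as.character(x$patch_id)
  x
}

cover_columns <- function(patches) grep("^cover_pl_\\d+$", names(patches), value = TRUE)

cover_years <- function(patches) {
  as.integer(sub("^cover_pl_", "", cover_columns(patches)))
}

# patch x year matrix of P. lanceolata cover, NA cells imputed with the
# patch mean over recorded years (all-NA patches raise)
cover_matrix <- function(patches, impute = TRUE) {
  cols <- cover_columns(patches)
  if (!length(cols)) stop("patch table has no cover_pl_<year> columns")
  m <- as.matrix(patches[, cols, drop = FALSE])
  dimnames(m) <- list(patches$patch_id, cover_years(patches))
  if (impute) {
    mu <- rowMeans(m, na.rm = TRUE)
    if (anyNA(mu) || any(is.nan(mu)))
      stop("patch(es) with no recorded cover in any year: ",
           paste(patches$patch_id[is.nan(mu)], collapse = ", "))
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- mu[idx[, 1]]
  }
  m
}

#' Mean host-plant cover per patch
#'
#' Average of the yearly \emph{P. lanceolata} cover columns, NA years dropped.
#'
#' @param patches patch table (see [read_patches()]).
#' @return named numeric vector (m2).
#' @export
patch_mean_cover <- function(patches) {
  m <- cover_matrix(patches, impute = FALSE)
  mu <- rowMeans(m, na.rm = TRUE)
  if (any(is.nan(mu)))
    stop("patch(es) with no recorded cover in any year: ",
         paste(patches$patch_id[is.nan(mu)], collapse = ", "))
  setNames(mu, patches$patch_id)
}

#' Read a long-format occupancy table
#'
#' Columns `patch_id,year,species,present` with `species` in `{M, C, P}` and
#' `present` in `{0, 1, NA}`.
#'
#' @param path CSV file path.
#' @return an [occupancy_history()] array.
#' @export
read_occupancy <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(patch_id = "character"))
  need <- c("patch_id", "year", "species", "present")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("occupancy table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(x$species), SPECIES)
  if (length(bad)) stop("unknown species label(s): ", paste(bad, collapse = ", "))
  patches <- unique(x$patch_id)
  years <- sort(unique(as.integer(x$year)))
  species <- SPECIES[SPECIES %in% x$species]
  arr <- array(NA_real_, dim = c(length(patches), length(years), length(species)),
               dimnames = list(patches, years, species))
  arr[cbind(match(x$patch_id, patches), match(x$year, years),
            match(x$species, species))] <- x$present
  occupancy_history(arr)
}

#' Write an occupancy history to long-format CSV
#'
#' @param history an [occupancy_history()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(history, path) {
  dn <- dimnames(history)
  out <- expand.grid(patch_id = dn[[1]], year = as.integer(dn[[2]]),
                     species = dn[[3]], KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$present <- as.vector(unclass(history))
  out <- out[order(out$patch_id, out$year, match(out$species, SPECIES)), ]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a monthly precipitation table
#'
#' Columns `year,may_mm,june_mm,july_mm,august_mm` (totals in mm).
#'
#' @param path CSV file path.
#' @return a `data.frame` keyed by year.
#' @export
read_precipitation <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "may_mm", "june_mm", "july_mm", "august_mm")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("precipitation table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(x[, need[-1]] <= 0, na.rm = TRUE))
    stop("precipitation totals must be positive (log scale is used downstream)")
  x
}

#' @rdname read_patches
#' @param patches patch table to write.
#' @param path output CSV path.
#' @export
write_patches <- function(patches, path) {
  fixed <- c("patch_id", "x_km", "y_km", "area_m2", "road", "vs_score")
  patches <- patches[, c(fixed, cover_columns(patches))]
  write.csv(patches, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_precipitation
#' @param precip precipitation table to write.
#' @export
write_precipitation <- function(precip, path) {
  precip <- precip[, c("year", "may_mm", "june_mm", "july_mm", "august_mm")]
  write.csv(precip, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
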