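#' Pairwise patch distances and the dispersal kernel
#'
#' Distances are Euclidean on the km coordinates (centroid to centroid).
#' `dispersal_kernel()` returns `exp(-alpha * d_ij)` with a zeroed diagonal so
#' that downstream connectivity sums always exclude the focal patch, even when
#' two distinct patches share coordinates.
#'
#' @param patches patch table (see [read_patches()]).
#' @param alpha kernel scale in 1/km; `1/alpha` is the mean dispersal
#'   distance. Default `1` (mean dispersal distance 1 km for all species).
#' @return a symmetric `n x n` matrix.
#' @export
patch_distances <- function(patches) {
  d <- as.matrix(dist(cbind(patches$x_km, patches$y_km)))
  dimnames(d) <- list(patches$patch_id, patches$patch_id)
  d
}

#' @rdname patch_distances
#' @export
dispersal_kernel <- function(patches, alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number (km^-1)")
  K <- exp(-alpha * patch_distances(patches))
  diag(K) <- 0
  K
}

#' Species-specific patch connectivity
#'
#' Connectivity of patch i in year t for species Y is
#' \deqn{S_{it}^Y = \sum_{j \ne i} e^{-\alpha d_{ij}} A_j O_{j,t-1}^Y}
#' where \eqn{A_j} is patch area (m2) and \eqn{O_{j,t-1}^Y} the focal species'
#' occupancy in year t-1. Unsurveyed (NA) neighbours contribute 0.
#'
#' @param history an [occupancy_history()].
#' @param patches patch table aligned with `history` (same patches, same order).
#' @param species species label, one of `"M"`, `"C"`, `"P"`.
#' @param year the year t for which connectivity is computed; `year - 1` must
#'   be present in the history.
#' @param alpha kernel scale (1/km).
#' @param kernel optional precomputed [dispersal_kernel()] matrix (re-used
#'   across years for speed).
#' @return named numeric vector of S values, one per patch.
#' @export
compute_connectivity <- function(history, patches, species, year, alpha = 1,
                                 kernel = NULL) {
  species <- match.arg(species, dimnames(history)[[3]])
  years <- history_years(history)
  if (!(year - 1L) %in% years)
    stop("year ", year - 1L, " (the predecessor of ", year,
         ") is not in the occupancy history")
  if (!identical(as.character(patches$patch_id), dimnames(history)[[1]]))
    stop("patch table and occupancy history are not aligned")
  K <- kernel %||% dispersal_kernel(patches, alpha)
  occ <- history[, as.character(year - 1L), species]
  occ[is.na(occ)] <- 0
  setNames(drop(K %*% (patches$area_m2 * occ)), patches$patch_id)
}

#' Host-plant connectivity
#'
#' Time-invariant connectivity to the host plant,
#' \deqn{S_i^{PL} = \sum_{j \ne i} e^{-\alpha d_{ij}} \bar A_j^{PL}}
#' with \eqn{\bar A_j^{PL}} the across-year mean \emph{P. lanceolata} cover of
#' patch j (NA years dropped from the average).
#'
#' @inheritParams compute_connectivity
#' @return named numeric vector of `S^PL` values.
#' @export
compute_host_connectivity <- function(patches, alpha = 1, kernel = NULL) {
  K <- kernel %||% dispersal_kernel(patches, alpha)
  mu <- patch_mean_cover(patches)
  setNames(drop(K %*% mu), patches$patch_id)
}

#' Assign colonization and extinction events
#'
#' A colonization is scored at (i, t) when the species is present in year t
#' but absent in year t-1, an extinction when it is absent in t but present in
#' t-1. Denominators count patch-years where the transition was possible
#' (absent at t-1 for colonization, present at t-1 for extinction);
#' transitions touching an NA are excluded from both events and denominators.
#'
#' For the parasitoid (`"C"`) a colonization is only possible into a patch
#' where the butterfly host is present in year t, which admits both
#' colonization of an existing host population and joint arrival with the
#' host; events coinciding with a host transition in the same year are flagged
#' `joint`.
#'
#' @param history an [occupancy_history()].
#' @param species species label present in the history.
#' @return a list of class `"turnover_events"` with elements `colonizations`
#'   and `extinctions` (data frames `patch_id, year, joint`), the possible-event
#'   denominators `n_possible_col` / `n_possible_ext`, and the joint-event
#'   counts `n_joint_col` / `n_joint_ext`.
#' @export
assign_turnover_events <- function(history, species) {
  if (!species %in% dimnames(history)[[3]])
    stop("species '", species, "' is not in the occupancy history")
  years <- history_years(history)
  if (length(years) < 2L) stop("need at least 2 years of data")
  v <- history[, , species, drop = FALSE]
  dim(v) <- dim(history)[1:2]
  host <- NULL
  if (species == "C") {
    if (!"M" %in% dimnames(history)[[3]])
      stop("parasitoid events require the host (M) in the history")
    host <- history[, , "M"]
  }
  ids <- dimnames(history)[[1]]
  col <- ext <- list()
  n_pos_col <- n_pos_ext <- 0L
  for (k in 2:length(years)) {
    prev <- v[, k - 1L]
    cur <- v[, k]
    ok <- !is.na(prev) & !is.na(cur)
    ok_col <- ok
    if (!is.null(host)) ok_col <- ok & !is.na(host[, k]) & host[, k] == 1
    elig_col <- ok_col & prev == 0
    elig_ext <- ok & prev == 1
    n_pos_col <- n_pos_col + sum(elig_col)
    n_pos_ext <- n_pos_ext + sum(elig_ext)
    ev_c <- elig_col & cur == 1
    ev_e <- elig_ext & cur == 0
    joint_c <- joint_e <- rep(FALSE, length(ev_c))
    if (!is.null(host)) {
      hp <- host[, k - 1L]
      hc <- host[, k]
      joint_c <- ev_c & !is.na(hp) & hp == 0 & !is.na(hc) & hc == 1
      joint_e <- ev_e & !is.na(hp) & hp == 1 & !is.na(hc) & hc == 0
    }
    if (any(ev_c))
      col[[length(col) + 1L]] <- data.frame(patch_id = ids[ev_c],
                                            year = years[k],
                                            joint = joint_c[ev_c])
    if (any(ev_e))
      ext[[length(ext) + 1L]] <- data.frame(patch_id = ids[ev_e],
                                            year = years[k],
                                            joint = joint_e[ev_e])
  }
  empty <- data.frame(patch_id = character(), year = integer(), joint = logical())
  col <- if (length(col)) do.call(rbind, col) else empty
  ext <- if (length(ext)) do.call(rbind, ext) else empty
  structure(list(species = species,
                 colonizations = col, extinctions = ext,
                 n_possible_col = n_pos_col, n_possible_ext = n_pos_ext,
                 n_joint_col = sum(col$joint), n_joint_ext = sum(ext$joint)),
            class = "turnover_events")
}

#' @export
print.turnover_events <- function(x, ...) {
  rate <- function(n, d) if (d > 0) sprintf(" (%.1f%%)", 100 * n / d) else ""
  cat("<turnover_events> species ", x$species, "\n",
      "  colonizations: ", nrow(x$colonizations), " / ", x$n_possible_col,
      " possible", rate(nrow(x$colonizations), x$n_possible_col), "\n",
      "  extinctions:   ", nrow(x$extinctions), " / ", x$n_possible_ext,
      " possible", rate(nrow(x$extinctions), x$n_possible_ext), "\n", sep = "")
  if (x$species == "C")
    cat("  joint with host: ", x$n_joint_col, " colonizations, ",
        x$n_joint_ext, " extinctions\n", sep = "")
  invisible(x)
}

#' Encode community patch states
#'
#' Maps presence/absence triples (butterfly M, parasitoid C, mildew P) to the
#' six valid patch-state labels `0, M, MC, MCP, MP, P`. The parasitoid cannot
#' be present without its host, so `c = 1, m = 0` is rejected.
#'
#' @param m,c,p binary presence vectors (recycled to common length).
#' @return character vector of state labels.
#' @seealso [patch_state_flags()] for the inverse mapping.
#' @export
encode_patch_state <- function(m, c, p) {
  n <- max(length(m), length(c), length(p))
  m <- rep_len(m, n); c <- rep_len(c, n); p <- rep_len(p, n)
  if (!all(c(m, c, p) %in% 0:1, na.rm = FALSE) || anyNA(c(m, c, p)))
    stop("state flags must be 0 or 1")
  if (any(c == 1 & m == 0))
    stop("invalid patch state: the parasitoid cannot be present without its host")
  lab <- paste0(ifelse(m == 1, "M", ""), ifelse(c == 1, "C", ""),
                ifelse(p == 1, "P", ""))
  lab[lab == ""] <- "0"
  lab
}

#' @rdname encode_patch_state
#' @param label patch-state label(s).
#' @return for `patch_state_flags()`, a matrix with columns `M`, `C`, `P`.
#' @export
patch_state_flags <- function(label) {
  bad <- setdiff(label, STATE_LEVELS)
  if (length(bad)) stop("unknown patch state(s): ", paste(bad, collapse = ", "))
  out <- cbind(M = as.integer(grepl("M", label)),
               C = as.integer(grepl("C", label)),
               P = as.integer(grepl("P", label)))
  rownames(out) <- label
  out
}

#' @rdname encode_patch_state
#' @export
patch_states <- function() STATE_LEVELS

#' Bin patches into equal-count cover classes
#'
#' Splits a cover gradient into `k` classes of as-near-as-possible equal patch
#' counts (quantile-type bins). Class index increases with cover; ties are
#' broken by the stable original patch order; when `n` is not a multiple of
#' `k` the lower classes receive the extra patches.
#'
#' @param values per-patch (mean) cover values, finite.
#' @param k number of classes; default 15.
#' @return integer class index per patch, in `1..k`.
#' @export
bin_cover_classes <- function(values, k = 15) {
  n <- length(values)
  if (k < 1) stop("`k` must be >= 1")
  if (k > n) stop("`k` (", k, ") exceeds the number of patches (", n, ")")
  if (!all(is.finite(values))) stop("cover values must be finite")
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  cls <- integer(n)
  cls[order(values)] <- rep(seq_len(k), times = sizes)
  cls
}
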