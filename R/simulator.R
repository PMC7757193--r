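#' Closed-loop metacommunity simulation
#'
#' Simulates the three-species patch-occupancy process forward from an initial
#' state. Each year, species-specific connectivity is recomputed from the
#' previous \emph{simulated} occupancy, colonization/extinction rates are
#' evaluated from the rate models, binary states are drawn as Bernoulli
#' variates, and the community constraint (parasitoid requires the butterfly)
#' is applied. Covariates for each simulated year are taken from the supplied
#' tables by calendar year; years outside the tables raise an error rather
#' than extrapolate.
#'
#' Random-effect handling is switchable: patch effects default to matched
#' point predictions (zero for unseen patches), year effects default to fresh
#' `N(0, sigma2_year)` draws per simulated year (observed-year effects are not
#' reused). `"draw"` for both is the fully generative mode used by
#' [generate_history()].
#'
#' @param initial `n x 3` binary matrix (columns `M`, `C`, `P`) giving the
#'   patch states in the year preceding `years[1]`.
#' @param models nested list `models[[species]]$col` / `$ext` of
#'   [rate_model()] or `spom_fit` objects.
#' @param patches,precip patch table and precipitation table.
#' @param years integer vector of consecutive calendar years to simulate.
#' @param alpha dispersal-kernel scale (1/km).
#' @param seed integer seed; fully determines the trajectory.
#' @param ranef_patch,ranef_year random-effect modes: `"estimate"`, `"draw"`
#'   or `"zero"`.
#' @return object of class `"spom_trajectory"`: `states` is a
#'   `(T+1) x patch x species` binary array whose first slice is the initial
#'   condition; `connectivity` logs the recomputed `S` values per simulated
#'   year.
#' @export
simulate_trajectory <- function(initial, models, patches, precip, years,
                                alpha = 1, seed = NULL,
                                ranef_patch = "estimate", ranef_year = "draw") {
  initial <- as.matrix(initial)
  n <- nrow(patches)
  if (nrow(initial) != n || !all(SPECIES %in% colnames(initial)))
    stop("`initial` must be an n x 3 matrix with columns M, C, P")
  initial <- initial[, SPECIES]
  if (anyNA(initial) || !all(initial %in% 0:1))
    stop("initial states must be 0/1 with no NA")
  if (any(initial[, "C"] == 1 & initial[, "M"] == 0))
    stop("invalid initial state: parasitoid present without host")
  if (length(years) < 1L || (length(years) > 1L && !all(diff(years) == 1L)))
    stop("`years` must be >= 1 consecutive calendar years")
  mods <- lapply(SPECIES, function(sp)
    list(col = as_rate_model(models[[sp]]$col),
         ext = as_rate_model(models[[sp]]$ext)))
  names(mods) <- SPECIES
  K <- dispersal_kernel(patches, alpha)
  covm <- cover_matrix(patches)
  host_conn <- compute_host_connectivity(patches, alpha, kernel = K)
  if (!is.null(seed)) set.seed(seed)
  # patch-level offsets are a property of the trajectory: drawn (or matched)
  # once and held fixed over time
  patch_off <- lapply(mods, function(m) lapply(m, function(rm)
    ranef_offset(rm, ranef_patch, patches$patch_id, "patch")))
  states <- array(NA_integer_, dim = c(length(years) + 1L, n, 3),
                  dimnames = list(c(years[1] - 1L, years), patches$patch_id,
                                  SPECIES))
  conn_log <- array(NA_real_, dim = c(length(years), n, 3),
                    dimnames = list(years, patches$patch_id, SPECIES))
  states[1, , ] <- initial
  prev <- initial
  for (k in seq_along(years)) {
    t <- years[k]
    base_cov <- year_covariates(patches, precip, t, covm)
    base_cov$host_conn <- host_conn
    cur <- matrix(0L, n, 3, dimnames = list(patches$patch_id, SPECIES))
    for (sp in SPECIES) {
      cv <- base_cov
      conn <- drop(K %*% (patches$area_m2 * prev[, sp]))
      conn_log[k, , sp] <- conn
      cv$conn <- conn
      yoff_c <- ranef_offset(mods[[sp]]$col, ranef_year, t, "year")
      yoff_e <- ranef_offset(mods[[sp]]$ext, ranef_year, t, "year")
      cprob <- plogis(rate_linpred(mods[[sp]]$col, cv, prev_states = prev,
                                   patch_offset = patch_off[[sp]]$col,
                                   year_offset = yoff_c))
      eprob <- plogis(rate_linpred(mods[[sp]]$ext, cv, prev_states = prev,
                                   patch_offset = patch_off[[sp]]$ext,
                                   year_offset = yoff_e))
      p <- one_step_probability(prev[, sp], cprob, eprob)
      cur[, sp] <- rbinom(n, 1, p)
    }
    cur[, "C"] <- cur[, "C"] * cur[, "M"]
    states[k + 1L, , ] <- cur
    prev <- cur
  }
  structure(list(states = states, connectivity = conn_log, years = years,
                 seed = seed), class = "spom_trajectory")
}

#' @export
print.spom_trajectory <- function(x, ...) {
  cat("<spom_trajectory> ", dim(x$states)[2], " patches, years ",
      dimnames(x$states)[[1]][1], "-", x$years[length(x$years)], "\n", sep = "")
  invisible(x)
}

#' Replicate ensemble of metacommunity simulations
#'
#' Runs `R` independent trajectories whose seeds are derived deterministically
#' from the master seed, and summarises per-year occupied counts per species
#' and patch-state counts with medians and 95% prediction intervals.
#'
#' @inheritParams simulate_trajectory
#' @param R number of replicate trajectories (default 100).
#' @param seed master seed.
#' @return object of class `"spom_ensemble"` with `trajectories` (list of
#'   [simulate_trajectory()] results), `summary_species` and `summary_states`
#'   (data frames `year, species/state, median, lo95, hi95` of counts).
#' @export
simulate_ensemble <- function(initial, models, patches, precip, years,
                              R = 100, alpha = 1, seed = 1,
                              ranef_patch = "estimate", ranef_year = "draw") {
  if (R < 1) stop("R must be >= 1")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, R)
  trajectories <- lapply(rep_seeds, function(s)
    simulate_trajectory(initial, models, patches, precip, years, alpha = alpha,
                        seed = s, ranef_patch = ranef_patch,
                        ranef_year = ranef_year))
  all_years <- c(years[1] - 1L, years)
  occ <- vapply(trajectories, function(tr)
    apply(tr$states, c(1, 3), sum), matrix(0, length(all_years), 3))
  qs <- function(v) c(median(v), quantile(v, c(0.025, 0.975), names = FALSE))
  sp_rows <- expand.grid(year = all_years, species = SPECIES,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sp_stats <- t(mapply(function(y, s) qs(occ[match(y, all_years), s, ]),
                       sp_rows$year, sp_rows$species))
  summary_species <- data.frame(sp_rows, median = sp_stats[, 1],
                                lo95 = sp_stats[, 2], hi95 = sp_stats[, 3],
                                row.names = NULL)
  st <- vapply(trajectories, state_distribution,
               matrix(0L, length(all_years), length(STATE_LEVELS)))
  st_rows <- expand.grid(year = all_years, state = STATE_LEVELS,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  st_stats <- t(mapply(function(y, s)
    qs(st[match(y, all_years), match(s, STATE_LEVELS), ]),
    st_rows$year, st_rows$state))
  summary_states <- data.frame(st_rows, median = st_stats[, 1],
                               lo95 = st_stats[, 2], hi95 = st_stats[, 3],
                               row.names = NULL)
  structure(list(trajectories = trajectories, R = R, seed = seed,
                 years = all_years,
                 summary_species = summary_species,
                 summary_states = summary_states),
            class = "spom_ensemble")
}

#' @export
print.spom_ensemble <- function(x, ...) {
  cat("<spom_ensemble> R = ", x$R, " replicates, years ", x$years[1], "-",
      x$years[length(x$years)], "\n", sep = "")
  invisible(x)
}

#' Per-year distribution of community patch states
#'
#' Counts patches in each of the six states `0, M, MC, MCP, MP, P` per year.
#' Counts sum to the number of (state-complete) patches each year; an invalid
#' state (parasitoid without host) raises an error.
#'
#' @param x a `spom_trajectory`, a `spom_ensemble`, or a `(years x patch x
#'   species)` binary array such as an [occupancy_history()] (NA-containing
#'   patch-years are dropped from the counts).
#' @return for trajectories/arrays, a `year x state` count matrix; for
#'   ensembles, a `year x state x replicate` array.
#' @export
state_distribution <- function(x) UseMethod("state_distribution")

#' @export
state_distribution.spom_trajectory <- function(x) {
  state_distribution_array(x$states)
}

#' @export
state_distribution.spom_ensemble <- function(x) {
  out <- vapply(x$trajectories, state_distribution,
                matrix(0L, length(x$years), length(STATE_LEVELS)))
  dimnames(out) <- list(x$years, STATE_LEVELS, NULL)
  out
}

#' @export
state_distribution.default <- function(x) {
  if (inherits(x, "occupancy_history")) {
    x <- aperm(unclass(x), c(2, 1, 3))  # patch x year x sp -> year x patch x sp
  }
  state_distribution_array(x)
}

state_distribution_array <- function(states) {
  if (length(dim(states)) != 3L || dim(states)[3] < 3L)
    stop("need a year x patch x species array with species M, C, P")
  yrs <- dimnames(states)[[1]] %||% seq_len(dim(states)[1])
  out <- matrix(0L, length(yrs), length(STATE_LEVELS),
                dimnames = list(yrs, STATE_LEVELS))
  for (k in seq_along(yrs)) {
    m <- states[k, , "M"]; cc <- states[k, , "C"]; p <- states[k, , "P"]
    full <- !is.na(m) & !is.na(cc) & !is.na(p)
    if (!any(full)) next
    lab <- encode_patch_state(m[full], cc[full], p[full])
    tab <- table(factor(lab, levels = STATE_LEVELS))
    out[k, ] <- as.integer(tab)
  }
  out
}
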