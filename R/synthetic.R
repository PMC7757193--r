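#' Generate a synthetic patch network
#'
#' Emulates the structure of a fragmented dry-meadow landscape: uniform patch
#' coordinates over the extent, log-normal patch areas, zero-inflated
#' log-normal yearly host-plant cover with a shared year effect (so landscape
#' cover fluctuates between years), an ordinal \emph{V. spicata} score
#' concentrated in the western third of the extent, and ~30% road-bordering
#' patches.
#'
#' @param n_patches number of patches (>= 2).
#' @param years survey years for which cover columns are generated.
#' @param extent_km landscape extent `c(width, height)` in km; default
#'   `c(50, 70)`.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return a patch table as returned by [read_patches()].
#' @export
generate_landscape <- function(n_patches, years = 2000:2018,
                               extent_km = c(50, 70), seed = 1) {
  if (n_patches < 2) stop("need at least 2 patches")
  if (any(extent_km <= 0)) stop("extent must be positive")
  set.seed(seed)
  id <- sprintf("p%04d", seq_len(n_patches))
  x <- runif(n_patches, 0, extent_km[1])
  y <- runif(n_patches, 0, extent_km[2])
  area <- rlnorm(n_patches, meanlog = 5, sdlog = 1)
  # host-plant cover: ~10% of patches never carry the plant; the rest get a
  # patch-level log-normal base level, a shared yearly multiplier and
  # patch-year noise
  zero <- runif(n_patches) < 0.10
  base <- rlnorm(n_patches, meanlog = log(5), sdlog = 1)
  base[zero] <- 0
  year_mult <- exp(rnorm(length(years), 0, 0.3))
  cov <- outer(base, year_mult) * matrix(rlnorm(n_patches * length(years), 0, 0.4),
                                         n_patches)
  cov <- round(cov, 3)
  # V. spicata gradient: abundant only in the western third
  west <- x < extent_km[1] / 3
  pvs <- ifelse(west, 0.7, 0.15)
  vs <- ifelse(runif(n_patches) < pvs, sample(1:3, n_patches, replace = TRUE), 0L)
  road <- rbinom(n_patches, 1, 0.3)
  out <- data.frame(patch_id = id, x_km = x, y_km = y, area_m2 = area,
                    road = road, vs_score = as.integer(vs))
  covdf <- as.data.frame(cov)
  names(covdf) <- paste0("cover_pl_", years)
  validate_patches(cbind(out, covdf))
}

#' Generate a synthetic monthly precipitation table
#'
#' Log-normal May-August monthly totals with a shared year-level component,
#' so wet and dry summers are correlated across months.
#'
#' @param years calendar years (>= 2); an integer `n` is shorthand for
#'   `2000:(2000 + n - 1)`.
#' @param seed integer seed.
#' @return precipitation table as returned by [read_precipitation()].
#' @export
generate_covariates <- function(years = 2000:2018, seed = 1) {
  if (length(years) == 1L) years <- 2000:(2000 + years - 1L)
  if (length(years) < 2L) stop("need at least 2 years")
  set.seed(seed)
  z <- rnorm(length(years), 0, 0.25)
  mk <- function() round(exp(log(50) + z + rnorm(length(years), 0, 0.35)), 1)
  data.frame(year = as.integer(years), may_mm = mk(), june_mm = mk(),
             july_mm = mk(), august_mm = mk())
}

#' Ground-truth rate parameters for the synthetic metacommunity
#'
#' Intercepts and slopes on the standard covariate scales (see
#' [build_transition_table()]), with crossed patch/year random-effect
#' variances, chosen so that on the default landscape the realised event
#' rates fall in realistic ranges for this kind of system (colonizations a
#' few percent of possible events, extinctions roughly half). Slope
#' magnitudes follow the ordering seen in field systems: host-plant cover and
#' connectivity dominate, roads and single-month precipitation are weaker.
#'
#' @param alpha dispersal-kernel scale shared by all species (1/km).
#' @return a truth-parameter list: `alpha` plus per-species `col`/`ext`
#'   [rate_model()] objects.
#' @export
default_truth_params <- function(alpha = 1) {
  list(
    alpha = alpha,
    M = list(
      col = rate_model(c("(Intercept)" = -6.4, log_cover = 0.7, vs = 0.5,
                         conn = 0.018, road = 0.35, logp_may = 0.2),
                       sigma2_patch = 0.25, sigma2_year = 0.25),
      ext = rate_model(c("(Intercept)" = 1.05, log_cover = -0.66, vs = -0.34,
                         conn = -0.012, road = -0.32, logp_july = 0.45),
                       sigma2_patch = 0.25, sigma2_year = 0.25)),
    C = list(
      col = rate_model(c("(Intercept)" = -4.9, log_cover = 0.20, vs = 0.66,
                         conn = 0.010, road = 0.20),
                       sigma2_patch = 0.30, sigma2_year = 0.20),
      ext = rate_model(c("(Intercept)" = 1.9, log_cover = -0.35, vs = -0.49,
                         conn = -0.010, road = 0.25),
                       sigma2_patch = 0.30, sigma2_year = 0.20)),
    P = list(
      col = rate_model(c("(Intercept)" = -4.3, log_cover = 0.75, conn = 0.010,
                         host_conn = 0.060, road = 0.70, logp_august = -0.40),
                       sigma2_patch = 0.40, sigma2_year = 0.30),
      ext = rate_model(c("(Intercept)" = 2.7, log_cover = -0.40, conn = -0.010,
                         host_conn = -0.040, road = -0.13, logp_july = -0.20),
                       sigma2_patch = 0.40, sigma2_year = 0.30)))
}

#' @rdname default_truth_params
#' @param truth a truth-parameter list.
#' @param species focal species whose rate gains the contrast.
#' @param rate `"col"` or `"ext"`.
#' @param contrasts named log-odds contrasts added when the named
#'   co-occurring species was present in the previous year, e.g.
#'   `c(P = 0.7)`.
#' @export
add_interaction <- function(truth, species, rate = c("col", "ext"), contrasts) {
  rate <- match.arg(rate)
  species <- match.arg(species, SPECIES)
  truth[[species]][[rate]]$interact <-
    c(truth[[species]][[rate]]$interact, contrasts)
  truth
}

#' Generate a ground-truth occupancy history
#'
#' Seeds an initial community (butterfly in ~18% of patches, mildew in ~10%,
#' parasitoid in ~25% of the initial butterfly patches) and propagates it with
#' [simulate_trajectory()] under the supplied truth parameters, drawing both
#' patch and year random effects fresh. Optionally injects unsurveyed (NA)
#' patch-years to exercise missing-data paths.
#'
#' @param patches patch table (typically [generate_landscape()]).
#' @param precip precipitation table covering all years after the first.
#' @param truth truth parameters ([default_truth_params()]).
#' @param years calendar years of the history; the first year holds the
#'   seeded initial community.
#' @param seed integer seed.
#' @param init_occ initial occupancy fractions `c(M=, C=, P=)`; `C` is the
#'   fraction \emph{of butterfly patches} seeded with the parasitoid.
#' @param prob_na per patch-year probability of marking all three species
#'   unsurveyed (default 0).
#' @return an [occupancy_history()].
#' @export
generate_history <- function(patches, precip, truth, years = 2000:2018,
                             seed = 1, init_occ = c(M = 0.18, C = 0.25, P = 0.10),
                             prob_na = 0) {
  n <- nrow(patches)
  set.seed(seed)
  m0 <- rbinom(n, 1, init_occ[["M"]])
  c0 <- rbinom(n, 1, init_occ[["C"]]) * m0
  p0 <- rbinom(n, 1, init_occ[["P"]])
  initial <- cbind(M = m0, C = c0, P = p0)
  # degenerate dynamics warning: all-certain rates wipe the system in year 1
  pr <- vapply(SPECIES, function(sp)
    plogis(truth[[sp]]$col$coef[["(Intercept)"]]), numeric(1))
  if (all(pr < 1e-12)) warning("truth implies near-certain extinction")
  traj <- simulate_trajectory(initial, truth, patches, precip, years[-1],
                              alpha = truth$alpha %||% 1,
                              seed = sample.int(.Machine$integer.max, 1),
                              ranef_patch = "draw", ranef_year = "draw")
  vals <- aperm(traj$states, c(2, 1, 3))  # year x patch x sp -> patch x year x sp
  storage.mode(vals) <- "double"
  if (prob_na > 0) {
    na_mask <- matrix(runif(n * length(years)) < prob_na, n)
    for (sp in SPECIES) vals[, , sp][na_mask] <- NA_real_
  }
  occupancy_history(vals, patch_id = patches$patch_id, years = years)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates a landscape, precipitation table and ground-truth occupancy
#' history for one of three profiles and writes `patches.csv`,
#' `occupancy.csv`, `precipitation.csv` and `truth.json` to `dir`. Profiles:
#' `tiny` (20 patches x 5 yr on a proportionally dense 10 x 14 km extent;
#' runs the full pipeline in seconds), `default` (500 patches x 19 yr,
#' 50 x 70 km), `power` (2000 patches x 15 yr with a +0.7 log-odds
#' mildew-on-butterfly colonization contrast).
#'
#' @param profile `"tiny"`, `"default"` or `"power"`.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated objects and file paths.
#' @export
make_fixture <- function(profile = c("tiny", "default", "power"), seed = 1,
                         dir = tempfile("fixture")) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
                tiny = list(n = 20, years = 2000:2004, extent = c(10, 14),
                            init = c(M = 0.45, C = 0.5, P = 0.35)),
                default = list(n = 500, years = 2000:2018, extent = c(50, 70),
                               init = c(M = 0.18, C = 0.25, P = 0.10)),
                power = list(n = 2000, years = 2000:2014, extent = c(50, 70),
                             init = c(M = 0.18, C = 0.25, P = 0.10)))
  truth <- default_truth_params()
  if (profile == "power") truth <- add_interaction(truth, "M", "col", c(P = 0.7))
  patches <- generate_landscape(cfg$n, years = cfg$years,
                                extent_km = cfg$extent, seed = seed)
  precip <- generate_covariates(cfg$years, seed = seed + 1L)
  # the tiny profile seeds a denser initial community so that all six
  # colonization/extinction models remain identifiable on 20 x 5 data
  history <- generate_history(patches, precip, truth, years = cfg$years,
                              seed = seed + 2L, init_occ = cfg$init)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(patches = file.path(dir, "patches.csv"),
                occupancy = file.path(dir, "occupancy.csv"),
                precipitation = file.path(dir, "precipitation.csv"),
                truth = file.path(dir, "truth.json"))
  write_patches(patches, paths$patches)
  write_occupancy(history, paths$occupancy)
  write_precipitation(precip, paths$precipitation)
  jsonlite::write_json(truth_to_list(truth), paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(profile = profile, patches = patches, precip = precip,
                 history = history, truth = truth, paths = paths, dir = dir))
}

truth_to_list <- function(truth) {
  out <- list(alpha = truth$alpha)
  for (sp in SPECIES) out[[sp]] <- lapply(truth[[sp]], function(rm)
    list(coef = as.list(rm$coef), sigma2_patch = rm$sigma2_patch,
         sigma2_year = rm$sigma2_year,
         interact = if (!is.null(rm$interact)) as.list(rm$interact)))
  out
}
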