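#' One-step-ahead occurrence probability
#'
#' \deqn{p = o_{t-1}(1 - e) + (1 - o_{t-1})\,c}
#' the probability that a patch is occupied in year t given its previous
#' state, a colonization rate `c` and an extinction rate `e`. Arguments are
#' recycled; `o_prev` may itself be a probability (used by the closed-loop
#' simulator in expectation checks).
#'
#' @param o_prev previous occupancy (0/1, or a probability).
#' @param col colonization rate(s) in `[0, 1]`.
#' @param ext extinction rate(s) in `[0, 1]`.
#' @return occurrence probability, same length as the longest argument.
#' @export
one_step_probability <- function(o_prev, col, ext) {
  if (any(col < 0 | col > 1, na.rm = TRUE) || any(ext < 0 | ext > 1, na.rm = TRUE))
    stop("rates must lie in [0, 1]")
  if (any(o_prev < 0 | o_prev > 1, na.rm = TRUE))
    stop("`o_prev` must lie in [0, 1]")
  o_prev * (1 - ext) + (1 - o_prev) * col
}

#' Rate models: the common currency of forecasting and simulation
#'
#' A rate model is the minimal description of one colonization or extinction
#' process: named coefficients on the standard covariate scales (see
#' [build_transition_table()]), the two random-effect variances, and
#' optionally a sampling covariance matrix, random-effect point predictions
#' and additive patch-state interaction contrasts (`interact`, named by the
#' co-occurring species whose previous-year presence shifts the log odds).
#' `as_rate_model()` converts a fitted [fit_occupancy_glmm()] object.
#'
#' @param coef named coefficients, `"(Intercept)"` included.
#' @param sigma2_patch,sigma2_year random-intercept variances (log-odds2).
#' @param vcov optional fixed-effect covariance matrix.
#' @param interact optional named vector of log-odds contrasts, e.g.
#'   `c(P = 0.7)` adds 0.7 to the linear predictor where mildew was present
#'   in the previous year.
#' @param ranef_patch,ranef_year optional named random-effect point
#'   predictions.
#' @return an object of class `"rate_model"`.
#' @export
rate_model <- function(coef, sigma2_patch = 0, sigma2_year = 0, vcov = NULL,
                       interact = NULL, ranef_patch = NULL, ranef_year = NULL) {
  if (!"(Intercept)" %in% names(coef)) stop("`coef` needs an \"(Intercept)\"")
  structure(list(coef = coef, sigma2_patch = sigma2_patch,
                 sigma2_year = sigma2_year, vcov = vcov, interact = interact,
                 ranef_patch = ranef_patch, ranef_year = ranef_year),
            class = "rate_model")
}

#' @rdname rate_model
#' @param x object to convert.
#' @export
as_rate_model <- function(x) UseMethod("as_rate_model")

#' @export
as_rate_model.rate_model <- function(x) x

#' @export
as_rate_model.spom_fit <- function(x) {
  rate_model(coef = x$beta, sigma2_patch = x$sigma2_patch,
             sigma2_year = x$sigma2_year, vcov = x$vcov,
             ranef_patch = x$ranef_patch, ranef_year = x$ranef_year)
}

# linear predictor of a rate model over a covariate data.frame; `beta`
# overrides the point coefficients (bootstrap draws). prev_states is the
# n x 3 previous-year presence matrix used for interaction contrasts.
rate_linpred <- function(rm, covars, beta = NULL, prev_states = NULL,
                         patch_offset = 0, year_offset = 0) {
  beta <- beta %||% rm$coef
  eta <- rep(beta[["(Intercept)"]], nrow(covars))
  for (nm in setdiff(names(beta), "(Intercept)")) {
    if (is.null(covars[[nm]]))
      stop("covariate '", nm, "' required by the rate model is missing")
    eta <- eta + beta[[nm]] * covars[[nm]]
  }
  if (!is.null(rm$interact)) {
    if (is.null(prev_states)) stop("interaction contrasts need `prev_states`")
    for (sp in names(rm$interact))
      eta <- eta + rm$interact[[sp]] * prev_states[, sp]
  }
  eta + patch_offset + year_offset
}

# standard covariate frame for one year: species-specific `conn` is filled
# in by the caller
year_covariates <- function(patches, precip, year, covm = NULL) {
  covm <- covm %||% cover_matrix(patches)
  yc <- as.character(year)
  if (!yc %in% colnames(covm))
    stop("no cover data for year ", year, " (no extrapolation)")
  i <- match(year, precip$year)
  if (is.na(i)) stop("no precipitation data for year ", year,
                     " (no extrapolation)")
  data.frame(log_cover = log1p(covm[, yc]),
             vs = as.numeric(patches$vs_score),
             road = as.numeric(patches$road),
             logp_may = log(precip$may_mm[i]),
             logp_june = log(precip$june_mm[i]),
             logp_july = log(precip$july_mm[i]),
             logp_august = log(precip$august_mm[i]))
}

# random-effect offsets for prediction: matched point estimates, fresh draws
# from N(0, sigma2), or zero
ranef_offset <- function(rm, mode, ids, which = c("patch", "year")) {
  which <- match.arg(which)
  s2 <- if (which == "patch") rm$sigma2_patch else rm$sigma2_year
  est <- if (which == "patch") rm$ranef_patch else rm$ranef_year
  switch(mode,
         zero = rep(0, length(ids)),
         draw = rnorm(length(ids), 0, sqrt(s2)),
         estimate = {
           off <- rep(0, length(ids))
           if (!is.null(est)) {
             hit <- match(as.character(ids), names(est))
             off[!is.na(hit)] <- est[hit[!is.na(hit)]]
           }
           off
         },
         stop("unknown random-effect mode '", mode, "'"))
}

# clip negative eigenvalues of a covariance matrix, warning when repair is
# more than numerical noise
nearest_psd <- function(V, tol = 1e-8) {
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values))) {
    warning("covariance matrix is not positive semi-definite; ",
            "repaired by eigenvalue clipping")
    V <- e$vectors %*% diag(pmax(e$values, 0), nrow(V)) %*% t(e$vectors)
    V <- (V + t(V)) / 2
  }
  V
}

#' Parametric-bootstrap one-step occupancy forecasts
#'
#' For each of `B` bootstrap draws, the fixed effects of all six
#' colonization/extinction models are sampled from their multivariate-normal
#' sampling distributions, per-patch rates are recomputed for every observed
#' yearly transition, the one-step occurrence probability is formed from the
#' observed previous-year state, and binary presences are drawn as Bernoulli
#' variates. The community constraint is applied to every draw (parasitoid
#' masked by the drawn butterfly state). Random-effect point predictions are
#' held at their estimates (`use_ranef = TRUE`) or zeroed.
#'
#' @param fits nested list `fits[[species]]$col` / `$ext` of `spom_fit` or
#'   [rate_model()] objects for species `M`, `C`, `P`.
#' @param history observed [occupancy_history()] providing previous-year
#'   states and connectivity.
#' @param patches,precip aligned patch table and precipitation table.
#' @param B number of bootstrap draws (default 1000).
#' @param seed integer seed; fully determines the ensemble.
#' @param alpha dispersal-kernel scale (1/km).
#' @param use_ranef use matched random-effect point predictions in the linear
#'   predictors.
#' @return object of class `"forecast_ensemble"`: `draws` is a
#'   `B x patch x year x species` binary array over the transition years;
#'   `p_hat` the plug-in (point-estimate) occurrence probabilities
#'   (`patch x year x species`); plus `years`, `patches`, `B`, `seed`.
#' @export
bootstrap_predictions <- function(fits, history, patches, precip, B = 1000,
                                  seed = 1, alpha = 1, use_ranef = TRUE) {
  if (B < 1) stop("B must be >= 1")
  mods <- lapply(SPECIES, function(sp)
    list(col = as_rate_model(fits[[sp]]$col), ext = as_rate_model(fits[[sp]]$ext)))
  names(mods) <- SPECIES
  years <- history_years(history)
  trans <- years[-1]
  n <- nrow(patches)
  K <- dispersal_kernel(patches, alpha)
  covm <- cover_matrix(patches)
  host_conn <- compute_host_connectivity(patches, alpha, kernel = K)
  remode <- if (use_ranef) "estimate" else "zero"
  set.seed(seed)
  betas <- lapply(mods, function(m) lapply(m, function(rm) {
    if (is.null(rm$vcov)) {
      matrix(rep(rm$coef, each = B), nrow = B,
             dimnames = list(NULL, names(rm$coef)))
    } else {
      draws <- MASS::mvrnorm(B, mu = rm$coef, Sigma = nearest_psd(rm$vcov))
      if (B == 1) draws <- matrix(draws, nrow = 1,
                                  dimnames = list(NULL, names(rm$coef)))
      draws
    }
  }))
  draws <- array(NA_integer_, dim = c(B, n, length(trans), 3),
                 dimnames = list(NULL, patches$patch_id, trans, SPECIES))
  p_hat <- array(NA_real_, dim = c(n, length(trans), 3),
                 dimnames = list(patches$patch_id, trans, SPECIES))
  for (k in seq_along(trans)) {
    t <- trans[k]
    base_cov <- year_covariates(patches, precip, t, covm)
    base_cov$host_conn <- host_conn
    m_prev <- history[, as.character(t - 1L), "M"]
    for (sp in SPECIES) {
      cv <- base_cov
      cv$conn <- compute_connectivity(history, patches, sp, t, kernel = K)
      o_prev <- history[, as.character(t - 1L), sp]
      off <- lapply(mods[[sp]], function(rm)
        ranef_offset(rm, remode, patches$patch_id, "patch") +
          ranef_offset(rm, remode, t, "year"))
      # n x B rate matrices from the sampled coefficients
      eta_c <- rate_eta_matrix(mods[[sp]]$col, cv, betas[[sp]]$col) + off$col
      eta_e <- rate_eta_matrix(mods[[sp]]$ext, cv, betas[[sp]]$ext) + off$ext
      cmat <- plogis(eta_c)
      emat <- plogis(eta_e)
      p <- o_prev * (1 - emat) + (1 - o_prev) * cmat
      p_hat[, k, sp] <- one_step_probability(
        o_prev,
        plogis(rate_linpred(mods[[sp]]$col, cv) + off$col),
        plogis(rate_linpred(mods[[sp]]$ext, cv) + off$ext))
      ok <- !is.na(p)
      d <- matrix(NA_integer_, n, B)
      d[ok] <- rbinom(sum(ok), 1, p[ok])
      draws[, , k, sp] <- t(d)
    }
    # community constraint: parasitoid masked by the drawn butterfly state
    draws[, , k, "C"] <- draws[, , k, "C"] * draws[, , k, "M"]
  }
  structure(list(draws = draws, p_hat = p_hat, years = trans,
                 patches = patches, B = B, seed = seed),
            class = "forecast_ensemble")
}

# n x B linear-predictor matrix for B coefficient draws
rate_eta_matrix <- function(rm, covars, beta_draws) {
  nm <- colnames(beta_draws)
  X <- matrix(1, nrow(covars), 1)
  for (j in setdiff(nm, "(Intercept)")) {
    if (is.null(covars[[j]]))
      stop("covariate '", j, "' required by the rate model is missing")
    X <- cbind(X, covars[[j]])
  }
  X %*% t(beta_draws[, c("(Intercept)", setdiff(nm, "(Intercept)")), drop = FALSE])
}

#' @export
print.forecast_ensemble <- function(x, ...) {
  cat("<forecast_ensemble> B = ", x$B, " draws, ",
      dim(x$draws)[2], " patches, years ", x$years[1], "-",
      x$years[length(x$years)], "\n", sep = "")
  invisible(x)
}

#' Apply the community assembly constraint
#'
#' Enforces host dependence on per-draw patch states: the parasitoid is absent
#' wherever the drawn butterfly state is absent (a butterfly extinction takes
#' the parasitoid with it). Where the butterfly newly colonizes and
#' `c_col_prob`/`m_prev` are supplied, parasitoid presence is re-sampled as a
#' Bernoulli draw with the estimated parasitoid colonization probability for
#' the focal patch; otherwise the supplied (already rate-based) parasitoid
#' draw is kept.
#'
#' @param m_new,c_new,p_new binary draws for butterfly, parasitoid, mildew
#'   (vectors or arrays of identical shape).
#' @param c_col_prob optional parasitoid colonization probabilities.
#' @param m_prev optional previous-year butterfly states (needed with
#'   `c_col_prob`).
#' @param seed optional seed for the re-sampling step.
#' @return list with constrained `M`, `C`, `P` (same shape as the inputs).
#' @export
assemble_community <- function(m_new, c_new, p_new, c_col_prob = NULL,
                               m_prev = NULL, seed = NULL) {
  if (!is.null(c_col_prob)) {
    if (is.null(m_prev)) stop("`c_col_prob` requires `m_prev`")
    if (any(c_col_prob < 0 | c_col_prob > 1, na.rm = TRUE))
      stop("colonization probabilities must lie in [0, 1]")
    if (!is.null(seed)) set.seed(seed)
    newly <- which(!is.na(m_new) & m_new == 1 & !is.na(m_prev) & m_prev == 0)
    if (length(newly))
      c_new[newly] <- rbinom(length(newly), 1,
                             rep_len(c_col_prob, length(m_new))[newly])
  }
  list(M = m_new, C = c_new * m_new, P = p_new)
}

#' Summarise a forecast ensemble
#'
#' Medians and 95% percentile intervals (2.5/97.5) of occupied fractions
#' across bootstrap draws, grouped by year or by equal-count host-plant cover
#' class (cover-class summaries are first averaged across years within each
#' draw). `what = "state"` summarises the shares of the six community patch
#' states instead of single-species occupancy.
#'
#' @param ensemble a [bootstrap_predictions()] result.
#' @param by `"year"` or `"cover_class"`.
#' @param what `"species"` or `"state"`.
#' @param k number of cover classes (default 15).
#' @return data.frame with columns `group`, `species_or_state`, `median`,
#'   `lo95`, `hi95`.
#' @export
summarize_forecast <- function(ensemble, by = c("year", "cover_class"),
                               what = c("species", "state"), k = 15) {
  by <- match.arg(by)
  what <- match.arg(what)
  d <- ensemble$draws
  B <- dim(d)[1]; n <- dim(d)[2]; Tn <- dim(d)[3]
  labels <- if (what == "species") SPECIES else STATE_LEVELS
  # per-draw, per-year fraction of patches in each category
  frac <- array(NA_real_, dim = c(B, Tn, length(labels)),
                dimnames = list(NULL, ensemble$years, labels))
  if (what == "species") {
    for (sp in SPECIES)
      frac[, , sp] <- apply(d[, , , sp, drop = FALSE], c(1, 3), mean, na.rm = TRUE)
  } else {
    code <- d[, , , "M", drop = FALSE] * 4 + d[, , , "C", drop = FALSE] * 2 +
      d[, , , "P", drop = FALSE]
    dim(code) <- dim(d)[1:3]
    state_code <- c("0" = 0, "M" = 4, "MC" = 6, "MCP" = 7, "MP" = 5, "P" = 1)
    for (s in labels)
      frac[, , s] <- apply(code == state_code[[s]], c(1, 3), mean, na.rm = TRUE)
  }
  qs <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    c(median(v), quantile(v, c(0.025, 0.975), names = FALSE))
  }
  if (by == "year") {
    rows <- expand.grid(group = ensemble$years, species_or_state = labels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    stats <- t(mapply(function(y, s) qs(frac[, as.character(y), s]),
                      rows$group, rows$species_or_state))
  } else {
    cls <- bin_cover_classes(patch_mean_cover(ensemble$patches), k)
    rows <- expand.grid(group = seq_len(k), species_or_state = labels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    state_code <- c("0" = 0, "M" = 4, "MC" = 6, "MCP" = 7, "MP" = 5, "P" = 1)
    stats <- t(mapply(function(g, s) {
      idx <- which(cls == g)
      if (!length(idx)) {
        warning("empty cover class ", g)
        return(c(NA_real_, NA_real_, NA_real_))
      }
      sub <- d[, idx, , , drop = FALSE]
      if (what == "species") {
        per_draw <- apply(sub[, , , s, drop = FALSE], 1, mean, na.rm = TRUE)
      } else {
        code <- sub[, , , "M", drop = FALSE] * 4 + sub[, , , "C", drop = FALSE] * 2 +
          sub[, , , "P", drop = FALSE]
        per_draw <- apply(code == state_code[[s]], 1, mean, na.rm = TRUE)
      }
      qs(per_draw)
    }, rows$group, rows$species_or_state))
  }
  data.frame(group = rows$group, species_or_state = rows$species_or_state,
             median = stats[, 1], lo95 = stats[, 2], hi95 = stats[, 3],
             row.names = NULL)
}
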