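#' Default environmental covariate sets
#'
#' Butterfly (M) and parasitoid (C) rates are modelled on log host-plant
#' cover, the \emph{V. spicata} ordinal score, species-specific connectivity
#' and the road flag; the mildew (P) drops the \emph{V. spicata} term and adds
#' host-plant connectivity. Monthly precipitation terms (`logp_may` ...
#' `logp_august`) are selected separately, see [select_weather_model()].
#'
#' @param species species label.
#' @return character vector of covariate names.
#' @export
covariate_terms <- function(species) {
  switch(match.arg(species, SPECIES),
         M = c("log_cover", "vs", "conn", "road"),
         C = c("log_cover", "vs", "conn", "road"),
         P = c("log_cover", "conn", "host_conn", "road"))
}

month_term <- function(month) {
  if (!length(month)) return(character(0))
  paste0("logp_", month)
}
MONTHS <- c("may", "june", "july", "august")

#' Assemble a colonization or extinction transition table
#'
#' One row per eligible patch-year transition (t-1 to t). Colonization rows
#' require absence at t-1, extinction rows presence at t-1; for the parasitoid,
#' colonization additionally requires host presence in year t, and extinction
#' rows are restricted to transitions where the host persists (host-loss-driven
#' parasitoid extinctions are deterministic under the community constraint and
#' are modelled there, not here). Transitions touching an NA are dropped.
#'
#' Covariate transforms: `log_cover = log(1 + cover)` with NA cover years
#' imputed by the patch mean; `vs` the ordinal 0-3 score entered as numeric;
#' `conn` the species-specific connectivity of year t; `host_conn` the
#' time-invariant host-plant connectivity (mildew only); `road` the 0/1 flag;
#' `logp_<month>` the log monthly precipitation (mm) of year t. `state_prev`
#' carries the community patch state at t-1 (NA when any species is
#' unsurveyed then).
#'
#' @param history an [occupancy_history()] containing all three species.
#' @param patches aligned patch table.
#' @param precip precipitation table covering all transition years.
#' @param species focal species label.
#' @param response `"colonization"` or `"extinction"`.
#' @param alpha dispersal-kernel scale (1/km).
#' @param kernel optional precomputed kernel matrix.
#' @return a `data.frame` with columns `patch_id`, `year`, `outcome` (1 =
#'   event), the covariates above, and `state_prev`.
#' @export
build_transition_table <- function(history, patches, precip, species,
                                   response = c("colonization", "extinction"),
                                   alpha = 1, kernel = NULL) {
  response <- match.arg(response)
  species <- match.arg(species, SPECIES)
  years <- history_years(history)
  if (length(years) < 2L) stop("need at least 2 years of data")
  trans_years <- years[-1]
  if (!all(trans_years %in% precip$year))
    stop("precipitation table does not cover transition year(s): ",
         paste(setdiff(trans_years, precip$year), collapse = ", "))
  K <- kernel %||% dispersal_kernel(patches, alpha)
  covm <- cover_matrix(patches)
  if (!all(as.character(trans_years) %in% colnames(covm)))
    stop("cover columns missing for transition year(s)")
  host_conn <- if (species == "P") compute_host_connectivity(patches, alpha, kernel = K)
  v <- history[, , species]
  m <- history[, , "M"]
  cc <- history[, , "C"]
  p <- history[, , "P"]
  rows <- vector("list", length(trans_years))
  for (k in seq_along(trans_years)) {
    t <- trans_years[k]
    tc <- as.character(t)
    tp <- as.character(t - 1L)
    prev <- v[, tp]; cur <- v[, tc]
    ok <- !is.na(prev) & !is.na(cur)
    if (response == "colonization") {
      elig <- ok & prev == 0
      if (species == "C") elig <- elig & !is.na(m[, tc]) & m[, tc] == 1
      outcome <- cur == 1
    } else {
      elig <- ok & prev == 1
      if (species == "C") elig <- elig & !is.na(m[, tc]) & m[, tc] == 1
      outcome <- cur == 0
    }
    if (!any(elig)) next
    conn <- compute_connectivity(history, patches, species, t, kernel = K)
    st <- rep(NA_character_, nrow(patches))
    full <- !is.na(m[, tp]) & !is.na(cc[, tp]) & !is.na(p[, tp])
    st[full] <- encode_patch_state(m[full, tp], cc[full, tp], p[full, tp])
    pr <- precip[match(t, precip$year), ]
    df <- data.frame(patch_id = patches$patch_id[elig], year = t,
                     outcome = as.integer(outcome[elig]),
                     log_cover = log1p(covm[elig, tc]),
                     vs = as.numeric(patches$vs_score[elig]),
                     conn = conn[elig],
                     road = as.numeric(patches$road[elig]),
                     logp_may = log(pr$may_mm), logp_june = log(pr$june_mm),
                     logp_july = log(pr$july_mm), logp_august = log(pr$august_mm),
                     state_prev = st[elig], row.names = NULL)
    df$host_conn <- if (species == "P") host_conn[elig] else NA_real_
    rows[[k]] <- df
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    # no eligible transitions at all (e.g. species absent throughout)
    out <- data.frame(patch_id = character(), year = integer(),
                      outcome = integer(), log_cover = numeric(),
                      vs = numeric(), conn = numeric(), road = numeric(),
                      logp_may = numeric(), logp_june = numeric(),
                      logp_july = numeric(), logp_august = numeric(),
                      state_prev = character(), host_conn = numeric())
  } else {
    out <- do.call(rbind, rows)
  }
  attr(out, "species") <- species
  attr(out, "response") <- response
  out
}

#' Fit a binomial colonization/extinction GLMM
#'
#' Logit model for the per-transition event probability with crossed random
#' intercepts for patch and year, fitted by Laplace-approximated maximum
#' likelihood (`lme4::glmer`). If any fixed effect exceeds
#' `ridge_threshold` in absolute value (quasi-complete separation, which
#' rare-event data can produce), the fixed effects are re-estimated with a
#' weak ridge penalty (precision `1e-4`) at the fitted random-effect
#' variances, with a warning.
#'
#' @param data transition table from [build_transition_table()].
#' @param terms character vector of fixed-effect terms (columns of `data`).
#' @param ridge_threshold absolute coefficient size that triggers the ridge
#'   fallback.
#' @return an object of class `"spom_fit"`: a list with elements `beta`
#'   (named fixed effects, intercept first), `vcov`, `sigma2_patch`,
#'   `sigma2_year`, `loglik`, `aic`, `n`, `terms`, `X` (fixed-effect design
#'   matrix), `ranef_patch`, `ranef_year`, `data` (rows used) and the
#'   underlying `merMod` in `model`.
#' @export
fit_occupancy_glmm <- function(data, terms, ridge_threshold = 15) {
  need <- c("outcome", "patch_id", "year", terms)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  sp <- attr(data, "species")
  resp <- attr(data, "response")
  keep <- complete.cases(data[, need])
  data <- data[keep, , drop = FALSE]
  data$patch_f <- factor(data$patch_id)
  data$year_f <- factor(data$year)
  if (nlevels(data$patch_f) < 2L || nlevels(data$year_f) < 2L)
    stop("need >= 2 levels for each random factor (patch, year)")
  if (var(data$outcome) == 0) {
    # all events or no events: the unpenalised MLE diverges.  Return a
    # half-count-corrected intercept-only fit so that tiny data sets keep the
    # pipeline total; callers are warned.
    warning("response is constant; returning a half-count-corrected ",
            "intercept-only fit")
    return(degenerate_fit(data, terms))
  }
  form <- reformulate(c(if (length(terms)) terms else "1",
                        "(1 | patch_f)", "(1 | year_f)"),
                      response = "outcome")
  # standardise numeric covariates for the optimizer; estimates and their
  # covariance are transformed back to the original scales afterwards
  fdata <- data
  scl <- list()
  for (tm in terms) {
    x <- fdata[[tm]]
    if (is.numeric(x) && (s <- stats::sd(x)) > 0) {
      scl[[tm]] <- c(m = mean(x), s = s)
      fdata[[tm]] <- (x - mean(x)) / s
    }
  }
  mod <- lme4::glmer(form, data = fdata, family = binomial(),
                     control = lme4::glmerControl(
                       optimizer = "bobyqa",
                       optCtrl = list(maxfun = 1e5),
                       calc.derivs = FALSE,
                       check.conv.singular = "ignore"))
  if (!is.null(mod@optinfo$conv$opt) && mod@optinfo$conv$opt != 0)
    stop("GLMM failed to converge (optimizer code ", mod@optinfo$conv$opt,
         ", gradient norm ",
         format(max(abs(mod@optinfo$derivs$gradient %||% NA))), ")")
  beta <- lme4::fixef(mod)
  V <- as.matrix(vcov(mod))
  if (length(scl)) {
    # exact back-transform: eta = b0' + sum b_j' (x_j - m_j)/s_j
    Tm <- diag(length(beta))
    dimnames(Tm) <- list(names(beta), names(beta))
    for (tm in names(scl)) {
      if (!tm %in% names(beta)) next
      Tm[tm, tm] <- 1 / scl[[tm]][["s"]]
      Tm["(Intercept)", tm] <- -scl[[tm]][["m"]] / scl[[tm]][["s"]]
    }
    beta <- drop(Tm %*% beta)
    names(beta) <- colnames(Tm)
    V <- Tm %*% V %*% t(Tm)
    dimnames(V) <- dimnames(Tm)
  }
  vc <- lme4::VarCorr(mod)
  s2p <- as.numeric(vc$patch_f)
  s2y <- as.numeric(vc$year_f)
  X <- stats::model.matrix(reformulate(if (length(terms)) terms else "1"),
                           data = data)
  # lme4 drops rank-deficient columns; keep the design aligned with beta
  X <- X[, names(beta), drop = FALSE]
  separated <- any(abs(beta) > ridge_threshold)
  if (separated) {
    warning("possible separation (|beta| > ", ridge_threshold,
            "); fixed effects re-estimated with a weak ridge penalty")
    rr <- ridge_logistic(X, data$outcome, lambda = 1e-4)
    beta <- setNames(rr$beta, names(beta))
    V <- rr$vcov
    dimnames(V) <- list(names(beta), names(beta))
  }
  re <- lme4::ranef(mod)
  structure(list(
    beta = beta, vcov = V,
    sigma2_patch = s2p, sigma2_year = s2y,
    loglik = as.numeric(logLik(mod)), aic = AIC(mod),
    n = nrow(data), terms = terms, X = X,
    ranef_patch = setNames(re$patch_f[[1]], rownames(re$patch_f)),
    ranef_year = setNames(re$year_f[[1]], rownames(re$year_f)),
    species = sp, response = resp,
    separated = separated,
    data = data, model = mod), class = "spom_fit")
}

#' @export
print.spom_fit <- function(x, digits = 3, ...) {
  cat("<spom_fit>", x$response %||% "binomial logit GLMM",
      if (!is.null(x$species)) paste0("[", x$species, "]"), "\n")
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = x$beta, se = se), digits))
  cat(sprintf("sigma2_patch = %.3f, sigma2_year = %.3f\n",
              x$sigma2_patch, x$sigma2_year))
  cat(sprintf("logLik = %.2f, AIC = %.2f, n = %d\n", x$loglik, x$aic, x$n))
  invisible(x)
}

# constant-response fallback: intercept at the Haldane-Anscombe corrected
# empirical logit, slopes 0, variances 0
degenerate_fit <- function(data, terms) {
  n <- nrow(data)
  k <- sum(data$outcome)
  p <- (k + 0.5) / (n + 1)
  X <- stats::model.matrix(reformulate(if (length(terms)) terms else "1"),
                           data = data)
  beta <- setNames(numeric(ncol(X)), colnames(X))
  beta["(Intercept)"] <- qlogis(p)
  V <- matrix(0, ncol(X), ncol(X), dimnames = list(names(beta), names(beta)))
  V["(Intercept)", "(Intercept)"] <- 1 / ((n + 1) * p * (1 - p))
  ll <- k * log(p) + (n - k) * log(1 - p)
  structure(list(beta = beta, vcov = V, sigma2_patch = 0, sigma2_year = 0,
                 loglik = ll, aic = -2 * ll + 2 * (length(beta) + 2),
                 n = n, terms = terms, X = X,
                 ranef_patch = setNames(numeric(0), character(0)),
                 ranef_year = setNames(numeric(0), character(0)),
                 species = attr(data, "species"),
                 response = attr(data, "response"),
                 separated = FALSE, degenerate = TRUE,
                 data = data, model = NULL), class = "spom_fit")
}

# penalised IRLS for the separation fallback; the intercept is not penalised
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(rep(lambda, p))
  if ("(Intercept)" %in% colnames(X)) pen[1, 1] <- 0
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(g)) < tol) break
  }
  list(beta = beta, vcov = solve(H))
}

#' Exhaustive weather-covariate model selection
#'
#' Fits the base model plus every subset of the supplied monthly precipitation
#' covariates (all \eqn{2^m} subsets; 16 candidates for the four months
#' May-August) and ranks the candidates by AIC, ties broken by fewer
#' parameters and then by lexicographic subset order. Candidates whose fit
#' fails are flagged and excluded from the ranking with a warning.
#'
#' @param data transition table.
#' @param base_terms environmental covariates common to all candidates.
#' @param months months whose `logp_<month>` terms enter the search;
#'   default all four.
#' @param ... passed to [fit_occupancy_glmm()].
#' @return list with `table` (one row per candidate: id, terms, npar, aic,
#'   rank), `fits` (all successful fits) and `best` (the winning
#'   `spom_fit`).
#' @export
select_weather_model <- function(data, base_terms, months = MONTHS, ...) {
  if (length(months)) months <- match.arg(months, MONTHS, several.ok = TRUE)
  m <- length(months)
  ids <- 0:(2^m - 1)
  subset_terms <- lapply(ids, function(id) month_term(months[bitwAnd(id, 2^(seq_len(m) - 1)) > 0]))
  fits <- vector("list", length(ids))
  aic <- npar <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    fit <- tryCatch(fit_occupancy_glmm(data, c(base_terms, subset_terms[[i]]), ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("candidate ", i, " (", paste(subset_terms[[i]], collapse = "+"),
              ") failed: ", conditionMessage(fit))
      next
    }
    fits[[i]] <- fit
    aic[i] <- fit$aic
    npar[i] <- length(fit$beta) + 2  # + two variance components
  }
  if (all(is.na(aic))) stop("all candidate weather models failed")
  ord <- order(aic, npar, ids, na.last = TRUE)
  rank <- integer(length(ids)); rank[ord] <- seq_along(ids)
  rank[is.na(aic)] <- NA_integer_
  tab <- data.frame(
    id = ids + 1L,
    terms = vapply(subset_terms, function(x)
      if (length(x)) paste(x, collapse = "+") else "(none)", character(1)),
    npar = npar, aic = aic, rank = rank)
  list(table = tab[order(tab$rank, na.last = TRUE), ],
       fits = fits, best = fits[[ord[1]]])
}

#' Marginal and conditional r2 for a logit GLMM
#'
#' Link-scale variance decomposition: with \eqn{\sigma^2_f} the variance of
#' the fixed-effect linear predictor over the observations, the marginal r2 is
#' \eqn{\sigma^2_f / (\sigma^2_f + \sigma^2_{patch} + \sigma^2_{year} +
#' \pi^2/3)} and the conditional r2 replaces the numerator by
#' \eqn{\sigma^2_f + \sigma^2_{patch} + \sigma^2_{year}}; \eqn{\pi^2/3} is
#' the logistic residual variance.
#'
#' @param fit a `spom_fit`.
#' @return list with `r2_marginal` and `r2_conditional`.
#' @export
r2_nakagawa <- function(fit) {
  eta <- drop(fit$X %*% fit$beta)
  vf <- if (length(eta) >= 2) var(eta) else 0
  if (vf == 0) warning("degenerate design: fixed-effect predictor has zero variance")
  denom <- vf + fit$sigma2_patch + fit$sigma2_year + pi^2 / 3
  list(r2_marginal = vf / denom,
       r2_conditional = (vf + fit$sigma2_patch + fit$sigma2_year) / denom)
}

#' Per-covariate explained-variance shares
#'
#' The contribution of fixed effect j is \eqn{\beta_j^2 \sigma^2(x_j)};
#' shares are these contributions normalised by their sum (covariances between
#' terms are ignored), reported as percentages. Factor terms contribute one
#' entry per dummy column.
#'
#' @param fit a `spom_fit`.
#' @return named numeric vector of percentages summing to 100.
#' @export
fixed_effect_variance_share <- function(fit) {
  slopes <- setdiff(colnames(fit$X), "(Intercept)")
  if (!length(slopes)) stop("model has no slopes")
  if (nrow(fit$X) < 2) stop("need >= 2 observations for variance shares")
  contrib <- vapply(slopes, function(j) fit$beta[[j]]^2 * var(fit$X[, j]),
                    numeric(1))
  if (sum(contrib) == 0)
    stop("all per-term contributions are zero; shares undefined")
  100 * contrib / sum(contrib)
}

#' Fit a model with a previous-year patch-state effect
#'
#' Adds the community patch state at t-1 (`state_prev`) as a fixed factor to
#' the environmental covariates, dummy-coded against its first level in
#' canonical state order. Only states compatible with the response occur in
#' the data (e.g. butterfly colonization rows can only have previous states 0
#' or P); canonical levels absent from the data are dropped with a warning.
#' If a single level remains the state term is dropped and the fit collapses
#' to the base model.
#'
#' @inheritParams fit_occupancy_glmm
#' @param ... passed to [fit_occupancy_glmm()].
#' @return a `spom_fit`; the retained levels are in `$state_levels`.
#' @export
fit_state_model <- function(data, terms, ...) {
  if (!"state_prev" %in% names(data)) stop("`data` has no state_prev column")
  data <- data[!is.na(data$state_prev), , drop = FALSE]
  present <- STATE_LEVELS[STATE_LEVELS %in% unique(data$state_prev)]
  if (length(present) < length(unique(data$state_prev)))
    stop("unknown patch state(s) in data")
  data$state_prev <- factor(data$state_prev, levels = present)
  if (length(present) < 2L) {
    warning("only one patch state present (", present,
            "); state term dropped, fitting base model")
    fit <- fit_occupancy_glmm(data, terms, ...)
  } else {
    fit <- fit_occupancy_glmm(data, c(terms, "state_prev"), ...)
  }
  fit$state_levels <- present
  fit
}

#' Patch-state rate table
#'
#' Inverse-logit rates (in %) per previous-year patch state, holding all
#' environmental covariates at their means over the fitted rows. 95%
#' confidence intervals are normal on the logit scale and inverse-logit
#' transformed.
#'
#' @param fit a `spom_fit` from [fit_state_model()].
#' @return data.frame with columns `state`, `rate_pct`, `lo95`, `hi95`.
#' @export
state_rates <- function(fit) {
  if (is.null(fit$state_levels)) stop("`fit` is not a patch-state model")
  nm <- names(fit$beta)
  xbar <- colMeans(fit$X)
  dummies <- paste0("state_prev", fit$state_levels)
  env <- setdiff(nm, c("(Intercept)", dummies))
  out <- lapply(fit$state_levels, function(s) {
    cvec <- setNames(numeric(length(nm)), nm)
    cvec["(Intercept)"] <- 1
    cvec[env] <- xbar[env]
    d <- paste0("state_prev", s)
    if (d %in% nm) cvec[d] <- 1
    eta <- sum(cvec * fit$beta)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    data.frame(state = s,
               rate_pct = 100 * plogis(eta),
               lo95 = 100 * plogis(eta - qnorm(0.975) * se),
               hi95 = 100 * plogis(eta + qnorm(0.975) * se))
  })
  do.call(rbind, out)
}

#' AIC difference between a state model and its base model
#'
#' `delta_aic = AIC(full) - AIC(reduced)`; negative values support the model
#' including patch state. Both models must have been fitted to the identical
#' transition rows.
#'
#' @param full,reduced `spom_fit` objects.
#' @return a single number.
#' @export
delta_aic <- function(full, reduced) {
  if (full$n != reduced$n)
    stop("models were fitted to different row counts (", full$n, " vs ",
         reduced$n, "); comparison is not nested")
  full$aic - reduced$aic
}

#' Patch-state effect screen
#'
#' Convenience wrapper fitting the base model and the patch-state model on the
#' identical rows (those with a known previous state and complete covariates)
#' and returning both fits, the state rate table and the AIC difference.
#'
#' @inheritParams fit_state_model
#' @return list with `base`, `state` (both `spom_fit`), `rates` and
#'   `delta_aic`.
#' @export
state_effect_screen <- function(data, terms, ...) {
  keep <- complete.cases(data[, c("outcome", "patch_id", "year", "state_prev", terms)])
  data <- data[keep, , drop = FALSE]
  base <- fit_occupancy_glmm(data, terms, ...)
  st <- fit_state_model(data, terms, ...)
  list(base = base, state = st, rates = state_rates(st),
       delta_aic = delta_aic(st, base))
}
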