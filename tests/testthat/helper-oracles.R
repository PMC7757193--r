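# Independent oracles and small fixture builders shared across the suite.
# These deliberately avoid the package's own code paths wherever they act as
# a cross-check (hand-written Newton logistic, double-loop connectivity).

# plain logistic regression by Newton-Raphson, no shortcuts
newton_logistic <- function(X, y, maxit = 100, tol = 1e-12) {
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    mu <- plogis(drop(X %*% b))
    g <- crossprod(X, y - mu)
    if (max(abs(g)) < tol) break
    W <- mu * (1 - mu)
    b <- b + drop(solve(crossprod(X, X * W), g))
  }
  drop(b)
}

logistic_loglik <- function(X, y, b) {
  p <- plogis(drop(X %*% b))
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# naive O(n^2) double-loop connectivity summation
naive_connectivity <- function(x, y, areas, occ, alpha) {
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      s[i] <- s[i] + exp(-alpha * d) * areas[j] * occ[j]
    }
  }
  s
}

# minimal patch table without cover columns (connectivity-only tests)
bare_patches <- function(x, y, areas, ids = NULL) {
  ids <- ids %||% paste0("p", seq_along(x))
  data.frame(patch_id = ids, x_km = x, y_km = y, area_m2 = areas,
             road = 0L, vs_score = 0L, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-species occupancy history from a patch x year 0/1 matrix
history_from_matrix <- function(m, species = "M", years = NULL,
                                ids = NULL) {
  years <- years %||% (2000 + seq_len(ncol(m)) - 1L)
  ids <- ids %||% paste0("p", seq_len(nrow(m)))
  occupancy_history(array(m, dim = c(dim(m), 1L)), patch_id = ids,
                    years = years, species = species)
}

# direct simulation of GLMM transition-style data (no landscape involved):
# crossed patch/year random intercepts, standard-normal covariates unless a
# generator is supplied per term
simulate_glmm_data <- function(n_patch, n_year, beta, s2_patch = 0,
                               s2_year = 0, seed = 1, year_level = character(0),
                               state_effect = NULL) {
  set.seed(seed)
  d <- expand.grid(patch_id = sprintf("p%04d", seq_len(n_patch)),
                   year = 2000 + seq_len(n_year) - 1L,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(d)
  terms <- setdiff(names(beta), "(Intercept)")
  eta <- rep(beta[["(Intercept)"]], n)
  for (tm in terms) {
    if (tm %in% year_level) {
      yv <- rnorm(n_year)
      d[[tm]] <- yv[match(d$year, sort(unique(d$year)))]
    } else {
      d[[tm]] <- rnorm(n)
    }
    eta <- eta + beta[[tm]] * d[[tm]]
  }
  if (!is.null(state_effect)) {
    d$state_prev <- sample(names(state_effect), n, replace = TRUE)
    eta <- eta + unname(state_effect[d$state_prev])
  }
  pe <- rnorm(n_patch, 0, sqrt(s2_patch))
  ye <- rnorm(n_year, 0, sqrt(s2_year))
  eta <- eta + pe[match(d$patch_id, unique(d$patch_id))] +
    ye[match(d$year, sort(unique(d$year)))]
  d$outcome <- rbinom(n, 1, plogis(eta))
  d
}

# fabricate a minimal spom_fit for closed-form arithmetic checks
fake_fit <- function(beta, X, sigma2_patch = 0, sigma2_year = 0,
                     vcov = NULL, loglik = NA_real_, aic = NA_real_,
                     n = nrow(X), state_levels = NULL) {
  structure(list(beta = beta,
                 vcov = vcov %||% diag(1e-6, length(beta),
                                       length(beta)) |>
                   `dimnames<-`(list(names(beta), names(beta))),
                 sigma2_patch = sigma2_patch, sigma2_year = sigma2_year,
                 loglik = loglik, aic = aic, n = n,
                 terms = setdiff(names(beta), "(Intercept)"), X = X,
                 state_levels = state_levels),
            class = "spom_fit")
}

# intercept-only truth parameters giving constant rates c and e everywhere
constant_rate_truth <- function(c_rate, e_rate) {
  rm_const <- function(p) rate_model(c("(Intercept)" = qlogis(p)))
  one <- list(col = rm_const(c_rate), ext = rm_const(e_rate))
  list(alpha = 1, M = one, C = one, P = one)
}

# full truth-model fits for forecasting tests, fitted on a generated history
fit_all_models <- function(history, patches, precip, truth) {
  fits <- list()
  for (sp in c("M", "C", "P")) {
    fits[[sp]] <- list()
    for (resp in c("colonization", "extinction")) {
      rt <- if (resp == "colonization") "col" else "ext"
      tab <- build_transition_table(history, patches, precip, sp, resp)
      terms <- setdiff(names(truth[[sp]][[rt]]$coef), "(Intercept)")
      fits[[sp]][[rt]] <- suppressWarnings(
        suppressMessages(fit_occupancy_glmm(tab, terms)))
    }
  }
  fits
}
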