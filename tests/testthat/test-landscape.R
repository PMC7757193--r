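test_that("connectivity matches hand summation and excludes the self-term", {
  pa <- bare_patches(x = c(0, 1, 3), y = c(0, 0, 0), areas = c(10, 20, 40))
  h <- history_from_matrix(cbind(c(1, 1, 0), c(0, 1, 1)))
  s <- compute_connectivity(h, pa, "M", 2001)
  expect_equal(unname(s),
               c(20 * exp(-1), 10 * exp(-1), 10 * exp(-3) + 20 * exp(-2)))
  expect_equal(unname(s),
               naive_connectivity(pa$x_km, pa$y_km, pa$area_m2, c(1, 1, 0), 1))
})

test_that("connectivity is zero with no occupied neighbours and errors cleanly", {
  pa <- bare_patches(c(0, 2), c(0, 0), c(5, 5))
  h <- history_from_matrix(cbind(c(0, 0), c(1, 1)))
  expect_equal(unname(compute_connectivity(h, pa, "M", 2001)), c(0, 0))
  expect_error(compute_connectivity(h, pa, "M", 2000), "not in the occupancy")
  expect_error(compute_connectivity(h, pa, "Q", 2001))
})

test_that("NA occupancy contributes zero to connectivity sums", {
  pa <- bare_patches(c(0, 1, 2), c(0, 0, 0), c(10, 20, 30))
  h_na <- history_from_matrix(cbind(c(1, NA, 1), c(0, 0, 0)))
  h_0 <- history_from_matrix(cbind(c(1, 0, 1), c(0, 0, 0)))
  expect_equal(compute_connectivity(h_na, pa, "M", 2001),
               compute_connectivity(h_0, pa, "M", 2001))
})

test_that("vectorized connectivity equals the double-loop oracle on random networks", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    pa <- bare_patches(runif(n, 0, 10), runif(n, 0, 10), rlnorm(n, 3, 1))
    occ <- rbinom(n, 1, 0.5)
    alpha <- runif(1, 0.2, 3)
    h <- history_from_matrix(cbind(occ, occ))
    s <- compute_connectivity(h, pa, "M", 2001, alpha = alpha)
    o <- naive_connectivity(pa$x_km, pa$y_km, pa$area_m2, occ, alpha)
    expect_lt(max(abs(s - o)) / max(max(abs(o)), 1e-300), 1e-12)
  }
})

test_that("connectivity is monotone in occupancy and antitone in alpha", {
  set.seed(7)
  n <- 8
  pa <- bare_patches(runif(n, 0, 5), runif(n, 0, 5), rlnorm(n, 3, 1))
  occ <- c(1, 0, 1, 0, 0, 1, 0, 0)
  occ2 <- occ; occ2[2] <- 1  # add one occupied patch
  h1 <- history_from_matrix(cbind(occ, occ))
  h2 <- history_from_matrix(cbind(occ2, occ2))
  s1 <- compute_connectivity(h1, pa, "M", 2001)
  s2 <- compute_connectivity(h2, pa, "M", 2001)
  expect_true(all(s2[-2] >= s1[-2]))
  expect_true(all(compute_connectivity(h1, pa, "M", 2001, alpha = 2) <= s1))
})

test_that("host connectivity averages cover over recorded years only", {
  pa <- bare_patches(c(0, 1), c(0, 0), c(10, 10))
  pa$cover_pl_2000 <- c(5, NA)
  pa$cover_pl_2001 <- c(5, 8)
  pa$cover_pl_2002 <- c(5, NA)
  s <- compute_host_connectivity(pa)
  expect_equal(unname(s), c(8 * exp(-1), 5 * exp(-1)))
  pa0 <- pa
  pa0[, c("cover_pl_2000", "cover_pl_2001", "cover_pl_2002")] <- 0
  expect_equal(unname(compute_host_connectivity(pa0)), c(0, 0))
  pa_na <- pa
  pa_na[2, c("cover_pl_2000", "cover_pl_2001", "cover_pl_2002")] <- NA
  expect_error(compute_host_connectivity(pa_na), "p2")
})

test_that("turnover events match exhaustive enumeration", {
  m <- rbind(c(0, 1, 1, 0), c(1, 1, 0, 1))
  h <- history_from_matrix(m, years = 2000:2003, ids = c("p1", "p2"))
  ev <- assign_turnover_events(h, "M")
  expect_equal(ev$colonizations$patch_id, c("p1", "p2"))
  expect_equal(ev$colonizations$year, c(2001L, 2003L))
  expect_equal(ev$extinctions$patch_id, c("p2", "p1"))
  expect_equal(sort(ev$extinctions$year), c(2002L, 2003L))
  expect_equal(ev$n_possible_col, 2L)
  expect_equal(ev$n_possible_ext, 4L)
})

test_that("constant occupancy yields no events; NA transitions are excluded", {
  h <- history_from_matrix(rbind(c(1, 1, 1), c(0, 0, 0)))
  ev <- assign_turnover_events(h, "M")
  expect_equal(nrow(ev$colonizations), 0L)
  expect_equal(nrow(ev$extinctions), 0L)
  h_na <- history_from_matrix(rbind(c(1, NA, 0), c(0, 1, 1)))
  ev <- assign_turnover_events(h_na, "M")
  # p1 transitions touch the NA in 2001 and are dropped from both sides
  expect_equal(ev$n_possible_col, 1L)  # p2 2001 only
  expect_equal(ev$n_possible_ext, 1L)  # p2 2002 only
  expect_error(assign_turnover_events(h, "P"), "not in the occupancy")
})

test_that("parasitoid events are conditioned on the host and flag joint transitions", {
  # patch 1: M and C arrive together in 2001 -> joint colonization;
  # patch 2: host absent throughout -> never a possible C colonization
  m <- rbind(c(0, 1, 1), c(0, 0, 0))
  cc <- rbind(c(0, 1, 1), c(0, 0, 0))
  p <- rbind(c(0, 0, 0), c(0, 0, 0))
  arr <- array(c(m, cc, p), dim = c(2, 3, 3),
               dimnames = list(c("p1", "p2"), 2000:2002, c("M", "C", "P")))
  h <- occupancy_history(arr)
  ev <- assign_turnover_events(h, "C")
  expect_equal(nrow(ev$colonizations), 1L)
  expect_true(ev$colonizations$joint)
  expect_equal(ev$n_joint_col, 1L)
  expect_equal(ev$n_possible_col, 1L)  # only p1/2001; p2 has no host
})

test_that("colonizations minus extinctions conserve occupancy change", {
  pa <- generate_landscape(80, years = 2000:2005, extent_km = c(15, 20),
                           seed = 3)
  pr <- generate_covariates(2000:2005, seed = 4)
  h <- generate_history(pa, pr, default_truth_params(), years = 2000:2005,
                        seed = 5)
  for (sp in c("M", "C", "P")) {
    ev <- assign_turnover_events(h, sp)
    occ <- colSums(h[, , sp])
    for (k in 2:6) {
      t <- (2000:2005)[k]
      expect_equal(sum(ev$colonizations$year == t) -
                     sum(ev$extinctions$year == t),
                   unname(occ[k] - occ[k - 1]))
    }
  }
})

test_that("patch-state encoding is a bijection over the six valid triples", {
  flags <- expand.grid(m = 0:1, c = 0:1, p = 0:1)
  valid <- flags[!(flags$c == 1 & flags$m == 0), ]
  labels <- encode_patch_state(valid$m, valid$c, valid$p)
  expect_setequal(labels, c("0", "M", "MC", "P", "MP", "MCP"))
  expect_equal(length(unique(labels)), 6L)
  back <- patch_state_flags(labels)
  expect_equal(unname(back), unname(as.matrix(valid)))
  expect_equal(encode_patch_state(1, 1, 1), "MCP")
  expect_equal(encode_patch_state(0, 0, 0), "0")
  expect_error(encode_patch_state(0, 1, 0), "without its host")
  expect_error(encode_patch_state(0, 1, 1), "without its host")
  expect_error(patch_state_flags("CM"), "unknown")
})

test_that("cover classes are equal-count quantile bins with stable ties", {
  expect_equal(bin_cover_classes(c(3, 1, 2), k = 1), c(1, 1, 1))
  v <- sample(seq(0.1, 30, length.out = 30))
  cls <- bin_cover_classes(v, k = 15)
  expect_equal(as.vector(table(cls)), rep(2L, 15))
  # sort-and-chunk oracle: class index must follow the value order
  expect_equal(cls[order(v)], rep(1:15, each = 2))
  # ties: stable original order
  expect_equal(bin_cover_classes(c(5, 5, 5, 5), k = 2), c(1, 1, 2, 2))
  expect_error(bin_cover_classes(1:3, k = 4), "exceeds")
  expect_error(bin_cover_classes(c(1, Inf), k = 1), "finite")
})
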