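test_that("Schoener overlap evaluates its defining cases", {
  expect_equal(schoener_alpha(c(0.3, 0.7), c(0.3, 0.7)), 1)
  expect_equal(schoener_alpha(c(1, 0), c(0, 1)), 0)
  expect_equal(schoener_alpha(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 0.5)
  expect_equal(schoener_alpha(c(a = 0.2, b = 0.8), c(b = 0.8, a = 0.2)), 1)
  expect_error(schoener_alpha(c(a = 1, b = 0), c(a = 0.5, c = 0.5)), "index")
  expect_error(schoener_alpha(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("Bray-Curtis is the overlap complement on the simplex", {
  expect_equal(bray_curtis(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  set.seed(14)
  for (i in 1:250) {
    k <- sample(3:20, 1)
    px <- random_simplex(k)
    py <- random_simplex(k)
    d <- bray_curtis(px, py)
    expect_equal(d, 0.5 * sum(abs(px - py)))
    expect_equal(d + schoener_alpha(px, py), 1)
  }
  # independent cross-check against the community-ecology standard
  if (requireNamespace("vegan", quietly = TRUE)) {
    set.seed(15)
    for (i in 1:10) {
      px <- random_simplex(8)
      py <- random_simplex(8)
      expect_equal(bray_curtis(px, py),
                   as.numeric(vegan::vegdist(rbind(px, py), "bray")))
    }
  }
})

test_that("diet pooling sums rarefied counts across fish", {
  props <- rbind(f1 = c(A = 0.75, B = 0.25), f2 = c(A = 0.25, B = 0.75))
  dm <- manual_diet_matrix(props, species = "rock_bass", period = "drift",
                           prey_reads = c(40, 40))
  pooled <- pool_diets(dm, "rock_bass", "drift")
  expect_equal(unname(pooled$p), c(0.5, 0.5))
  expect_identical(pooled$n_fish, 2L)

  # counts (30,10) and (10,30): pooled (0.5, 0.5) regardless of order
  dm_rev <- manual_diet_matrix(props[2:1, ], species = "rock_bass",
                               period = "drift", prey_reads = c(40, 40))
  expect_equal(pool_diets(dm_rev, "rock_bass", "drift")$p, pooled$p)

  # unequal denominators weight fish by prey reads under count pooling
  dm_w <- manual_diet_matrix(props, species = "rock_bass", period = "drift",
                             prey_reads = c(120, 40))
  expect_equal(unname(pool_diets(dm_w, "rock_bass", "drift")$p),
               c((90 + 10) / 160, (30 + 30) / 160))
  expect_equal(unname(pool_diets(dm_w, "rock_bass", "drift",
                                 method = "mean")$p), c(0.5, 0.5))

  one <- manual_diet_matrix(props[1, , drop = FALSE], "burbot", "postdrift")
  expect_equal(unname(pool_diets(one, "burbot", "postdrift")$p), c(0.75, 0.25))
  expect_error(pool_diets(dm, "logperch", "drift"), "no qualifying samples")
})

test_that("overlap matrices are symmetric with a correct substantial flag", {
  props <- rbind(a1 = c(A = 1, B = 0), b1 = c(A = 0.61, B = 0.39),
                 a2 = c(A = 1, B = 0), b2 = c(A = 0.60, B = 0.40))
  dm <- manual_diet_matrix(props, species = c("sp_a", "sp_b", "sp_a", "sp_b"),
                           period = c("drift", "drift", "postdrift",
                                      "postdrift"))
  ov <- overlap_matrices(dm)
  m <- ov$alpha$drift
  expect_identical(diag(m), c(sp_a = 1, sp_b = 1))
  expect_identical(m, t(m))
  expect_equal(m["sp_a", "sp_b"], 0.61)
  expect_true(ov$pairs$substantial_drift)      # 0.61 > 0.6
  expect_equal(ov$alpha$postdrift["sp_a", "sp_b"], 0.60)
  expect_false(ov$pairs$substantial_postdrift) # 0.60 is not substantial
  expect_equal(ov$pairs$delta, -0.01)

  same <- manual_diet_matrix(rbind(x = c(A = 0.4, B = 0.6),
                                   y = c(A = 0.4, B = 0.6)),
                             species = c("sp_x", "sp_y"), period = "drift")
  expect_equal(overlap_matrices(same)$alpha$drift["sp_x", "sp_y"], 1)
})

test_that("sign-flip test handles degenerate input and matches enumeration", {
  z <- paired_sign_flip_test(delta = rep(0, 5), n_perm = 99, seed = 1)
  expect_identical(z$statistic, 0)
  expect_identical(z$p, 1)
  expect_error(paired_sign_flip_test(delta = 1), "2 pairs")

  # exact oracle: full enumeration of the 2^8 sign assignments
  set.seed(23)
  delta <- round(stats::rnorm(8, -0.1, 0.2), 3)
  p_exact <- exact_sign_flip_p(delta)
  mc <- paired_sign_flip_test(delta = delta, n_perm = 49999, seed = 2)
  se <- sqrt(p_exact * (1 - p_exact) / 49999)
  expect_lt(abs(mc$p - p_exact), 4 * se + 2 / 49999)

  # one-sided variants agree with their enumerations
  mc_less <- paired_sign_flip_test(delta = delta, n_perm = 49999, seed = 3,
                                   alternative = "less")
  p_less <- exact_sign_flip_p(delta, "less")
  expect_lt(abs(mc_less$p - p_less),
            4 * sqrt(p_less * (1 - p_less) / 49999) + 2 / 49999)
})

test_that("sign-flip test is order-invariant and seed-reproducible", {
  set.seed(29)
  delta <- stats::rnorm(12, -0.05, 0.1)
  a <- paired_sign_flip_test(delta = delta, n_perm = 4999, seed = 7)
  b <- paired_sign_flip_test(delta = rev(delta), n_perm = 4999, seed = 7)
  c <- paired_sign_flip_test(delta = delta, n_perm = 4999, seed = 7)
  expect_identical(a$p, b$p)
  expect_identical(a, c)
  expect_equal(a$statistic, mean(delta))
  # p bounded below by the add-one rule
  expect_gte(a$p, 1 / 5000)
})

test_that("Manly's index standardizes diet by availability", {
  expect_equal(unname(manly_alpha(c(0.5, 0.5), c(0.5, 0.5))), c(0.5, 0.5))
  expect_equal(unname(manly_alpha(c(0.8, 0.2), c(0.4, 0.6))), c(6 / 7, 1 / 7))
  expect_equal(unname(manly_alpha(c(1, 0), c(0.3, 0.7))), c(1, 0))
  expect_error(manly_alpha(c(0.5, 0.5), c(1, 0)), "positive")
  r <- random_simplex(7)
  n <- random_simplex(7)
  expect_equal(sum(manly_alpha(r, n)), 1)
})

test_that("Chesson's epsilon spans [-1, 1] and increases in alpha", {
  for (m in c(2, 5, 15)) {
    expect_equal(chesson_epsilon(1 / m, m), 0)
    expect_equal(chesson_epsilon(1, m), 1)
    expect_equal(chesson_epsilon(0, m), -1)
    a <- seq(0, 1, by = 0.01)
    eps <- chesson_epsilon(a, m)
    expect_true(all(diff(eps) > 0))
    expect_true(all(eps >= -1 - 1e-12 & eps <= 1 + 1e-12))
  }
  expect_equal(chesson_epsilon(0.3, 2), 2 * 0.3 - 1)
  expect_error(chesson_epsilon(0.5, 1), "m")
  expect_error(chesson_epsilon(1.2, 5), "alpha_i")
})

test_that("per-day selectivity is neutral when diet tracks availability", {
  avail <- c(E1 = 0.5, E2 = 0.3, E3 = 0.2)
  nightly <- data.frame(night = "2015-06-04", esu = names(avail),
                        biomass_g = avail * 10)
  props <- rbind(s1 = avail, s2 = avail)
  dm <- manual_diet_matrix(props, species = "rock_bass", period = "drift",
                           date = "2015-06-05", night = "2015-06-04")
  sel <- selectivity_by_day(dm, nightly)
  expect_equal(sel$chesson_epsilon, rep(0, 3))
  expect_equal(sum(sel$manly_alpha), 1)
  expect_identical(unique(sel$m), 3L)
  expect_identical(unique(sel$n_fish), 2L)
})

test_that("per-day selectivity renormalizes over surveyed ESUs and skips empties", {
  nightly <- data.frame(night = "2015-06-04", esu = c("E1", "E2"),
                        biomass_g = c(6, 2))
  # diet has an unsurveyed ESU (dropped and renormalized) and one
  # species-day with no surveyed reads at all (skipped)
  props <- rbind(s1 = c(E1 = 0.3, E2 = 0.1, X = 0.6),
                 s2 = c(E1 = 0, E2 = 0, X = 1))
  dm <- manual_diet_matrix(props, species = c("rock_bass", "logperch"),
                           period = "drift", date = "2015-06-05",
                           night = "2015-06-04")
  sel <- selectivity_by_day(dm, nightly)
  expect_identical(unique(sel$species), "rock_bass")
  expect_equal(sel$r_i, c(0.75, 0.25))
  expect_equal(sel$n_i, c(0.75, 0.25))
  expect_equal(sel$chesson_epsilon, c(0, 0))
  expect_identical(attr(sel, "skipped"), "logperch 2015-06-05")

  # Manly alpha sums to 1 for every record regardless of flooring
  nightly0 <- data.frame(night = "2015-06-04", esu = c("E1", "E2"),
                         biomass_g = c(6, 0))
  sel0 <- selectivity_by_day(dm, nightly0)
  expect_equal(sum(sel0$manly_alpha), 1)
  expect_true(sel0$n_i[sel0$esu == "E2"] > 0)
})
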