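two_class_surface <- function(seed = 201, n = 6) {
  gen_surface_set(n, default_profiles(), c("forest", "open"), seed = seed)
}

test_that("recent assemblages average then square-root per record", {
  rec <- pollen_record("r1", 50, 10, c(100, 300, 4000), c("A", "B"),
                       matrix(c(3, 1,
                                1, 3,
                                2, 2), 3, 2, byrow = TRUE))
  ra <- recent_assemblages(list(rec))
  # only the two samples in [-60, 500] BP; mean proportions then sqrt
  expect_equal(unname(ra$r1), sqrt(c(0.5, 0.5)))
  # a single in-window sample is its own mean
  rec1 <- pollen_record("r2", 50, 10, c(200, 2000), c("A", "B"),
                        matrix(c(3, 1, 9, 9), 2, 2, byrow = TRUE))
  expect_equal(unname(recent_assemblages(list(rec1))$r2),
               sqrt(c(0.75, 0.25)))
  # the alternative operation order square-roots before averaging
  ra2 <- recent_assemblages(list(rec), order = "sqrt_then_mean")
  expect_equal(unname(ra2$r1),
               c(mean(sqrt(c(0.75, 0.25))), mean(sqrt(c(0.25, 0.75)))))
  # records without recent samples are excluded
  old <- pollen_record("r3", 50, 10, c(3000, 4000), c("A", "B"),
                       matrix(1, 2, 2))
  expect_null(recent_assemblages(list(old))$r3)
})

test_that("typical assemblages honour class selection and group weights", {
  surf <- two_class_surface()
  recent <- recent_assemblages(surf$records)
  a_f <- typical_assemblage(recent, "forest", biome_id = "Fo")
  expect_equal(a_f$n_source_records, 6)
  # dominant taxa of the typical assemblage match the generating profile
  profs <- default_profiles()
  top_true <- names(sort(profs$forest, decreasing = TRUE))[1:3]
  top_est <- a_f$taxa[order(a_f$weights, decreasing = TRUE)][1:3]
  expect_setequal(top_est, top_true)
  expect_error(typical_assemblage(recent, "tundra"), "tundra")

  # equal group weights with unbalanced group sizes (4:1): the result is
  # the unweighted mean of the two group means
  surf2 <- gen_surface_set(4, default_profiles()["forest"], "evergreen",
                           seed = 300)
  surf3 <- gen_surface_set(1, default_profiles()["open"], "deciduous",
                           seed = 301)
  recent2 <- recent_assemblages(c(surf2$records, surf3$records))
  aw <- typical_assemblage(recent2, c("evergreen", "deciduous"),
                           group_weights = c(evergreen = 0.5, deciduous = 0.5),
                           biome_id = "Bo")
  m_e <- typical_assemblage(recent2, "evergreen", biome_id = "e")$weights
  m_d <- typical_assemblage(recent2, "deciduous", biome_id = "d")$weights
  al <- align_taxa(m_e, m_d)
  expect_equal(aw$weights, (al[[1]] + al[[2]]) / 2, tolerance = 1e-12)
  # when group sizes are equal, weights change nothing
  surf4 <- gen_surface_set(4, default_profiles()["open"], "deciduous",
                           seed = 302)
  recent3 <- recent_assemblages(c(surf2$records, surf4$records))
  w_eq <- typical_assemblage(recent3, c("evergreen", "deciduous"),
                             group_weights = c(evergreen = 0.5, deciduous = 0.5),
                             biome_id = "x")$weights
  w_un <- typical_assemblage(recent3, c("evergreen", "deciduous"),
                             biome_id = "x")$weights
  expect_equal(w_eq, w_un, tolerance = 1e-12)
})

test_that("difference axes subtract, cancel shared taxa and antisymmetrize", {
  a <- structure(list(biome_id = "i", taxa = c("A", "B"),
                      weights = c(A = 0.6, B = 0.2)),
                 class = "typical_assemblage")
  b <- structure(list(biome_id = "j", taxa = c("A", "B"),
                      weights = c(A = 0.1, B = 0.5)),
                 class = "typical_assemblage")
  ax <- difference_axis(a, b)
  expect_equal(unname(ax$values), c(0.5, -0.3))
  expect_equal(ax$axis_id, "i,j")
  # self-difference vanishes
  expect_true(all(difference_axis(a, a)$values == 0))
  # a taxon equally dominant on both sides cancels
  c1 <- structure(list(biome_id = "x", taxa = c("Pinus", "A"),
                       weights = c(Pinus = 0.7, A = 0.2)),
                  class = "typical_assemblage")
  c2 <- structure(list(biome_id = "y", taxa = c("Pinus", "B"),
                       weights = c(Pinus = 0.7, B = 0.3)),
                  class = "typical_assemblage")
  expect_equal(unname(difference_axis(c1, c2)$values["Pinus"]), 0)
  # antisymmetry, including the induced scores
  rec <- quick_record(seed = 71)
  ax_ij <- difference_axis(a, b)
  ax_ji <- difference_axis(b, a)
  expect_equal(ax_ij$values, -ax_ji$values)
})

test_that("projection is an uncentred dot product, linear in the axis", {
  rec <- pollen_record("p", 50, 10, c(100, 200, 300), c("A", "B"),
                       matrix(c(4, 0, 2, 2, 0, 4), 3, 2, byrow = TRUE))
  ax <- structure(list(axis_id = "i,j", taxa = c("A", "B"),
                       values = c(A = 0.5, B = -0.5)),
                  class = "difference_axis")
  ss <- project_scores(rec, ax)
  sq <- unclass(sqrt_transform(to_proportions(rec)))
  expect_equal(ss$values, as.numeric(sq %*% c(0.5, -0.5)))
  expect_gt(ss$values[1], 0)   # pure-A sample points toward biome i
  expect_lt(ss$values[3], 0)
  # zero axis gives zero scores
  ax0 <- structure(list(axis_id = "0", taxa = c("A", "B"),
                        values = c(A = 0, B = 0)), class = "difference_axis")
  expect_true(all(project_scores(rec, ax0)$values == 0))
  # linearity: project(x, a - b) = project(x, a) - project(x, b)
  axa <- structure(list(axis_id = "a", taxa = c("A", "B"),
                        values = c(A = 0.3, B = 0.4)), class = "difference_axis")
  axb <- structure(list(axis_id = "b", taxa = c("A", "B"),
                        values = c(A = 0.1, B = 0.9)), class = "difference_axis")
  axd <- structure(list(axis_id = "d", taxa = c("A", "B"),
                        values = axa$values - axb$values), class = "difference_axis")
  expect_equal(project_scores(rec, axd)$values,
               project_scores(rec, axa)$values - project_scores(rec, axb)$values,
               tolerance = 1e-12)
  # disjoint taxa are an error
  ax2 <- structure(list(axis_id = "z", taxa = c("X", "Y"),
                        values = c(X = 1, Y = -1)), class = "difference_axis")
  expect_error(project_scores(rec, ax2), "no shared taxa")
})

test_that("window means, quantile groups and filters behave as declared", {
  ss <- structure(list(times = c(1000, 3000, 5000, 9000),
                       values = c(9, -1, 1, 9), source = "x"),
                  class = "score_series")
  ms <- mean_score(ss)
  expect_equal(ms$u_bar, 0)
  expect_equal(ms$n_samples_in_window, 2)
  expect_true(is.na(mean_score(ss, window = c(10000, 12000))$u_bar))

  expect_equal(as.vector(table(quantile_groups(rnorm(10), 5))), rep(2L, 5))
  g <- quantile_groups(1:100, 5)
  expect_true(all(g[1:20] == 1))
  expect_error(quantile_groups(1:3, 5), "fewer sites")
  # size difference at most one, ties stable
  g2 <- quantile_groups(c(rep(1, 7), rep(2, 6)), 5)
  expect_lte(diff(range(table(g2))), 1)

  bs <- data.frame(site_id = c("a", "b", "c"), u_bar = c(-1, 0.5, 2),
                   region = c("W_Eurasia", "E_Eurasia", "W_Eurasia"))
  expect_setequal(binary_filter(bs, rule_positive()), c("b", "c"))
  bs0 <- data.frame(site_id = c("a", "b"), u_bar = c(0, 1),
                    region = "W_Eurasia")
  expect_message(keep <- binary_filter(bs0, rule_positive()), "negative side")
  expect_identical(keep, "b")
  big <- data.frame(site_id = paste0("s", 1:100), u_bar = rnorm(100),
                    region = "W_Eurasia")
  expect_length(binary_filter(big, rule_upper_q(0.4)), 40)
  expect_setequal(binary_filter(bs, rule_region("W_Eurasia")), c("a", "c"))
  expect_error(binary_filter(bs, list(type = "bogus")), "unknown rule")
  expect_error(binary_filter(bs, "positive"), "unknown rule")
})

test_that("axis classification separates the synthetic biomes", {
  surf <- two_class_surface(seed = 401, n = 8)
  recent <- recent_assemblages(surf$records)
  a_f <- typical_assemblage(recent, "forest", biome_id = "Fo")
  a_o <- typical_assemblage(recent, "open", biome_id = "Op")
  ax <- difference_axis(a_f, a_o)

  # surface records themselves: perfect sign separation
  u_surf <- vapply(surf$records, function(r) {
    mean(project_scores(r, ax)$values)
  }, numeric(1))
  expect_true(all(u_surf[surf$meta$class == "forest"] > 0))
  expect_true(all(u_surf[surf$meta$class == "open"] < 0))

  # fossil records: sign accuracy and monotonicity in the mixture
  world <- gen_two_biome_world(40, H_true = 0, mixture_range = c(0.05, 0.95),
                               seed = 402)
  u <- vapply(world$records, function(r) {
    mean_score(project_scores(r, ax))$u_bar
  }, numeric(1))
  acc <- mean((u > 0) == (world$meta$true_mixture > 0.5))
  expect_gte(acc, 0.9)
  expect_gte(cor(u, world$meta$true_mixture, method = "spearman"), 0.9)

  # iterative chain: positive-side filter isolates forest-leaning sites
  bs <- data.frame(site_id = world$meta$site_id, u_bar = u,
                   region = "W_Eurasia")
  kept <- binary_filter(bs, rule_positive())
  purity <- mean(world$meta$true_mixture[world$meta$site_id %in% kept] > 0.5)
  expect_gte(purity, 0.9)
})
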