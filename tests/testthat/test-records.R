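test_that("records survive a write / load round trip", {
  world <- gen_two_biome_world(3, seed = 17)
  dir <- withr::local_tempdir()
  cp <- file.path(dir, "counts.csv"); mp <- file.path(dir, "meta.csv")
  write_records(world$records, cp, mp)
  back <- load_records(cp, mp)
  expect_setequal(names(back), vapply(world$records, `[[`, "", "site_id"))
  for (orig in world$records) {
    got <- back[[orig$site_id]]
    expect_equal(got$times, orig$times)
    expect_equal(got$lat, orig$lat)
    # loader sorts taxa; compare on the shared taxon order
    al <- align_taxa(got$counts, orig$counts)
    expect_equal(al[[1]], al[[2]])
  }
})

test_that("loader validates schema and site metadata", {
  dir <- withr::local_tempdir()
  counts <- data.frame(site_id = "a", age_bp = 100, taxon = "Pinus", count = 5)
  meta <- data.frame(site_id = "a", lat = 50, lon = 10)
  cp <- file.path(dir, "c.csv"); mp <- file.path(dir, "m.csv")
  utils::write.csv(counts[, -4], cp, row.names = FALSE)
  utils::write.csv(meta, mp, row.names = FALSE)
  expect_error(load_records(cp, mp), "count")

  utils::write.csv(counts, cp, row.names = FALSE)
  utils::write.csv(meta[0, ], mp, row.names = FALSE)
  expect_error(load_records(cp, mp), "a")
})

test_that("duplicate rows are summed and taxon maps merge synonyms", {
  dir <- withr::local_tempdir()
  counts <- data.frame(
    site_id = "a", age_bp = c(100, 100, 100, 200, 200),
    taxon = c("Picea_sp", "Picea", "Pinus", "Pinus", "Pinus"),
    count = c(2, 3, 5, 7, 1))
  meta <- data.frame(site_id = "a", lat = 50, lon = 10)
  cp <- file.path(dir, "c.csv"); mp <- file.path(dir, "m.csv")
  utils::write.csv(counts, cp, row.names = FALSE)
  utils::write.csv(meta, mp, row.names = FALSE)

  expect_warning(recs <- load_records(cp, mp, taxon_map = c(Picea_sp = "Picea")),
                 "duplicate")
  r <- recs$a
  expect_setequal(r$taxa, c("Picea", "Pinus"))
  expect_equal(unname(r$counts[1, "Picea"]), 5)   # 2 + 3 merged
  expect_equal(unname(r$counts[2, "Pinus"]), 8)   # 7 + 1 summed
})

test_that("proportion and square-root transforms close over the simplex", {
  rec <- pollen_record("x", 50, 10, c(100, 200), c("A", "B"),
                       matrix(c(3, 1, 1, 1), 2, 2, byrow = TRUE))
  pr <- to_proportions(rec)
  expect_equal(unclass(pr)[1, ], c(A = 0.75, B = 0.25))
  sq <- sqrt_transform(pr)
  expect_equal(unclass(sq)[1, ], c(A = sqrt(0.75), B = 0.5))
  expect_equal(rowSums(unclass(sq)^2), rep(1, 2), tolerance = 1e-12)
  expect_error(sqrt_transform(sq), "already")
  expect_error(sqrt_transform(matrix(0.5, 2, 2)), "proportion")
  # zeros stay zero
  rec0 <- pollen_record("y", 50, 10, 1:3, c("A", "B"),
                        matrix(c(2, 0, 1, 1, 0, 2), 3, 2, byrow = TRUE))
  expect_true(all(unclass(sqrt_transform(to_proportions(rec0)))[c(1, 6)] %in% c(0, 1)))
  # a zero-total sample is refused with its age named
  fake <- list(counts = matrix(c(1, 0, 1, 0), 2, 2), times = c(100, 250),
               taxa = c("A", "B"))
  fake$counts[2, ] <- 0
  expect_error(to_proportions(fake), "250")
})

test_that("record filtering applies the window, count and latitude rules", {
  mk <- function(id, lat, ages) {
    pollen_record(id, lat, 10, ages, c("A", "B"),
                  matrix(1, length(ages), 2))
  }
  south <- mk("south", 20, seq(2000, 8000, length.out = 10))
  sparse <- mk("sparse", 50, c(100, 2500, 3000, 3500, 4000, 4500, 9000))
  good <- mk("good", 50, seq(2100, 7900, length.out = 8))
  out <- filter_records(list(south, sparse, good))
  expect_named(out, "good")
  rep <- attr(out, "filter_report")
  expect_equal(rep$removed_lat, 1)
  expect_equal(rep$removed_samples, 1)
  # out-of-window samples are trimmed from survivors
  expect_true(all(out$good$times >= 2000 & out$good$times <= 8000))
})

test_that("a constructed cohort splits as designed by the two rules", {
  mk <- function(id, lat, n_in) {
    ages <- c(seq(2100, 7900, length.out = max(n_in, 1)),
              if (n_in < 6) seq(8100, 9000, length.out = 6) else numeric(0))
    pollen_record(id, lat, 10, sort(ages), c("A", "B"),
                  matrix(1, length(ages), 2))
  }
  recs <- c(lapply(1:3, function(i) mk(paste0("s", i), 20, 8)),   # fail lat
            lapply(1:3, function(i) mk(paste0("t", i), 50, 4)),   # fail count
            lapply(1:4, function(i) mk(paste0("u", i), 50, 8)))   # pass both
  out <- filter_records(recs)
  rep <- attr(out, "filter_report")
  expect_equal(rep$removed_lat, 3)
  expect_equal(rep$removed_samples, 3)
  expect_length(out, 4)
  # idempotence
  again <- filter_records(out)
  expect_equal(lapply(again, `[[`, "times"), lapply(out, `[[`, "times"))
})

test_that("taxon alignment zero-fills and commutes with reordering", {
  a <- c(Pinus = 0.5, Picea = 0.3)
  b <- c(Picea = 0.2, Poaceae = 0.7)
  al <- align_taxa(a, b)
  expect_equal(names(al[[1]]), c("Picea", "Pinus", "Poaceae"))
  expect_equal(unname(al[[1]]), c(0.3, 0.5, 0))
  expect_equal(unname(al[[2]]), c(0.2, 0, 0.7))
  # sqrt-transform commutes with column reordering
  rec <- quick_record(seed = 2)
  perm <- sample(ncol(rec$counts))
  rec_p <- pollen_record(rec$site_id, rec$lat, rec$lon, rec$times,
                         rec$taxa[perm], rec$counts[, perm])
  s1 <- sqrt_transform(to_proportions(rec))
  s2 <- sqrt_transform(to_proportions(rec_p))
  expect_equal(unclass(s1)[, rec$taxa], unclass(s2)[, rec$taxa])
})
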