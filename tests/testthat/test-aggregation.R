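test_that("richness grid counts positive-area intersections", {
  g <- toy_grid(4, 4, dlon = 1)
  # one species covering the whole grid: every cell has richness >= 1
  all_r <- rect_range("all", 0, 4, 0, 4)
  rich <- richness_matrix(list(all_r), g)
  expect_true(all(rich >= 1L))
  # two species in single disjoint cells
  r1 <- rect_range("a", 0.2, 0.8, 0.2, 0.8)
  r2 <- rect_range("b", 2.2, 2.8, 2.2, 2.8)
  rich2 <- richness_matrix(list(r1, r2), g)
  expect_equal(sum(rich2), 2L)
  expect_equal(rich2[1, 1], 1L)
  expect_equal(rich2[3, 3], 1L)
  # random rectangles equal a pairwise polygon-cell intersection oracle
  set.seed(61)
  specs <- lapply(1:15, function(k) sort(runif(4, 0, 4))[c(1, 3, 2, 4)])
  ranges <- lapply(seq_along(specs), function(k)
    rect_range(paste0("r", k), specs[[k]][1], specs[[k]][2],
               specs[[k]][3], specs[[k]][4]))
  oracle <- Reduce(`+`, lapply(specs, function(s)
    (rect_cell_area_oracle(s[1], s[2], s[3], s[4], g) > 1e-9) * 1L))
  expect_equal(richness_matrix(ranges, g), oracle)
})

test_that("exposed grids divide counts by richness with the same rule", {
  g <- toy_grid(2, 2, dlon = 2)
  ranges <- list(rect_range("a", 0.2, 1.8, 0.2, 1.8),
                 rect_range("b", 0.2, 1.8, 0.2, 1.8),
                 rect_range("c", 0.2, 1.8, 0.2, 1.8))
  expo <- data.frame(species_id = c("a", "b", "c"), event_class = "heat_wave",
                     proportion = c(1, 1, 0), exposed = c(TRUE, TRUE, FALSE))
  gs <- exposed_grid(ranges, expo, cell_degrees = g)
  expect_equal(gs$richness[1, 1], 3L)
  expect_equal(gs$exposed_count$heat_wave[1, 1], 2L)
  expect_equal(gs$exposed_proportion$heat_wave[1, 1], 2 / 3)
  expect_true(is.na(gs$exposed_proportion$heat_wave[2, 2]))  # richness 0
  # all exposed -> proportion 1 wherever richness > 0
  expo$exposed <- TRUE
  gs1 <- exposed_grid(ranges, expo, cell_degrees = g)
  expect_true(all(gs1$exposed_proportion$heat_wave[gs1$richness > 0] == 1))
  # none exposed -> proportion 0
  expo$exposed <- FALSE
  gs0 <- exposed_grid(ranges, expo, cell_degrees = g)
  expect_true(all(gs0$exposed_proportion$heat_wave[gs0$richness > 0] == 0))
})

test_that("grid summaries are invariant to species processing order", {
  set.seed(71)
  g <- toy_grid(4, 4, dlon = 1)
  ranges <- lapply(1:10, function(k) random_range(paste0("r", k), g, max_span = 2))
  a <- richness_matrix(ranges, g)
  b <- richness_matrix(rev(ranges), g)
  expect_identical(a, b)
})

test_that("taxon summaries reproduce printed-count arithmetic", {
  n <- 215
  expo <- make_exposure(n, list(heat_wave = 210))
  tax <- data.frame(species_id = sprintf("sp%05d", 1:n), order = "Anura",
                    family = "Mantellidae", genus = "g")
  ts <- taxon_summary(expo, tax, "family")
  expect_equal(ts$n_species, 215L)
  expect_equal(ts$n_exposed, 210L)
  expect_equal(round(ts$percent_exposed), 98)   # 210 of 215 species
  # small tallies at one decimal
  expo3 <- make_exposure(3, list(drought = 2))
  tax3 <- data.frame(species_id = sprintf("sp%05d", 1:3), order = "o",
                     family = "f", genus = "g")
  expect_equal(round(taxon_summary(expo3, tax3, "family")$percent_exposed, 1), 66.7)
  # zero exposed
  expo0 <- make_exposure(10, list(heat_wave = 0))
  expect_equal(taxon_summary(expo0, tax = data.frame(
    species_id = sprintf("sp%05d", 1:10), order = "o", family = "f", genus = "g"),
    "order")$percent_exposed, 0)
})

test_that("species without a taxon label are collected under UNASSIGNED", {
  expo <- make_exposure(4, list(heat_wave = 2))
  tax <- data.frame(species_id = sprintf("sp%05d", 1:3), order = "o",
                    family = "f", genus = "g")
  expect_warning(ts <- taxon_summary(expo, tax, "family"), "UNASSIGNED")
  expect_true("UNASSIGNED" %in% ts$taxon)
})

test_that("country counts use the border-straddling intersection rule", {
  west <- cbind(c(0, 2, 2, 0), c(0, 0, 4, 4))
  east <- cbind(c(2, 4, 4, 2), c(0, 0, 4, 4))
  countries <- list(West = west, East = east)
  ranges <- list(rect_range("in_west", 0.2, 1.0, 1, 2),
                 rect_range("straddler", 1.5, 2.5, 1, 2))
  cs <- country_summary(ranges, countries)
  expect_equal(cs$n_species[cs$country == "West"], 2L)
  expect_equal(cs$n_species[cs$country == "East"], 1L)
  # exposure-filtered counts
  expo <- data.frame(species_id = c("in_west", "straddler"),
                     event_class = "heat_wave", proportion = c(1, 1),
                     exposed = c(FALSE, TRUE))
  cse <- country_summary(ranges, countries, expo)
  expect_equal(cse$n_species[cse$country == "West"], 1L)
  expect_equal(cse$n_species[cse$country == "East"], 1L)
})

test_that("multi-exposure partitions species exactly", {
  expo <- rbind(
    data.frame(species_id = "a", event_class = c("heat_wave", "drought", "cold_spell"),
               proportion = 1, exposed = c(TRUE, TRUE, TRUE)),
    data.frame(species_id = "b", event_class = c("heat_wave", "drought", "cold_spell"),
               proportion = 0, exposed = c(TRUE, FALSE, FALSE)),
    data.frame(species_id = "c", event_class = c("heat_wave", "drought", "cold_spell"),
               proportion = 0, exposed = FALSE))
  me <- multi_exposure(expo)
  expect_equal(sum(me$combinations$n_species), 3L)
  expect_equal(me$n_multi, 1L)
  trip <- me$combinations$n_species[me$combinations$combination ==
                                      "cold_spell+drought+heat_wave"]
  expect_equal(trip, 1L)                        # triple-exposed species counted once
  expect_equal(me$combinations$n_species[me$combinations$combination == "none"], 1L)
  expect_error(multi_exposure(rbind(expo, expo[1, ])), "duplicate")
})

test_that("no exposures puts every species in the empty combination", {
  expo <- make_exposure(5, list(heat_wave = 0, drought = 0))
  me <- multi_exposure(expo)
  expect_equal(me$combinations$n_species[me$combinations$combination == "none"], 5L)
  expect_equal(me$percent_multi, 0)
})
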