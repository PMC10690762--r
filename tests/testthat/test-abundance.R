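test_that("species are classified by the group map and unknowns are errors", {
  map <- species_group_map()
  expect_equal(classify_species_group("Pinus massoniana", map), "pine")
  expect_equal(classify_species_group("Cunninghamia lanceolata", map), "fir")
  expect_equal(classify_species_group("  pinus   MASSONIANA ", map), "pine")
  expect_equal(classify_species_group(c("Quercus", "Schima superba"), map),
               c("broadleaf", "broadleaf"))
  expect_error(classify_species_group("Unlisted species X", map),
               "Unlisted species X")
  expect_error(species_group_map(list(pine = "A", fir = "a")),
               "more than one group")
})

test_that("plot abundance is the biomass share and empty plots are rejected", {
  expect_equal(unname(compute_plot_abundance(c(20, 30, 50))), c(0.2, 0.3, 0.5))
  expect_equal(unname(compute_plot_abundance(c(7, 0, 0))), c(1, 0, 0))
  expect_error(compute_plot_abundance(c(0, 0, 0)), "zero total biomass")
  # matrix form, and the simplex property over random positive triples
  b <- matrix(runif(300, 0, 50), ncol = 3)
  ab <- compute_plot_abundance(b)
  expect_true(all(abs(rowSums(ab) - 1) < 1e-12))
  expect_true(all(ab >= 0 & ab <= 1))
})

test_that("pairing keeps plots measured at both endpoints and forested at start", {
  s <- data.frame(plot_id = c("A", "A", "B"), year = c(1994, 1999, 1994),
                  pine = c(.6, .5, 1), fir = c(.3, .3, 0),
                  broadleaf = c(.1, .2, 0))
  p <- pair_surveys(s, c(1994, 1999))
  expect_equal(nrow(p), 1L)
  expect_equal(p$plot_id, "A")
  expect_equal(c(p$y10, p$y20, p$y30), c(.6, .3, .1))
  expect_equal(sum(attr(p, "exclusions")), 1L)

  # non-forested at the start is excluded even if measured later
  s2 <- rbind(s, data.frame(plot_id = c("C", "C"), year = c(1994, 1999),
                            pine = c(NA, .5), fir = c(NA, .3), broadleaf = c(NA, .2)))
  s2[c("pine_biomass", "fir_biomass", "broadleaf_biomass")] <-
    s2[c("pine", "fir", "broadleaf")] * 10
  s2$pine_biomass[s2$plot_id == "C" & s2$year == 1994] <- 0
  s2[s2$plot_id == "C" & s2$year == 1994, c("fir_biomass", "broadleaf_biomass")] <- 0
  s2[s2$plot_id == "C" & s2$year == 1994, c("pine", "fir", "broadleaf")] <- NA
  p2 <- pair_surveys(s2, c(1994, 1999))
  expect_false("C" %in% p2$plot_id)
  expect_equal(unname(attr(p2, "exclusions")["nonforested_former"]), 1L)

  # fully paired set: no exclusions
  s3 <- data.frame(plot_id = rep(c("A", "B", "D"), each = 2),
                   year = rep(c(1994, 1999), 3),
                   pine = .2, fir = .3, broadleaf = .5)
  p3 <- pair_surveys(s3, c(1994, 1999))
  expect_equal(nrow(p3), 3L)
  expect_equal(sum(attr(p3, "exclusions")), 0L)
})

test_that("pairing accounting: kept + excluded = plots at the former year", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 40
    ids <- sprintf("P%02d", 1:n)
    rows <- list()
    for (id in ids) {
      at_former <- runif(1) < 0.8
      at_latter <- runif(1) < 0.8
      forested_f <- runif(1) < 0.9
      if (at_former) {
        b <- if (forested_f) runif(3, 0, 10) else c(0, 0, 0)
        rows[[length(rows) + 1]] <- data.frame(plot_id = id, year = 2014,
          pine_biomass = b[1], fir_biomass = b[2], broadleaf_biomass = b[3])
      }
      if (at_latter) {
        b <- runif(3, 0, 10)
        rows[[length(rows) + 1]] <- data.frame(plot_id = id, year = 2019,
          pine_biomass = b[1], fir_biomass = b[2], broadleaf_biomass = b[3])
      }
    }
    s <- do.call(rbind, rows)
    p <- pair_surveys(s, c(2014, 2019))
    expect_equal(nrow(p) + sum(attr(p, "exclusions")),
                 sum(s$year == 2014))
  }
})

test_that("duplicate (plot_id, year) rows and biomass/abundance mismatch are errors", {
  s <- data.frame(plot_id = c("A", "A", "A"), year = c(1994, 1994, 1999),
                  pine = .2, fir = .3, broadleaf = .5)
  expect_error(pair_surveys(s, c(1994, 1999)), "duplicate")
  s2 <- data.frame(plot_id = c("A", "A"), year = c(1994, 1999),
                   pine = c(.9, .2), fir = c(.05, .3), broadleaf = c(.05, .5),
                   pine_biomass = c(2, 2), fir_biomass = c(3, 3),
                   broadleaf_biomass = c(5, 5))
  expect_error(pair_surveys(s2, c(1994, 1999)), "disagree")
})

test_that("dominance tallies use the largest share, fixed tie priority, and scale invariance", {
  f <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3), c(0.1, 0.2, 0.7))
  p <- exact_pairs(zhejiang_params("2014-2019"), f)
  tal <- tally_dominant_groups(p, "former")
  expect_equal(unname(tal$counts), c(1L, 1L, 1L))
  expect_equal(tal$total, 3L)
  expect_equal(tal$ties, 0L)

  # exact two-way tie resolves pine > fir and is flagged
  pt <- exact_pairs(zhejiang_params("2014-2019"), rbind(c(0.5, 0.5, 0)))
  tt <- tally_dominant_groups(pt, "former")
  expect_equal(unname(tt$counts), c(1L, 0L, 0L))
  expect_equal(tt$ties, 1L)

  # single plot fully pine
  t1 <- tally_dominant_groups(exact_pairs(zhejiang_params("2014-2019"),
                                          rbind(c(1, 0, 0))), "former")
  expect_equal(unname(t1$counts), c(1L, 0L, 0L))

  # invariant to uniform biomass rescaling within a plot
  b <- data.frame(plot_id = rep(c("A", "B"), each = 2),
                  year = rep(c(2014, 2019), 2),
                  pine_biomass = c(4, 4, 1, 1), fir_biomass = c(2, 2, 5, 5),
                  broadleaf_biomass = c(1, 1, 2, 2))
  b2 <- b
  b2[b2$plot_id == "A", 3:5] <- b2[b2$plot_id == "A", 3:5] * 137.5
  tA <- tally_dominant_groups(pair_surveys(b, c(2014, 2019)), "former")
  tB <- tally_dominant_groups(pair_surveys(b2, c(2014, 2019)), "former")
  expect_equal(tA$counts, tB$counts)
})

test_that("plot tables and species maps round-trip through their file formats", {
  cfg <- synthetic_config(n_plots = 8, n_surveys = 3, seed = 11)
  panel <- generate_panel(cfg)
  for (sep in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_plot_table(panel, path, sep = sep)
    back <- read_plot_table(path)
    expect_equal(back$plot_id, panel$plot_id)
    expect_equal(as.matrix(back[c("pine", "fir", "broadleaf")]),
                 as.matrix(panel[c("pine", "fir", "broadleaf")]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  path <- withr::local_tempfile(fileext = ".yaml")
  write_species_map(species_group_map(), path)
  map2 <- read_species_map(path)
  expect_equal(classify_species_group("Pinus elliottii", map2), "pine")
})
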