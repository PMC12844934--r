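test_that("measurement tables validate keys, units and values", {
  ok <- data.frame(site_id = "S1", tree_id = "T1", compartment = "leaf",
                   analyte = "Cd", value = 0.11, units = "mg/kg")
  tab <- measurement_table(ok)
  expect_s3_class(tab, "measurement_table")
  expect_equal(nrow(tab), 1)

  expect_error(measurement_table(rbind(ok, ok)), "duplicate")
  bad_units <- rbind(ok, transform(ok, tree_id = "T2", units = "ug/kg"))
  expect_error(measurement_table(bad_units), "inconsistent units")
  expect_error(measurement_table(transform(ok, value = -1)), "negative")
  expect_error(measurement_table(transform(ok, value = Inf)), "non-finite")
  expect_error(measurement_table(transform(ok, compartment = "root")),
               "compartment")
  # missing values are allowed, explicitly
  expect_silent(measurement_table(transform(ok, value = NA_real_)))
})

test_that("long CSV round-trips bit-exactly and wide CSV melts", {
  set.seed(42)
  n <- 30
  tab <- measurement_table(data.frame(
    site_id = rep(sprintf("S%d", 1:5), each = 6),
    tree_id = rep(sprintf("T%d", 1:3), 10),
    compartment = "leaf",
    analyte = rep(c("Cd", "Pb"), 15),
    value = exp(rnorm(n)), units = "mg/kg"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements(tab, f)
  back <- load_measurements(f, "long")
  expect_identical(back$value, tab$value)  # bit-exact via 17 sig digits
  expect_identical(as.data.frame(back), as.data.frame(tab))

  # wide: 2 trees x 2 analytes -> 4 long records
  fw <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,tree_id,Cd,Pb",
               "S1,T1,0.1,0.5", "S1,T2,0.2,0.6"), fw)
  wtab <- load_measurements(fw, "wide")
  expect_equal(nrow(wtab), 4)
  expect_setequal(wtab$analyte, c("Cd", "Pb"))
  expect_equal(wtab$value[wtab$analyte == "Cd" & wtab$tree_id == "T2"], 0.2)

  # non-numeric cell reported with coordinates
  fbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,tree_id,Cd", "S1,T1,oops"), fbad)
  expect_error(load_measurements(fbad, "wide"), "non-numeric.*Cd")
})

test_that("site summaries compute mean and n-1 SEM", {
  tab <- measurement_table(data.frame(
    site_id = c(rep("S1", 4), rep("S2", 4), "S3"),
    tree_id = c(sprintf("T%d", 1:4), sprintf("T%d", 1:4), "T1"),
    compartment = "leaf", analyte = "X",
    value = c(3, 3, 3, 3, 1, 2, 3, 4, 7), units = "%"))
  s <- summarize_sites(tab, "X", "leaf")
  expect_equal(s$mean, c(3, 2.5, 7))
  # sd({1,2,3,4}) = 1.2909944..., / sqrt(4)
  expect_equal(s$sem[1], 0)
  expect_equal(s$sem[2], 0.6454972243679028, tolerance = 1e-12)
  expect_true(is.na(s$sem[3]))  # n = 1: SEM undefined, not 0
  expect_equal(s$n, c(4L, 4L, 1L))
  expect_error(summarize_sites(tab, "missing", "leaf"), "not present")
})

test_that("grand summaries aggregate site means with lexicographic ties", {
  s <- data.frame(site_id = c("S1", "S2", "S3"), analyte = "X",
                  mean = c(1, 2, 3))
  g <- grand_summary(s)
  expect_equal(g$grand_mean, 2)
  expect_equal(g$min_site$site_id, "S1")
  expect_equal(g$max_site$site_id, "S3")
  # tie broken lexicographically
  g2 <- grand_summary(data.frame(site_id = c("S7", "S1"), analyte = "X",
                                 mean = c(5, 5)))
  expect_equal(g2$min_site$site_id, "S1")
  expect_equal(g2$max_site$site_id, "S1")
  # single site: identity
  g3 <- grand_summary(s[1, ])
  expect_equal(g3$grand_mean, 1)
  expect_error(grand_summary(transform(s, analyte = c("X", "Y", "X"))),
               "mixed analytes")
})

test_that("balanced designs make tree-level and site-mean grand means agree", {
  tab <- generate_orchard_dataset(orchard_sim_config(seed = 9))
  for (a in c("Cd", "N", "SPAD")) {
    s <- summarize_sites(tab, a, "leaf")
    tree_mean <- mean(tab$value[tab$analyte == a & tab$compartment == "leaf"])
    expect_equal(grand_summary(s)$grand_mean, tree_mean, tolerance = 1e-12)
  }
})

test_that("star codes use strict boundaries", {
  expect_equal(star_code(c(0.0005, 0.005, 0.03, 0.05, 0.2)),
               c("***", "**", "*", "ns", "ns"))
  expect_equal(star_code(c(0.001, 0.01)), c("**", "*"))  # strict at bounds
  expect_error(star_code(-0.1), "0, 1")
  expect_error(star_code(1.1), "0, 1")
})

test_that("packaged fixtures reproduce the published site summaries", {
  leaf <- leaf_site_summaries()
  expect_equal(nrow(leaf), 20 * 17)
  s1n <- leaf[leaf$site_id == "S1" & leaf$analyte == "N", ]
  expect_equal(s1n$mean, 3.06)
  expect_equal(s1n$sem, 0.11)
  expect_equal(leaf$mean[leaf$site_id == "S17" & leaf$analyte == "Cd"], 0.31)

  baf <- baf_site_summaries()
  expect_equal(nrow(baf), 20 * 7)
  expect_equal(baf$mean[baf$site_id == "S5" & baf$element == "Cd"], 6.71)
  expect_equal(baf$mean[baf$site_id == "S17" & baf$element == "Mn"], 37.29)
})
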