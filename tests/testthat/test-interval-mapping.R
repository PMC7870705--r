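map4 <- marker_map(paste0("m", 1:4))

test_that("marker maps validate order and positions", {
  expect_error(marker_map("m1"), "at least two")
  expect_error(marker_map(c("m1", "m1")), "unique")
  expect_error(marker_map(c("m1", "m2"), bp = c(5, 5)), "strictly increase")
  expect_error(marker_map(c("m1", "m2"), cm = c(2, 1)), "strictly increase")
  m <- marker_map(c("a", "b"), bp = c(1, 10), cm = c(0, 1))
  expect_s3_class(m, "marker_map")
})

test_that("breakpoints are located between adjacent informative calls", {
  expect_equal(nrow(breakpoint_intervals(c("T", "T", "T", "T"), map4)), 0)
  bp <- breakpoint_intervals(c("T", "T", "H", "H"), map4)
  expect_equal(bp$left, "m2")
  expect_equal(bp$right, "m3")
  # widened across a missing call
  bp <- breakpoint_intervals(c("T", "-", "H", "H"), map4)
  expect_equal(bp$left, "m1")
  expect_equal(bp$right, "m3")
  # two breakpoints
  bp <- breakpoint_intervals(c("T", "H", "H", "T"), map4)
  expect_equal(nrow(bp), 2)
  expect_error(breakpoint_intervals(c("-", "-", "-", "-"), map4),
               "missing")
  expect_error(breakpoint_intervals(c("T", "X", "H", "H"), map4),
               "Unknown")
})

test_that("a single recombinant constrains the locus past its breakpoint", {
  rec <- tibble::tibble(plant_id = "p1", m1 = "T", m2 = "T", m3 = "H",
                        m4 = "H", phenotype = "SS")
  ci <- delimit_locus(rec, map4)
  expect_equal(ci$intervals$left, "m2")
  expect_equal(ci$intervals$right, "m4")
  expect_true(ci$intervals$left_open)
  expect_false(ci$intervals$right_open)   # closed at the map end
  expect_equal(ci$informative, "p1")
})

test_that("disjoint constraints raise a conflicting-recombinants error", {
  # het segments confined to opposite map ends with excluded markers
  # between them: no position can satisfy both semi-sterile plants
  recs <- tibble::tibble(
    plant_id = c("p1", "p2"),
    m1 = c("T", "H"), m2 = c("T", "T"), m3 = c("T", "T"), m4 = c("H", "T"),
    phenotype = c("SS", "SS"))
  expect_error(delimit_locus(recs, map4), "Conflicting recombinants.*p2")
  # homozygous-wild calls are impossible at the locus under 1:1:0 and
  # exclude their span: q2's G calls at m2/m3 split the allowed region
  recs2 <- tibble::tibble(
    plant_id = c("q1", "q2"),
    m1 = c("T", "H"), m2 = c("H", "G"), m3 = c("H", "G"), m4 = c("H", "H"),
    phenotype = c("SS", "SS"))
  expect_warning(ci <- delimit_locus(recs2, map4), "non-contiguous")
  expect_equal(nrow(ci$intervals), 2)
  expect_equal(ci$intervals$left[2], "m3")
  expect_equal(ci$intervals$right[2], "m4")
})

test_that("opposed breakpoints in one gap resolve to that bare gap", {
  # both semi-sterile constraints are satisfiable only strictly between
  # m2 and m3: fine mapping legitimately ends in a marker-free interval
  recs <- tibble::tibble(
    plant_id = c("p1", "p2"),
    m1 = c("T", "H"), m2 = c("T", "H"), m3 = c("H", "T"), m4 = c("H", "T"),
    phenotype = c("SS", "SS"))
  ci <- delimit_locus(recs, map4)
  expect_equal(ci$intervals$left, "m2")
  expect_equal(ci$intervals$right, "m3")
  expect_true(ci$intervals$left_open)
  expect_true(ci$intervals$right_open)
})

test_that("non-recombinant plants span the whole map and are uninformative", {
  recs <- tibble::tibble(
    plant_id = c("p1", "p2"),
    m1 = c("H", "T"), m2 = c("H", "T"), m3 = c("H", "T"), m4 = c("H", "T"),
    phenotype = c("SS", "N"))
  ci <- delimit_locus(recs, map4)
  expect_equal(ci$intervals$left, "m1")
  expect_equal(ci$intervals$right, "m4")
  expect_false(ci$intervals$left_open)
  expect_false(ci$intervals$right_open)
  expect_length(ci$informative, 0)
})

test_that("the synthetic recombinant fixture delimits the expected window", {
  map <- read_map_tsv(system.file("extdata", "marker_map_synthetic.tsv",
                                  package = "gametx"))
  recs <- read_marker_tsv(system.file("extdata",
                                      "recombinants_synthetic.tsv",
                                      package = "gametx"), map)
  expect_equal(nrow(recs), 5)
  ci <- delimit_locus(recs, map)
  expect_equal(ci$intervals$left, "M4")
  expect_equal(ci$intervals$right, "M6")
  expect_true(ci$intervals$left_open)
  expect_true(ci$intervals$right_open)
  # 9-7 sets the left boundary, 23-2 the right; 39-7 excludes markers
  # m1-m4 but cannot rule the locus out of the gaps between them (a
  # plant-level double crossover could hide a homozygous tract there),
  # so it does not itself pin a boundary
  expect_setequal(ci$informative, c("9-7", "23-2"))
  expect_equal(ci$span_bp, 166000 - 104000)
  expect_true(locus_in_interval(ci, "M4"))
  expect_false(locus_in_interval(ci, "M6"))
})

test_that("adding records never widens the interval (monotone refinement)", {
  map <- marker_map(paste0("m", 1:6))
  withr::with_seed(61, {
    sim <- simulate_marker_population(
      marker_map(paste0("m", 1:6), cm = seq(0, 10, by = 2)),
      locus_cm = 5, n = 120, k = 0, seed = 99)
    ci_all <- suppressWarnings(delimit_locus(sim, map))
    for (m in c(20, 60, 100)) {
      ci_sub <- suppressWarnings(delimit_locus(sim[seq_len(m), ], map))
      # every slot allowed by the full set is allowed by the subset
      expect_true(all(ci_sub$slots[ci_all$slots]))
    }
  })
})

test_that("record order does not change the delimited interval", {
  map <- marker_map(paste0("m", 1:6), cm = seq(0, 10, by = 2))
  sim <- simulate_marker_population(map, locus_cm = 5, n = 80, k = 0,
                                    seed = 17)
  ci1 <- delimit_locus(sim, map)
  withr::with_seed(62, {
    ci2 <- delimit_locus(sim[sample(nrow(sim)), ], map)
  })
  expect_equal(ci1$intervals, ci2$intervals)
  expect_setequal(ci1$informative, ci2$informative)
})

test_that("morphology subclass labels are accepted as semi-sterile", {
  rec <- tibble::tibble(m1 = "T", m2 = "H", m3 = "H", m4 = "H",
                        phenotype = "S22B_SS")
  ci <- delimit_locus(rec, map4)
  expect_equal(ci$intervals$left, "m1")
  expect_error(
    delimit_locus(tibble::tibble(m1 = "T", m2 = "T", m3 = "T", m4 = "T",
                                 phenotype = "odd"), map4),
    "phenotype")
})

test_that("recombinant yield and rate estimation are exact-binomial", {
  expect_equal(recombinant_yield(7424, 308 / 7424), 308)
  expect_equal(recombinant_yield(7424, 0), 0)
  est <- estimate_recomb_rate(308, 7424)
  bt <- binom.test(308, 7424)$conf.int
  expect_equal(est$estimate, 308 / 7424)
  expect_equal(est$ci_low, bt[1], tolerance = 1e-10)
  expect_equal(est$ci_high, bt[2], tolerance = 1e-10)
  expect_error(estimate_recomb_rate(10, 5), "exceed")
})
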