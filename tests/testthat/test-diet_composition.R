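test_that("gut filtering excludes empty and non-identifiable-only guts", {
  fish <- data.frame(fish_id = c("a", "b", "c", "d"),
                     stringsAsFactors = FALSE)
  recs <- data.frame(
    fish_id = c("a", "b", "b", "c"),
    taxon = "x", family = "y",
    prey_group = c(NA, "crabs", NA, NA),
    count = 1L, dry_weight = 0.1,
    content_flag = c("bait", "identifiable", "chyme", "inorganic"),
    stringsAsFactors = FALSE)
  flt <- filter_guts(recs, fish)
  expect_identical(flt$included, "b")  # crab + chyme keeps the gut
  ex <- flt$excluded
  expect_identical(ex$reason[ex$fish_id == "a"], "bait-only")
  expect_identical(ex$reason[ex$fish_id == "c"], "inorganic-only")
  expect_identical(ex$reason[ex$fish_id == "d"], "empty")
  recs$fish_id[1] <- "zzz"
  expect_error(filter_guts(recs, fish), "unknown fish")
})

test_that("rare prey groups are dropped at the dry-weight threshold", {
  recs <- data.frame(
    fish_id = "f", taxon = "t", family = "fa",
    prey_group = c("A", "B", "C"),
    count = 1L,
    dry_weight = c(98.5, 1.0, 0.5),
    content_flag = "identifiable", stringsAsFactors = FALSE)
  rp <- restrict_prey_groups(recs, threshold_pct = 1)
  expect_setequal(rp$retained, c("A", "B"))  # exactly 1.0% is kept (>= rule)
  expect_equal(unname(rp$shares["C"]), 0.5)
  one <- recs[1, ]
  expect_identical(restrict_prey_groups(one)$retained, "A")
  none <- recs; none$content_flag <- "chyme"
  expect_error(restrict_prey_groups(none), "no identifiable content")
})

test_that("composition metrics match the two-gut hand computation", {
  cs <- composition_summary(two_gut_records(), c("f1", "f2"))
  a <- cs[cs$prey_group == "A", ]; b <- cs[cs$prey_group == "B", ]
  expect_equal(a$pct_fo, 100); expect_equal(b$pct_fo, 50)
  expect_equal(a$pct_n, 75);   expect_equal(b$pct_n, 25)
  expect_equal(a$pct_w, 75);   expect_equal(b$pct_w, 25)
  expect_equal(sum(cs$pct_n), 100, tolerance = 1e-9)
  expect_equal(sum(cs$pct_w), 100, tolerance = 1e-9)
  # a group absent from every gut reports zeros
  cs3 <- composition_summary(two_gut_records(), c("f1", "f2"),
                             prey_groups = c("A", "B", "Z"))
  expect_equal(unlist(cs3[cs3$prey_group == "Z", c("pct_fo", "pct_n", "pct_w")]),
               c(pct_fo = 0, pct_n = 0, pct_w = 0))
  # single gut, single group: all metrics 100
  one <- composition_summary(two_gut_records()[1, ], "f1")
  expect_equal(unlist(one[, c("pct_fo", "pct_n", "pct_w")]),
               c(pct_fo = 100, pct_n = 100, pct_w = 100))
})

test_that("%IRI integrates the three measures and normalizes to 100", {
  cs <- percent_iri(composition_summary(two_gut_records(), c("f1", "f2")))
  # IRI_A = (75 + 75) * 100 = 15000; IRI_B = (25 + 25) * 50 = 2500
  expect_equal(cs$iri[cs$prey_group == "A"], 15000)
  expect_equal(cs$iri[cs$prey_group == "B"], 2500)
  expect_equal(cs$pct_iri[cs$prey_group == "A"], 85.71, tolerance = 1e-4)
  expect_equal(cs$pct_iri[cs$prey_group == "B"], 14.29, tolerance = 1e-3)
  expect_equal(sum(cs$pct_iri), 100, tolerance = 1e-9)
  # symmetric groups split 50/50
  sym <- data.frame(prey_group = c("A", "B"), pct_fo = 50, pct_n = 50,
                    pct_w = 50)
  expect_equal(percent_iri(sym)$pct_iri, c(50, 50))
  zero <- data.frame(prey_group = "A", pct_fo = 0, pct_n = 0, pct_w = 0)
  expect_error(percent_iri(zero), "no identifiable prey")
})

test_that("Bray-Curtis on sqrt-%W behaves as a bounded semimetric", {
  w <- rbind(c(100, 0), c(0, 100), c(100, 0))
  rownames(w) <- c("g1", "g2", "g3"); colnames(w) <- c("A", "B")
  d <- braycurtis_matrix(w)
  expect_equal(unname(d["g1", "g3"]), 0)           # identical rows
  expect_equal(unname(d["g1", "g2"]), 1)           # disjoint rows
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  # hand example: raw (4,0) and (1,1) -> sqrt (2,0),(1,1) -> BC = 0.5
  w2 <- rbind(c(4, 0), c(1, 1))
  d2 <- braycurtis_matrix(w2)
  expect_equal(unname(d2[1, 2]), 0.5, tolerance = 1e-12)
  expect_error(braycurtis_matrix(rbind(c(0, 0), c(1, 1))), "all zeros")
})

test_that("%W, %IRI and Bray-Curtis are invariant to a global weight scale", {
  set.seed(9)
  recs <- two_gut_records()
  recs2 <- recs; recs2$dry_weight <- recs2$dry_weight * 137.5
  cs1 <- percent_iri(composition_summary(recs, c("f1", "f2")))
  cs2 <- percent_iri(composition_summary(recs2, c("f1", "f2")))
  expect_equal(cs1$pct_w, cs2$pct_w)
  expect_equal(cs1$pct_iri, cs2$pct_iri)
  w1 <- percent_weight_matrix(recs, c("f1", "f2"))
  w2 <- percent_weight_matrix(recs2, c("f1", "f2"))
  expect_equal(braycurtis_matrix(w1), braycurtis_matrix(w2))
})

test_that("size classes follow the species fork-length breakpoints", {
  expect_identical(
    assign_size_class(rep("gray_triggerfish", 4), c(150, 183, 200, 300)),
    c("juvenile", "juvenile", "sub_adult", "adult"))
  expect_identical(
    assign_size_class(rep("red_snapper", 4), c(150, 222, 300, 400)),
    c("juvenile", "juvenile", "sub_adult", "adult"))
  expect_error(assign_size_class("tuna", 100), "unknown species")
})
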