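test_that("the packaged hierarchy is total and structured as expected", {
  h <- cheetah_hierarchy()
  expect_equal(nrow(h), 17)
  expect_false(anyNA(h))
  expect_setequal(h$coarse, c("active", "inactive", "head movement", "other"))
  sed <- h$fine[h$medium == "sedentary"]
  expect_setequal(sed, c("crouch", "lie", "sit", "stand"))
  expect_setequal(h$fine[h$medium == "moving stalk"],
                  c("walking stalk", "trotting stalk"))
  expect_setequal(h$fine[h$coarse == "active"],
                  c("walk", "trot", "canter", "gallop", "walking stalk",
                    "trotting stalk", "pounce"))
  expect_setequal(h$fine[h$coarse == "inactive"],
                  c("crouch", "lie", "sit", "stand", "crouching stalk",
                    "lying stalk", "sitting stalk", "standing stalk"))
  # pounce joins the rag-bag at medium resolution
  expect_equal(h$medium[h$fine == "pounce"], "other")
  expect_equal(h$medium[h$fine == "other"], "other")
})

test_that("hierarchy construction validates its input", {
  expect_error(behaviour_hierarchy(data.frame(fine = "a")), "columns")
  expect_error(behaviour_hierarchy(
    data.frame(fine = c("a", "a"), medium = "m", coarse = "c")), "duplicated")
  expect_error(behaviour_hierarchy(
    data.frame(fine = c("a", "other"), medium = c(NA, "other"),
               coarse = c("c", "other"))), "total")
  expect_error(behaviour_hierarchy(
    data.frame(fine = "other", medium = "x", coarse = "other")),
    "'other' must map")
})

test_that("interval labels align half-open onto the sample grid", {
  tr <- tibble::tibble(time_s = seq(0, 9.9, by = 0.1),
                       heave_g = 1, surge_g = 0, sway_g = 0)
  iv <- tibble::tibble(start_s = c(0, 4), end_s = c(4, 8),
                       behaviour = c("lie", "walk"))
  labs <- align_labels(tr, iv)
  expect_equal(nrow(labs), nrow(tr))
  # boundary sample at exactly 4 s belongs to the later interval
  expect_equal(labs$behaviour[which.min(abs(labs$time_s - 4))], "walk")
  expect_equal(labs$behaviour[which.min(abs(labs$time_s - 3.9))], "lie")
  # uncovered tail is unassignable
  expect_true(all(labs$behaviour[labs$time_s >= 8] == "unassignable"))
  # single covering interval labels everything
  all_iv <- tibble::tibble(start_s = 0, end_s = 10, behaviour = "sit")
  expect_true(all(align_labels(tr, all_iv)$behaviour == "sit"))
})

test_that("random interval sets match a per-sample linear-scan oracle", {
  withr::with_seed(41, {
    tr <- tibble::tibble(time_s = sort(runif(500, 0, 100)),
                         heave_g = 1, surge_g = 0, sway_g = 0)
    edges <- sort(runif(11, 0, 100))
    keep <- sort(sample(10, 6))
    iv <- tibble::tibble(start_s = edges[keep], end_s = edges[keep + 1],
                         behaviour = paste0("b", keep))
    got <- align_labels(tr, iv)$behaviour
    oracle <- vapply(tr$time_s, function(t) {
      hit <- which(t >= iv$start_s & t < iv$end_s)
      if (length(hit) == 0) "unassignable" else iv$behaviour[hit[1]]
    }, character(1))
    expect_equal(got, oracle)
  })
})

test_that("overlapping intervals are reported", {
  tr <- tibble::tibble(time_s = 0:10, heave_g = 1, surge_g = 0, sway_g = 0)
  iv <- tibble::tibble(start_s = c(0, 3), end_s = c(5, 8),
                       behaviour = c("a", "b"))
  expect_error(align_labels(tr, iv), "overlap")
})

test_that("drop_unassignable removes exactly the unassignable rows", {
  d <- tibble::tibble(x = 1:6,
                      behaviour = c("lie", "unassignable", "walk",
                                    "unassignable", "lie", "walk"))
  out <- suppressMessages(drop_unassignable(d))
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "removed"), 2)
  clean <- tibble::tibble(x = 1:3, behaviour = "lie")
  expect_equal(nrow(drop_unassignable(clean)), 3)
  allbad <- tibble::tibble(x = 1, behaviour = "unassignable")
  expect_warning(suppressMessages(drop_unassignable(allbad)), "empty")
})

test_that("collapsing reproduces the published aggregate counts", {
  counts <- cheetah_event_counts()
  for (device in c("cefas", "gcdc")) {
    fine <- rep(counts$behaviour, counts[[device]])
    med <- count_by_label(collapse_labels(fine, "medium"))
    coa <- count_by_label(collapse_labels(fine, "coarse"))
    if (device == "cefas") {
      expect_equal(med$n[med$behaviour == "sedentary"], 48925L)
      expect_equal(med$n[med$behaviour == "moving stalk"], 4291L)
      expect_equal(coa$n[coa$behaviour == "active"], 19517L)
    } else {
      expect_equal(med$n[med$behaviour == "sedentary"], 83228L)
      expect_equal(med$n[med$behaviour == "moving stalk"], 7261L)
      expect_equal(coa$n[coa$behaviour == "inactive"], 105729L)
    }
    # conservation at every level
    expect_equal(sum(med$n), length(fine))
    expect_equal(sum(coa$n), length(fine))
  }
})

test_that("collapsing is idempotent by level and errors on unknown labels", {
  fine <- c("lie", "walk", "pounce", "other")
  coarse <- collapse_labels(fine, "coarse")
  expect_equal(collapse_labels(coarse, "coarse"), coarse)
  medium <- collapse_labels(fine, "medium")
  expect_equal(collapse_labels(medium, "medium"), medium)
  expect_equal(collapse_labels(character(), "coarse"), character())
  expect_error(collapse_labels("teleport", "coarse"), "teleport")
})

test_that("random fine multisets collapse to brute-force category sums", {
  h <- cheetah_hierarchy()
  withr::with_seed(43, {
    fine <- sample(h$fine, 2000, replace = TRUE)
    got <- count_by_label(collapse_labels(fine, "medium"))
    oracle <- table(sapply(fine, function(b) h$medium[h$fine == b]))
    for (lbl in names(oracle)) {
      expect_equal(got$n[got$behaviour == lbl], as.integer(oracle[[lbl]]))
    }
  })
})

test_that("count_by_label counts exactly", {
  expect_equal(count_by_label(rep("lie", 7)),
               tibble::tibble(behaviour = "lie", n = 7L))
  labs <- tibble::tibble(time_s = 1:3, behaviour = c("a", "b", "a"))
  out <- count_by_label(labs)
  expect_equal(out$n[out$behaviour == "a"], 2L)
})

test_that("label tracks join features positionally", {
  f <- tibble::tibble(time_s = 1:3, heave = 1)
  labs <- tibble::tibble(time_s = 1:3, behaviour = c("a", "b", "a"))
  out <- label_features(f, labs, device = "CEFAS")
  expect_equal(out$behaviour, c("a", "b", "a"))
  expect_error(label_features(f, labs[1:2, ]), "lengths differ")
})
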