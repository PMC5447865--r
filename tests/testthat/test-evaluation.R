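# Fuzzy accuracy assessment: MAX / RIGHT / producer's metrics, combined
# classes and the methods comparison table.

# a 2 m x 2 m raster at 0.1 m: columns 1-10 medusahead, 11-20 vetch
two_class_result <- function() {
  cr <- matrix(2L, 20, 20)       # classes sorted: medusahead=1, vetch=2
  cr[, 1:10] <- 1L
  painted_result(cr, c("medusahead", "vetch"), pixel_size_m = 0.1)
}

test_that("a perfect classification scores 1 on every metric", {
  res <- two_class_result()
  s <- make_samples(x = c(0.5, 0.5, 1.5, 1.5), y = c(0.5, 1.5, 0.5, 1.5),
                    best = c("medusahead", "medusahead", "vetch", "vetch"))
  rep <- evaluate_fuzzy(res, s, square_size_m = 0.3)
  expect_equal(rep$max_metric, 1)
  expect_equal(rep$right_metric, 1)
  expect_equal(rep$producer, 1)
  expect_equal(rep$diff, 0)
})

test_that("MAX and RIGHT follow the hand-counted 3-sample fixture", {
  # three samples classified medusahead; best = {target, vetch, clover};
  # only the vetch sample lists the target acceptable
  res <- two_class_result()
  s <- make_samples(
    x = c(0.3, 0.6, 0.9), y = c(0.5, 1.0, 1.5),
    best = c("medusahead", "vetch", "clover_brome"),
    acceptable = list(character(0), "medusahead", character(0)))
  rep <- evaluate_fuzzy(res, s)
  expect_equal(rep$n_predicted, 3L)
  expect_equal(rep$max_metric, 1 / 3)
  expect_equal(rep$right_metric, 2 / 3)
  expect_equal(rep$diff, 1 / 3)
})

test_that("RIGHT minus MAX reproduces the published worst-case row", {
  # the published table's SVM 3-class spectral row: MAX 0.23, RIGHT 0.67
  tab <- published_accuracy_table("fuzzy")
  row <- tab[tab$method == "Supervised SVM 3 classes" &
               tab$texture == "no", ]
  expect_equal(row$max, 0.23)
  expect_equal(row$right, 0.67)
  expect_equal(round(row$right - row$max, 2), 0.44)
})

test_that("zero predicted-target samples yield NA metrics, not zero", {
  cr <- matrix(1L, 10, 10)
  res <- painted_result(cr, "vetch", pixel_size_m = 0.1)
  s <- make_samples(x = c(0.3, 0.6), y = c(0.3, 0.6),
                    best = c("medusahead", "vetch"))
  rep <- evaluate_fuzzy(res, s)
  expect_true(is.na(rep$max_metric))
  expect_true(is.na(rep$right_metric))
  expect_equal(rep$n_predicted, 0L)
  expect_equal(rep$producer, 0)        # the target sample found nothing
})

test_that("RIGHT >= MAX and order invariance hold on random fixtures", {
  set.seed(31)
  for (i in 1:10) {
    cr <- matrix(sample(1:3, 400, replace = TRUE), 20, 20)
    res <- painted_result(cr, c("medusahead", "vetch", "clover_brome"),
                          pixel_size_m = 0.1)
    n <- 30
    s <- make_samples(
      x = runif(n, 0.2, 1.8), y = runif(n, 0.2, 1.8),
      best = sample(c("medusahead", "vetch", "clover_brome"), n, TRUE),
      acceptable = lapply(seq_len(n), function(j)
        if (runif(1) < 0.4) "medusahead" else character(0)))
    s$acceptable <- lapply(seq_len(n), function(j)
      setdiff(s$acceptable[[j]], s$best_class[j]))
    rep <- evaluate_fuzzy(res, s)
    if (!is.na(rep$max_metric))
      expect_gte(rep$right_metric, rep$max_metric)
    perm <- sample(n)
    rep2 <- evaluate_fuzzy(res, s[perm, ])
    expect_equal(rep2$max_metric, rep$max_metric)
    expect_equal(rep2$producer, rep$producer)
  }
})

test_that("adding a correct sample never hurts MAX or RIGHT", {
  res <- two_class_result()
  s <- make_samples(x = c(0.3, 0.6), y = c(0.5, 1.0),
                    best = c("medusahead", "vetch"))
  base <- evaluate_fuzzy(res, s)
  s2 <- rbind(s, make_samples(x = 0.9, y = 1.5, best = "medusahead"))
  more <- evaluate_fuzzy(res, s2)
  expect_gte(more$max_metric, base$max_metric)
  expect_gte(more$right_metric, base$right_metric)
})

test_that("combined-class metrics dominate when confusions are internal", {
  # classifier swaps medusahead and goatgrass wholesale
  cr <- matrix(2L, 20, 20)
  cr[, 1:10] <- 1L               # classes: barbed_goatgrass=1, medusahead=2
  res <- painted_result(cr, c("barbed_goatgrass", "medusahead"),
                        pixel_size_m = 0.1)
  # truth: left half medusahead, right half goatgrass (i.e. all swapped)
  s <- make_samples(
    x = c(0.3, 0.6, 1.3, 1.6), y = c(0.5, 1.0, 0.5, 1.0),
    best = c("medusahead", "medusahead", "barbed_goatgrass",
             "barbed_goatgrass"))
  sep <- evaluate_fuzzy(res, s)
  comb <- evaluate_combined(res, s)
  expect_equal(sep$max_metric, 0)        # every prediction swapped
  expect_equal(comb$max_metric, 1)       # merged class absorbs the swap
  expect_gte(comb$right_metric, sep$right_metric)
  expect_gte(comb$producer, sep$producer)
})

test_that("merging a class with itself leaves the report unchanged", {
  res <- two_class_result()
  s <- make_samples(x = c(0.3, 1.3), y = c(0.5, 0.5),
                    best = c("medusahead", "vetch"))
  a <- evaluate_fuzzy(res, s)
  b <- evaluate_combined(res, s, merge = "medusahead")
  expect_equal(b$max_metric, a$max_metric)
  expect_equal(b$producer, a$producer)
})

test_that("confusions only with non-merged classes leave metrics equal", {
  # predictions confuse medusahead with vetch (not in the merge set)
  cr <- matrix(1L, 20, 20)       # everything predicted medusahead
  res <- painted_result(cr, "medusahead", pixel_size_m = 0.1)
  s <- make_samples(x = c(0.3, 0.6, 1.3), y = c(0.5, 1.0, 0.5),
                    best = c("medusahead", "vetch", "clover_brome"))
  a <- evaluate_fuzzy(res, s)
  b <- evaluate_combined(res, s)
  expect_equal(b$max_metric, a$max_metric)
  expect_equal(b$right_metric, a$right_metric)
})

test_that("tabulate_methods reports per-method rows and metric ranges", {
  res <- two_class_result()
  s <- make_samples(x = c(0.3, 0.6, 1.3), y = c(0.5, 1.0, 0.5),
                    best = c("medusahead", "vetch", "clover_brome"),
                    acceptable = list(character(0), "medusahead",
                                      character(0)))
  r1 <- evaluate_fuzzy(res, s)
  tab1 <- tabulate_methods(list(r1))
  expect_equal(nrow(tab1), 1L)
  expect_equal(attr(tab1, "ranges")$max, rep(r1$max_metric, 2))
  expect_equal(nrow(tabulate_methods(list())), 0L)
})
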