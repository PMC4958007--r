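test_that("within/between ratio is 1 for homogeneous data and detects structure", {
  bg <- stats::setNames(sprintf("%dcT", 5000 + 10 * (1:2)), c("B1", "B2"))
  same <- list(c("100aG", "200cT"))
  d <- mut_dataset(make_calls(
    stats::setNames(rep(list(same), 4), c("a1", "a2", "b1", "b2")),
    list(a1 = "B1", a2 = "B1", b1 = "B2", b2 = "B2")), bg)
  res <- within_between_test(d, n_boot = 99, seed = 1)
  expect_equal(res$ratio, 1)

  # planted: a shared hotspot everywhere plus background-private mutations
  keys <- abstract_keys(8)
  wa <- list(keys[c(7, 1:3)])
  wb <- list(keys[c(7, 4:6)])
  d2 <- mut_dataset(make_calls(
    list(a1 = wa, a2 = wa, a3 = wa, a4 = wa,
         b1 = wb, b2 = wb, b3 = wb, b4 = wb),
    list(a1 = "B1", a2 = "B1", a3 = "B1", a4 = "B1",
         b1 = "B2", b2 = "B2", b3 = "B2", b4 = "B2")), bg)
  res2 <- within_between_test(d2, n_boot = 999, seed = 2)
  expect_gt(res2$mean_within, res2$mean_between)
  expect_lt(res2$p_value, 0.05)
  expect_identical(res2$p_value,
                   within_between_test(d2, n_boot = 999, seed = 2)$p_value)
})

test_that("the mutation-background LRT matches a direct likelihood evaluation", {
  # one mutation present in all 8 wells of one background, absent from 60
  bgs <- stats::setNames(sprintf("%dcT", 5000 + 10 * (1:2)), c("B1", "B2"))
  wells <- list()
  bg_of <- list()
  for (i in 1:8) {
    w <- sprintf("a%02d", i)
    wells[[w]] <- list(c("100aG", "200cT"))
    bg_of[[w]] <- "B1"
  }
  for (i in 1:60) {
    w <- sprintf("b%02d", i)
    wells[[w]] <- list("200cT")
    bg_of[[w]] <- "B2"
  }
  d <- mut_dataset(make_calls(wells, bg_of), bgs)
  res <- mutation_background_lrt(d, n_perm = 99, seed = 1)

  # independent route: binomial log-likelihoods evaluated directly
  ll_null <- direct_binom_ll(8, 68, 8 / 68)
  ll_alt <- direct_binom_ll(c(8, 0), c(8, 60), c(1, 0))
  expect_equal(unname(res$per_mutation_delta["100aG"]), ll_alt - ll_null)
  # 200cT is present in every well: saturated, contributes exactly zero
  expect_true("200cT" %in% res$saturated)
  expect_equal(unname(res$per_mutation_delta["200cT"]), 0)
  # Lambda additivity and nonnegativity
  expect_equal(res$lambda, sum(res$per_mutation_delta))
  expect_true(all(res$per_mutation_delta >= 0))
})

test_that("a single-background dataset gives Lambda of exactly zero", {
  d <- simulate_dataset(sim_config(c(B1 = "5000cT"), abstract_keys(10),
                                   p = rep(0.3, 10), lambda = 3,
                                   m_range = c(1L, 6L),
                                   wells_per_background = 6L,
                                   isolates_per_well = 4L), seed = 3)$dataset
  res <- mutation_background_lrt(d, n_perm = 19, seed = 1)
  expect_equal(res$lambda, 0)
})

test_that("stepwise removal finds the planted background-exclusive mutation first", {
  sim <- simulate_dataset(planted_cfg(), seed = 31)
  d <- sim$dataset
  sw <- stepwise_influential(d, alpha = 0.05, n_perm = 199, seed = 7)
  expect_gt(nrow(sw), 0)
  expect_equal(sw$key[1], planted_key())
  expect_false(anyDuplicated(sw$key) > 0)
  expect_lt(attr(sw, "p_initial"), 0.05)
})

test_that("the reversion LRT reduces to direct binomial arithmetic", {
  res <- reversion_lrt(c(A = 7, B = 0), c(A = 8, B = 8))
  ll_null <- direct_binom_ll(c(7, 0), c(8, 8), 7 / 16)
  ll_alt <- direct_binom_ll(c(7, 0), c(8, 8), c(7 / 8, 0))
  expect_equal(res$lambda, ll_alt - ll_null)
  expect_equal(res$p_value,
               stats::pchisq(2 * res$lambda, df = 1, lower.tail = FALSE))

  # equal frequencies across backgrounds collapse the models
  res0 <- reversion_lrt(c(A = 2, B = 2, C = 2), c(A = 8, B = 8, C = 8))
  expect_equal(res0$lambda, 0)
  expect_error(reversion_lrt(c(A = 1), c(A = 8)), "two backgrounds")

  # dataset interface agrees with explicit counts
  sim <- simulate_dataset(study_preset(), seed = 41)
  d <- sim$dataset
  flags <- classify_reversions(d)
  by_bg <- split(flags, d$wells$background_id)
  res_d <- reversion_lrt(d)
  res_c <- reversion_lrt(vapply(by_bg, sum, 0), vapply(by_bg, length, 0))
  expect_equal(res_d$lambda, res_c$lambda)
})

test_that("co-occurrence expectations match product-of-marginals on a toy", {
  # two mutations placed independently: 10 wells x 4 isolates; A occupies one
  # isolate in 5 wells, B one isolate in 4 wells
  wells <- list()
  bg_of <- list()
  for (i in 1:10) {
    w <- sprintf("w%02d", i)
    gts <- rep(list(character(0)), 4)
    if (i <= 5) gts[[1]] <- "100aG"
    if (i %in% c(1, 4, 6, 9)) gts[[2]] <- c(gts[[2]], "200cT")
    gts <- lapply(gts, function(g) if (length(g)) g else character(0))
    wells[[w]] <- gts
    bg_of[[w]] <- "B1"
  }
  d <- mut_dataset(make_calls(wells, bg_of), c(B1 = "5000cT"))
  res <- cooccurrence_test(d, n_rand = 2000, seed = 9)
  # null: A in well (p 1/2) x B in same well (p 2/5) x same isolate (1/4)
  analytic <- 10 * 0.5 * 0.4 * 0.25
  row <- res$table[res$table$a == "100aG" & res$table$b == "200cT", ]
  expect_lt(abs(row$expected - analytic), 0.15)

  # planted attraction: a pair that always travels together
  wells2 <- list()
  for (i in 1:10) {
    w <- sprintf("v%02d", i)
    gts <- rep(list("900tA"), 4)
    if (i <= 5) gts[[1]] <- c("100aG", "200cT")
    wells2[[w]] <- gts
    bg_of[[w]] <- "B1"
  }
  d2 <- mut_dataset(make_calls(wells2, stats::setNames(bg_of[1:10],
                                                       names(wells2))),
                    c(B1 = "5000cT"))
  res2 <- cooccurrence_test(d2, n_rand = 500, seed = 10)
  row2 <- res2$table[res2$table$a == "100aG" & res2$table$b == "200cT", ]
  expect_gt(row2$observed, row2$expected)
  expect_lt(row2$p, 0.05)
})

test_that("co-occurrence filtering removes singletons, reversions and 1-count hits", {
  # singleton mutations (1 well) and reversions are never tested
  bg <- c(B1 = "300gT")
  wells <- list(
    w1 = list(c("100aG", "200cT", "300tG"), "100aG"),
    w2 = list(c("100aG", "200cT"), "100aG"),
    w3 = list(c("100aG", "500gA")))
  d <- mut_dataset(make_calls(wells, list(w1 = "B1", w2 = "B1", w3 = "B1")), bg)
  res <- cooccurrence_test(d, n_rand = 200, seed = 2)
  expect_setequal(res$keys, c("100aG", "200cT"))   # 300tG reversion, 500gA singleton
  expect_false("300tG" %in% c(res$table$a, res$table$b))
})

test_that("block aggregation counts any-member and distinct-member co-occurrence", {
  bg <- c(B1 = "5000cT")
  wells <- list(
    w1 = list(c("100aG", "900tA"), "110aG"),
    w2 = list(c("110aG", "900tA"), "100aG"),
    w3 = list(c("100aG", "110aG"), "900tA"),
    w4 = list("900tA", "100aG"))
  d <- mut_dataset(make_calls(wells, stats::setNames(as.list(rep("B1", 4)),
                                                     names(wells))), bg)
  res <- cooccurrence_test(d, n_rand = 200, seed = 3,
                           blocks = list(blk = c("100aG", "110aG")))
  self <- res$blocks[res$blocks$a == "blk" & res$blocks$b == "blk", ]
  expect_equal(self$observed, 1L)  # only w3 has two distinct members in one isolate
  vs <- res$blocks[res$blocks$a == "blk" & res$blocks$b == "900tA", ]
  expect_equal(vs$observed, 2L)    # w1 and w2
})
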