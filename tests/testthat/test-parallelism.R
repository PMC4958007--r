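test_that("pairwise parallelism reproduces the defining arithmetic", {
  bg <- c(B1 = "5000cT")
  d <- mut_dataset(make_calls(
    list(w1 = list(c("100aG", "200cT")), w2 = list("100aG"),
         w3 = list(c("100aG", "200cT")), w4 = list(c("300gT", "400tA"))),
    list(w1 = "B1", w2 = "B1", w3 = "B1", w4 = "B1")), bg)
  P <- pairwise_parallelism(d)$values
  expect_equal(P["w1", "w2"], 0.75)            # (1/2 + 1/1) / 2
  expect_equal(P["w1", "w3"], 1)               # identical sets
  expect_equal(P["w1", "w4"], 0)               # disjoint sets
  expect_equal(P, t(P))
  expect_true(all(diag(P) == 1))
})

test_that("P_ij is bounded, symmetric and unit-diagonal on simulated data", {
  for (s in 1:5) {
    d <- simulate_dataset(null_cfg(), seed = 1200 + s)$dataset
    P <- pairwise_parallelism(d)$values
    off <- P[upper.tri(P)]
    expect_true(all(off >= 0 & off <= 1, na.rm = TRUE))
    expect_equal(P, t(P))
  }
})

test_that("cluster-level parallelism never falls below nucleotide level", {
  for (s in 1:10) {
    d <- simulate_dataset(annotated_cfg(), seed = 1300 + s)$dataset
    Pn <- pairwise_parallelism(d, "nucleotide")$values
    Pc <- pairwise_parallelism(d, "cluster")$values
    ok <- !is.na(Pn) & !is.na(Pc)
    expect_true(all(Pc[ok] >= Pn[ok] - 1e-12))
  }
})

test_that("feature exclusion matches brute force and empties become missing", {
  d <- simulate_dataset(annotated_cfg(), seed = 1401)$dataset
  Px <- pairwise_parallelism(d, exclude_features = "D-promoter")
  dp <- feature_mutations(d, "D-promoter")
  sets <- lapply(d$wells$well_id, function(w)
    setdiff(well_mutation_set(d, w), dp))
  names(sets) <- d$wells$well_id
  for (pair in list(c(1, 2), c(3, 9), c(5, 20))) {
    si <- sets[[pair[1]]]; sj <- sets[[pair[2]]]
    brute <- if (length(si) == 0 || length(sj) == 0) NA_real_ else
      (mean(si %in% sj) + mean(sj %in% si)) / 2
    expect_equal(Px$values[pair[1], pair[2]], brute)
  }

  # a well empty after exclusion yields NA against every other well
  bg <- c(B1 = "5000cT")
  ann <- synthetic_phage_annotation()
  d2 <- mut_dataset(make_calls(
    list(w1 = list("1910aG"), w2 = list(c("100aG", "1911cT"))),
    list(w1 = "B1", w2 = "B1")), bg, ann)
  P2 <- pairwise_parallelism(d2, exclude_features = "D-promoter")$values
  expect_true(is.na(P2["w1", "w2"]))
})

test_that("within-background summaries equal enumerated-pair averages", {
  d <- simulate_dataset(null_cfg(), seed = 1500)$dataset
  P <- pairwise_parallelism(d)
  ws <- within_background_summary(P)
  for (b in unique(d$wells$background_id)) {
    ids <- d$wells$well_id[d$wells$background_id == b]
    prs <- utils::combn(ids, 2)
    brute <- mean(vapply(seq_len(ncol(prs)), function(k)
      P$values[prs[1, k], prs[2, k]], 0), na.rm = TRUE)
    expect_equal(ws$per_background$mean[ws$per_background$background_id == b],
                 brute)
  }
  expect_equal(ws$grand_mean, mean(ws$per_background$mean))

  # identical wells within a background give a background mean of exactly 1
  bg <- c(B1 = "5000cT", B2 = "6000gA")
  d2 <- mut_dataset(make_calls(
    list(w1 = list(c("100aG", "200cT")), w2 = list(c("100aG", "200cT")),
         w3 = list("300gT"), w4 = list("400tA")),
    list(w1 = "B1", w2 = "B1", w3 = "B2", w4 = "B2")), bg)
  ws2 <- within_background_summary(pairwise_parallelism(d2))
  expect_equal(ws2$per_background$mean[ws2$per_background$background_id == "B1"], 1)
})

test_that("the background-effect randomization test detects planted structure", {
  # one background of identical wells embedded among heterogeneous ones
  bg <- stats::setNames(sprintf("%dcT", 5000 + 10 * (1:3)), paste0("B", 1:3))
  keys <- abstract_keys(12)
  wells <- list()
  bg_of <- list()
  for (i in 1:4) {  # B1: four identical wells
    w <- paste0("a", i)
    wells[[w]] <- list(keys[1:3])
    bg_of[[w]] <- "B1"
  }
  set <- withr::with_seed(42, replicate(8, sample(keys, 3), simplify = FALSE))
  for (i in 1:4) {
    w <- paste0("b", i)
    wells[[w]] <- list(set[[i]])
    bg_of[[w]] <- "B2"
  }
  for (i in 1:4) {
    w <- paste0("c", i)
    wells[[w]] <- list(set[[4 + i]])
    bg_of[[w]] <- "B3"
  }
  d <- mut_dataset(make_calls(wells, bg_of), bg)
  res <- background_effect_test(d, n_perm = 999, seed = 5)
  expect_lt(res$p_value, 0.05)
  expect_true(res$R_real >= 0 && res$R_real <= 1)
  # same seed reproduces the p-value exactly
  res2 <- background_effect_test(d, n_perm = 999, seed = 5)
  expect_identical(res$p_value, res2$p_value)

  # degenerate: identical wells everywhere -> all P equal -> R defined as 0
  wells_eq <- stats::setNames(
    rep(list(list(keys[1:2])), 6),
    c("a1", "a2", "b1", "b2", "c1", "c2"))
  bg_eq <- stats::setNames(as.list(rep(paste0("B", 1:3), each = 2)),
                           names(wells_eq))
  d_eq <- mut_dataset(make_calls(wells_eq, bg_eq), bg)
  expect_warning(res_eq <- background_effect_test(d_eq, n_perm = 99, seed = 1),
                 "n_perm")
  expect_equal(res_eq$R_real, 0)
})

test_that("occurrence spectra give squared co-occurrence probabilities", {
  # 68 wells; one mutation in 53, another in 8
  wells <- list()
  bg_of <- list()
  for (i in 1:68) {
    w <- sprintf("w%02d", i)
    g <- c(if (i <= 53) "1910aG", if (i <= 8) "2397aG", "9999aG")
    wells[[w]] <- list(g)
    bg_of[[w]] <- "B1"
  }
  d <- mut_dataset(make_calls(wells, bg_of), c(B1 = "5000cT"))
  sp <- occurrence_spectrum(d)
  tab <- sp$spectrum
  expect_equal(tab$n_wells_present[tab$id == "1910aG"], 53L)
  expect_equal(round(tab$freq_squared[tab$id == "1910aG"], 2), 0.61)
  expect_equal(round(tab$freq_squared[tab$id == "2397aG"], 3), 0.014)
  expect_true(all(tab$n_wells_present <= sp$n_wells))
  expect_equal(sp$mean_freq_squared, mean(tab$freq_squared))
})

test_that("feature grouping pools member mutations into one identity", {
  ann <- synthetic_phage_annotation()
  wells <- list()
  bg_of <- list()
  for (i in 1:10) {
    w <- sprintf("w%02d", i)
    g <- if (i <= 4) "1910aG" else if (i <= 7) "1911cT" else "100aG"
    wells[[w]] <- list(g)
    bg_of[[w]] <- "B1"
  }
  d <- mut_dataset(make_calls(wells, bg_of), c(B1 = "5000cT"), ann)
  sp <- occurrence_spectrum(d, group_features = "D-promoter")
  tab <- sp$spectrum
  expect_equal(tab$n_wells_present[tab$id == "D-promoter"], 7L)
  expect_false(any(tab$id %in% c("1910aG", "1911cT")))
  expect_equal(tab$freq_squared[tab$id == "D-promoter"], 0.49)
})
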