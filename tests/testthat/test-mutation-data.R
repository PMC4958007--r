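test_that("a toy table builds the expected dataset and round-trips through TSV", {
  d <- toy_well(list("100aG", c("100aG", "200cT"), character(0)))
  expect_s3_class(d, "mut_dataset")
  expect_equal(nrow(d$wells), 1L)
  expect_equal(d$wells$n_isolates, 3L)
  expect_equal(d$catalog, c("100aG", "200cT"))

  sim <- simulate_dataset(study_preset(), seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(sim$dataset, path)
  back <- read_mutation_table(path, sim$dataset$background_catalog,
                              sim$dataset$annotation)
  expect_equal(back$isolates, sim$dataset$isolates)
  expect_equal(back$genotypes, sim$dataset$genotypes)
  expect_equal(back$wells, sim$dataset$wells)
  expect_equal(back$catalog, sim$dataset$catalog)
})

test_that("malformed or inconsistent tables are rejected with informative errors", {
  bg <- c(B1 = "5000cT")
  base <- data.frame(isolate_id = "i1", well_id = "w1", background_id = "B1",
                     mutation_key = "100aG", stringsAsFactors = FALSE)
  bad_key <- base; bad_key$mutation_key <- "100a"
  expect_error(mut_dataset(bad_key, bg), "malformed")
  two_wells <- rbind(base, transform(base, well_id = "w2"))
  expect_error(mut_dataset(two_wells, bg), "more than one well")
  dup_row <- rbind(base, base)
  expect_error(mut_dataset(dup_row, bg), "duplicated isolate x mutation")
  unknown_bg <- transform(base, background_id = "B9")
  expect_error(mut_dataset(unknown_bg, bg), "unknown background_id")
})

test_that("well QC drops exactly the under-sampled wells and is idempotent", {
  # 72 wells, 4 of which have <= 3 isolates, mirroring the study's design
  wells <- list()
  bg_of <- list()
  for (i in 1:72) {
    w <- sprintf("w%02d", i)
    n_iso <- if (i <= 4) c(1L, 2L, 3L, 3L)[i] else 5L
    wells[[w]] <- replicate(n_iso, "100aG", simplify = FALSE)
    bg_of[[w]] <- "B1"
  }
  d <- mut_dataset(make_calls(wells, bg_of), c(B1 = "5000cT"))
  q <- apply_well_qc(d, min_isolates = 4)
  brute <- names(wells)[vapply(wells, length, 0L) >= 4]
  expect_setequal(q$wells$well_id, brute)
  expect_equal(nrow(q$wells), 68L)
  expect_equal(apply_well_qc(q, 4), q, ignore_attr = TRUE)
  expect_equal(apply_well_qc(d, 1)$wells, d$wells)

  sim <- simulate_dataset(null_cfg(), seed = 3)$dataset
  expect_equal(apply_well_qc(sim, 1)$genotypes, sim$genotypes)
})

test_that("reversion classification matches generator truth and key algebra", {
  expect_equal(reversion_key("1910aG"), "1910gA")
  expect_true(is_reversion_key("1910gA", "1910aG"))
  expect_false(is_reversion_key("1910gC", "1910aG"))

  sim <- simulate_dataset(study_preset(), seed = 21)
  flags <- classify_reversions(sim$dataset)
  truth <- vapply(sim$truth$wells, function(w)
    w$reversion && any(vapply(
      w$sampled_nodes, function(nd)
        reversion_key(sim$truth$config$background_catalog[[w$background_id]]) %in%
          w$genotype[[nd]], TRUE)), TRUE)
  expect_equal(unname(flags[names(truth)]), unname(truth))

  d0 <- toy_well(list("100aG", c("100aG", "200cT")))
  expect_false(any(classify_reversions(d0)))
})

test_that("well mutation sets are isolate unions with optional reversion removal", {
  d <- toy_well(list("100aG", c("100aG", "200cT")), bg_key = "300gT")
  expect_equal(well_mutation_set(d, "w1"), c("100aG", "200cT"))
  d2 <- toy_well(list(c("100aG", "300tG"), "100aG"), bg_key = "300gT")
  expect_equal(well_mutation_set(d2, "w1"), c("100aG", "300tG"))
  expect_equal(well_mutation_set(d2, "w1", include_reversions = FALSE), "100aG")

  sim <- simulate_dataset(null_cfg(), seed = 5)$dataset
  for (w in sim$wells$well_id[1:4]) {
    iso <- sim$isolates$isolate_id[sim$isolates$well_id == w]
    brute <- sort(unique(unlist(sim$genotypes[iso])))
    expect_equal(well_mutation_set(sim, w), brute)
  }
})

test_that("mutation and event counting matches a brute-force tally", {
  d <- toy_well(list(c("100aG", "200cT", "300gT")))
  cm <- count_mutations_and_events(d)
  expect_equal(cm$unique_mutations, 3L)
  expect_equal(cm$events, 3L)

  sim <- simulate_dataset(null_cfg(), seed = 9)$dataset
  cm <- count_mutations_and_events(sim)
  sets <- lapply(sim$wells$well_id, well_mutation_set, dataset = sim)
  brute <- table(unlist(sets))
  expect_equal(cm$events, sum(brute))
  expect_equal(cm$unique_mutations, length(brute))
  expect_gte(cm$events, cm$unique_mutations)
  # order invariance: shuffling isolate rows leaves the counts unchanged
  calls <- do.call(rbind, lapply(seq_len(nrow(sim$isolates)), function(i) {
    iso <- sim$isolates[i, ]
    g <- sim$genotypes[[iso$isolate_id]]
    data.frame(isolate_id = iso$isolate_id, well_id = iso$well_id,
               background_id = iso$background_id,
               mutation_key = if (length(g) == 0) NA_character_ else g,
               stringsAsFactors = FALSE)
  }))
  calls <- calls[withr::with_seed(1, sample(nrow(calls))), ]
  d2 <- mut_dataset(calls, sim$background_catalog)
  expect_equal(count_mutations_and_events(d2)[1:2], cm[1:2])
})

test_that("contamination flags fire on planted foreign-background isolates only", {
  bg <- c(B1 = "1000aG", B2 = "2000cT")
  wells <- list(
    clean = list("100aG", "200cT"),
    # isolate reverts its own background AND carries B2's founding mutation
    dirty = list(c("1000gA", "2000cT"), "100aG"),
    # reversion alone is not a contamination flag
    revonly = list("1000gA", "200cT"))
  bg_of <- list(clean = "B1", dirty = "B1", revonly = "B1")
  d <- mut_dataset(make_calls(wells, bg_of), bg)
  fl <- flag_contamination(d)
  expect_equal(fl$flagged[fl$well_id == "dirty"], TRUE)
  expect_equal(fl$flagged[fl$well_id == "clean"], FALSE)
  expect_equal(fl$flagged[fl$well_id == "revonly"], FALSE)
  expect_match(fl$foreign_backgrounds[fl$well_id == "dirty"], "B2")
})

test_that("the shipped synthetic example loads and analyzes end to end", {
  dir <- system.file("extdata", "synthetic_example", package = "repadapt")
  ann <- read_annotation(file.path(dir, "annotation.tsv"),
                         file.path(dir, "ancestral.fasta"))
  bg <- utils::read.delim(file.path(dir, "background_catalog.tsv"))
  d <- read_mutation_table(file.path(dir, "mutations_by_isolate.tsv"),
                           stats::setNames(bg$mutation_key, bg$background_id),
                           ann)
  expect_equal(nrow(d$wells), 72L)
  expect_equal(nrow(d$isolates), 360L)
  d <- apply_well_qc(d)
  expect_gt(count_mutations_and_events(d)$events, 0)
})
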