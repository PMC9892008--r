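test_that("species selection applies the detection and fraction rules per dataset", {
  det <- data.frame(sgb_id = c("S1", "S2", "S3", "S3"),
                    dataset_id = c("A", "A", "A", "B"),
                    n_detected = c(20L, 19L, 25L, 30L))
  sizes <- c(A = 100L, B = 100L)
  sel <- select_sgbs_for_profiling(det, sizes)
  expect_true("S1" %in% sel)          # 20/100: both rules at the boundary
  expect_false("S2" %in% sel)         # 19 detections
  expect_true("S3" %in% sel)          # selected via dataset B

  det2 <- data.frame(sgb_id = "S4", dataset_id = "A", n_detected = 25L)
  expect_false("S4" %in% select_sgbs_for_profiling(det2, c(A = 300L)))  # 8.3%
  expect_error(select_sgbs_for_profiling(det, c(A = 100L)), "unknown dataset")
})

test_that("food-strain flagging is inclusive at the SNV cutoff", {
  ids <- c("s1", "s2", "s3", "F1")
  m <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(m) <- 0
  m["s1", "F1"] <- m["F1", "s1"] <- 0.0015   # excluded: inclusive rule
  m["s2", "F1"] <- m["F1", "s2"] <- 0.0020   # retained
  m["s3", "F1"] <- m["F1", "s3"] <- 0.0001
  expect_setequal(flag_food_strains(m, "F1"), c("s1", "s3"))
  expect_message(out <- flag_food_strains(m, character(0)), "no food")
  expect_length(out, 0L)
})

test_that("planted food strains are recovered exactly on synthetic SNV tables", {
  set.seed(31)
  samples <- sprintf("s%03d", 1:100)
  planted <- sample(samples, 10)
  refs <- c("FOOD1", "FOOD2")
  rows <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_a = s, sample_b = refs,
               snv_rate = if (s %in% planted) stats::runif(2, 0, 0.001)
                          else stats::runif(2, 0.01, 0.1),
               stringsAsFactors = FALSE)
  }))
  expect_setequal(flag_food_strains(rows, refs), planted)
})

test_that("sharing calls respect the inclusive boundary and exclusions", {
  ids <- c("a", "b", "c")
  m <- matrix(0, 3, 3, dimnames = list(ids, ids))
  m["a", "b"] <- m["b", "a"] <- 0.05
  m["a", "c"] <- m["c", "a"] <- 0.0
  m["b", "c"] <- m["c", "b"] <- 0.2
  ds <- structure(list(sgb_id = "S", leaves = ids, ngd = m),
                  class = "sgb_dist")
  calls <- call_sharing_events(ds, 0.05)
  expect_true(calls$shared[calls$sample_a == "a" & calls$sample_b == "b"])
  expect_true(calls$shared[calls$sample_a == "a" & calls$sample_b == "c"])
  expect_false(calls$shared[calls$sample_a == "b" & calls$sample_b == "c"])

  strict <- call_sharing_events(ds, 0.05, inclusive = FALSE)
  expect_false(strict$shared[strict$sample_a == "a" & strict$sample_b == "b"])

  excl <- call_sharing_events(ds, 0.05, excluded = "a")
  expect_equal(nrow(excl), 1L)
})

test_that("event counts are non-decreasing in the threshold", {
  study <- default_study()
  d <- study$trees$dist_sets[[1]]
  ths <- seq(0, 1, by = 0.05)
  n_events <- vapply(ths, function(t)
    sum(call_sharing_events(d, t)$shared), integer(1))
  expect_true(all(diff(n_events) >= 0L))
})

test_that("subject collapse uses the any-time-point rule and profile intersection", {
  calls <- data.frame(
    sample_a = c("a1", "a2", "a1"), sample_b = c("b1", "b1", "a2"),
    ngd = c(0.5, 0.01, 0.01), shared = c(FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  map <- c(a1 = "A", a2 = "A", b1 = "B")
  sub <- collapse_to_subjects(calls, map, "S")
  expect_equal(nrow(sub), 1L)   # same-subject pair dropped
  expect_true(sub$shared)       # any cross-subject shared pair counts
  expect_equal(sub$min_ngd, 0.01)

  # invariant to sample ordering
  perm <- calls[c(3, 1, 2), ]
  expect_equal(collapse_to_subjects(perm, map, "S"), sub)
})

test_that("sharing rates follow the shared-strain / shared-species ratio with the >=10 gate", {
  counts <- data.frame(subject_a = c("A", "A", "A"),
                       subject_b = c("B", "C", "D"),
                       n_shared_sgbs = c(20L, 9L, 15L),
                       n_shared_strains = c(5L, 9L, 0L),
                       stringsAsFactors = FALSE)
  r <- sharing_rate(counts)
  expect_equal(r$sharing_rate_pct, c(25.0, NA, 0.0))
})

test_that("acquisition rate is the mother-shared fraction of offspring strains", {
  profiles <- stats::setNames(
    lapply(1:20, function(i) c("kid", "mom")), sprintf("S%02d", 1:20))
  calls <- data.frame(
    sgb_id = sprintf("S%02d", 1:20),
    subject_a = "kid", subject_b = "mom",
    shared = c(rep(TRUE, 4), rep(FALSE, 16)),
    min_ngd = 0.01, stringsAsFactors = FALSE)
  expect_equal(acquisition_rate("kid", "mom", calls, profiles), 0.20)

  all_shared <- calls; all_shared$shared <- TRUE
  expect_equal(acquisition_rate("kid", "mom", all_shared, profiles), 1.0)

  expect_true(is.na(acquisition_rate("kid", "mom", calls, profiles[1:9])))
})

test_that("pair classification follows the precedence order", {
  s <- rbind(
    make_samples("m1", "mom", household_id = "H1", village_id = "V1",
                 age_years = 30),
    make_samples("f1", "dad", household_id = "H1", village_id = "V1",
                 age_years = 33),
    make_samples("c1", "kid", household_id = "H1", village_id = "V1",
                 age_years = 0.5, mother_id = "mom", father_id = "dad"),
    make_samples("c2", "kid2", household_id = "H1", village_id = "V1",
                 age_years = 8, mother_id = "mom", father_id = "dad"),
    make_samples("g1", "lodger", household_id = "H1", village_id = "V1"),
    make_samples("v1", "neighbour", household_id = "H2", village_id = "V1"),
    make_samples("p1", "citizen", household_id = "H3", village_id = "V2"),
    make_samples("x1", "foreigner", dataset_id = "D02", household_id = "H4",
                 village_id = "V3"))
  subj <- subject_table(s)
  expect_equal(classify_pair("mom", "kid", subj)$category, "mother_offspring")
  expect_equal(classify_pair("mom", "kid", subj)$offspring_age_bin, "<=1y")
  expect_equal(classify_pair("dad", "kid2", subj)$category, "father_offspring")
  expect_equal(classify_pair("dad", "kid2", subj)$offspring_age_bin, "3-18y")
  expect_equal(classify_pair("mom", "dad", subj)$category, "partners")
  expect_equal(classify_pair("kid", "kid2", subj)$category, "siblings")
  expect_equal(classify_pair("mom", "lodger", subj)$category, "household")
  expect_equal(classify_pair("mom", "neighbour", subj)$category, "same_village")
  expect_equal(classify_pair("mom", "citizen", subj)$category, "same_population")
  expect_equal(classify_pair("mom", "foreigner", subj)$category,
               "inter_population")
  expect_error(classify_pair("mom", "nobody", subj), "unknown subject")
})

test_that("twins outrank siblings and vectorized classification matches scalar", {
  s <- rbind(
    make_samples("m1", "mom", household_id = "H1", age_years = 30),
    make_samples("f1", "dad", household_id = "H1", age_years = 31),
    make_samples("t1", "twinA", household_id = "H1", age_years = 4,
                 mother_id = "mom", father_id = "dad"),
    make_samples("t2", "twinB", household_id = "H1", age_years = 4,
                 mother_id = "mom", father_id = "dad"))
  subj <- subject_table(s)
  expect_equal(classify_pair("twinA", "twinB", subj)$category, "twins")

  study <- default_study()
  subjects <- subject_table(study$samples)
  all_cls <- classify_all_pairs(subjects)
  set.seed(66)
  idx <- sample.int(nrow(all_cls), 50)
  for (i in idx) {
    sc <- classify_pair(all_cls$subject_a[i], all_cls$subject_b[i], subjects)
    expect_identical(sc$category, all_cls$category[i])
    expect_identical(is.na(sc$offspring_age_bin),
                     is.na(all_cls$offspring_age_bin[i]))
    if (!is.na(sc$offspring_age_bin)) {
      expect_identical(sc$offspring_age_bin, all_cls$offspring_age_bin[i])
    }
  }
})

test_that("relationship summaries report medians and zero-sharing percentages", {
  summaries <- data.frame(
    subject_a = letters[1:6], subject_b = LETTERS[1:6],
    n_shared_sgbs = 20L, n_shared_strains = c(0L, 5L, 10L, 0L, 0L, 0L),
    sharing_rate_pct = c(0, 25, 50, 0, 0, 0),
    category = c(rep("household", 3), rep("same_village", 3)),
    stringsAsFactors = FALSE)
  g <- rate_by_relationship(summaries)
  hh <- g[g$category == "household", ]
  expect_equal(hh$median_rate, 25)
  expect_equal(hh$pct_zero_sharing, 100 / 3, tolerance = 1e-10)
  sv <- g[g$category == "same_village", ]
  expect_equal(sv$median_rate, 0)
  expect_equal(sv$pct_zero_sharing, 100)
})

test_that("network construction applies the edge cutoffs without self-loops", {
  counts <- data.frame(subject_a = c("B", "A", "C", "D"),
                       subject_b = c("C", "B", "C", "E"),
                       n_shared_sgbs = c(60L, 12L, 10L, 55L),
                       n_shared_strains = c(5L, 4L, 2L, 1L),
                       stringsAsFactors = FALSE)
  net <- build_sharing_network(counts)
  expect_equal(nrow(net), 1L)  # only the pair with >=5 shared strains
  expect_equal(net$subject_a, "B")
  expect_false(any(net$subject_a == net$subject_b))

  spec_net <- build_sharing_network(counts, what = "species")
  expect_setequal(spec_net$subject_a, c("B", "D"))  # >=50 shared species
})

test_that("food exclusion never increases subject-pair strain sharing", {
  study <- default_study()
  d <- study$trees$dist_sets[[1]]
  samples <- study$samples
  map <- stats::setNames(samples$subject_id, samples$sample_id)
  refs <- grep("^FOODREF_", d$leaves, value = TRUE)
  food <- study$trees$truth$food_strains
  excl <- food$sample_id[food$sgb_id == d$sgb_id]
  th <- 0.01
  base <- pair_counts(collapse_to_subjects(
    call_sharing_events(d, th, excluded = refs), map, d$sgb_id))
  filt <- pair_counts(collapse_to_subjects(
    call_sharing_events(d, th, excluded = c(refs, excl)), map, d$sgb_id))
  key <- function(x) paste(x$subject_a, x$subject_b)
  m <- match(key(filt), key(base))
  expect_true(all(filt$n_shared_strains <= base$n_shared_strains[m]))
})

test_that("a planted mother-infant sharing probability of 0.5 is recovered in the rate summary", {
  cfg <- simulation_config(
    seed = 808L, n_datasets = 1L, villages_per_dataset = 1L,
    households_per_village = 100L, n_sgbs = 15L, carriage_prob = 1.0,
    longitudinal_fraction = 0.3,
    sharing_prob = c(same_individual = 0.95, mother_offspring = 0.5,
                     father_offspring = 0, twins = 0, partners = 0,
                     siblings = 0, household = 0, same_village = 0,
                     same_population = 0, inter_population = 0),
    food_sgb_fraction = 0, fmt_triads = 0L)
  set.seed(808)
  rows <- list()
  for (k in seq_len(100L)) {
    hh <- sprintf("H%03d", k)
    mom <- paste0(hh, "_mom"); kid <- paste0(hh, "_kid")
    rows[[length(rows) + 1L]] <- make_samples(
      paste0(mom, "_t0"), mom, household_id = hh, village_id = "V1",
      age_years = 30)
    rows[[length(rows) + 1L]] <- make_samples(
      paste0(kid, "_t0"), kid, household_id = hh, village_id = "V1",
      age_years = 0.5, mother_id = mom)
  }
  samples <- validate_metadata(do.call(rbind, rows))
  trees <- generate_sgb_trees(samples, cfg)
  thresholds <- calibrate_all(trees$dist_sets, samples, seed = 808L)
  map <- stats::setNames(samples$subject_id, samples$sample_id)
  calls <- do.call(rbind, lapply(names(trees$dist_sets), function(sgb) {
    collapse_to_subjects(
      call_sharing_events(trees$dist_sets[[sgb]],
                          thresholds[thresholds$sgb_id == sgb, ]),
      map, sgb)
  }))
  summaries <- sharing_rate(pair_counts(calls))
  summaries <- classify_pairs(summaries, subject_table(samples))
  g <- rate_by_relationship(summaries)
  mo <- g[g$category == "mother_offspring", ]
  expect_gte(mo$n_pairs, 90L)
  expect_lt(abs(mo$median_rate - 50), 5)
})
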