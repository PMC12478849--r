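test_that("percentile thresholds use linear interpolation", {
  expect_equal(rmsd_threshold(rep(0.07, 50), 99), 0.07)
  expect_equal(rmsd_threshold(1:100, 99), 99.01)
  expect_equal(rmsd_threshold(1:100, 50), 50.5)
  x <- generate_folded_rmsd_trace("3T-RH", 1000, seed = 3)
  expect_gt(rmsd_threshold(x, 99), median(x))
  expect_error(rmsd_threshold(numeric(0)), "nonempty")
  expect_error(rmsd_threshold(1:10, 0), "percentile")
})

test_that("foldable labels use a strict per-class threshold", {
  rec <- data.frame(n_tetrads = 3L, helicity = "RH", topology = "-p-p-p",
                    polarity = "LP-LP-LP", len_I = 1L, len_II = 1L,
                    len_III = 1L, rmsd_nm = c(0.05, 0.104, 0.1039, 0.2))
  lab <- label_foldable(rec)
  expect_equal(lab$foldable, c(TRUE, FALSE, TRUE, FALSE))
  rec$helicity <- "LH"   # no 3T-LH threshold in the default set
  expect_error(label_foldable(rec), "no threshold")

  # extreme thresholds mark everything / nothing foldable
  rec$helicity <- "RH"
  expect_true(all(label_foldable(
    rec, g4_thresholds(c("3T-RH" = 1e9)))$foldable))
  expect_false(any(label_foldable(
    rec, g4_thresholds(c("3T-RH" = 1e-12)))$foldable))

  # mixed batch: partition sizes agree with a direct scan
  recs <- default_records(1:2)
  thr <- default_thresholds()$thresholds["3T-RH"]
  expect_equal(sum(recs$foldable), sum(recs$rmsd_nm < thr))
})

test_that("the foldability map aggregates by topology and total length", {
  recs <- separable_records()
  fm <- foldability_map(recs)
  expect_true(all(fm[rownames(fm) %in% c("-p-p-p", "-p-l-l"), ] == 1,
                  na.rm = TRUE))
  expect_true(all(fm >= 0 & fm <= 1, na.rm = TRUE))
  expect_equal(sort(as.numeric(colnames(fm))), 3:6)
  # rows ordered by decreasing mean foldability
  topo_mean <- tapply(recs$foldable, recs$topology, mean)
  expect_true(all(diff(topo_mean[rownames(fm)]) <= 0))
  # single-record cells are exactly 0 or 1
  one <- recs[!duplicated(paste(recs$topology,
                                recs$len_I + recs$len_II + recs$len_III)), ]
  expect_true(all(foldability_map(one) %in% c(0, 1, NA)))
  # aggregation is invariant to record order
  shuffled <- recs[rev(seq_len(nrow(recs))), ]
  expect_equal(foldability_map(shuffled), fm)
})

test_that("map cells rise with total loop length for LD topologies", {
  recs <- default_records()
  cen <- propeller_census("RH")
  # construction property: the generative fold probability rises with
  # total loop length in every LD-bearing topology
  total <- recs$len_I + recs$len_II + recs$len_III
  pcell <- tapply(recs$p_fold, list(recs$topology, total), mean)
  for (t in cen$topology[cen$has_ld]) {
    v <- pcell[t, !is.na(pcell[t, ])]
    expect_gt(cor(as.numeric(names(v)), v, method = "spearman"), 0.9)
  }
  # and the realised fractions follow it where the signal is strong
  fm <- foldability_map(recs)
  for (t in cen$topology[cen$ld_count == 1]) {
    v <- fm[t, !is.na(fm[t, ])]
    expect_gt(cor(as.numeric(names(v)), v, method = "spearman"), 0.5)
  }
})

test_that("per-feature foldability reflects position-dependent geometry", {
  uniform <- separable_records()
  uniform$foldable <- TRUE
  bt <- foldability_by_feature(uniform, "type")
  expect_true(all(bt$foldability == 1))

  recs <- default_records()
  bt <- foldability_by_feature(recs, "type")
  get <- function(pos, val) bt$foldability[bt$position == pos &
                                             bt$value == val]
  # -p at I is never long-distance under RH; at II it often is
  expect_gt(get("I", "-p"), get("II", "-p"))
  bl <- foldability_by_feature(recs, "length")
  expect_equal(nrow(bl), 12)   # 4 lengths x 3 positions
  expect_true(all(bl$n > 0))
})

test_that("two-loop combinations average over their carrier topologies", {
  recs <- default_records(1:2)
  tab <- two_loop_combination_table(recs)
  # a combination carried by one topology equals that topology's foldability
  single <- tab[!grepl(",", tab$topologies), ]
  expect_gt(nrow(single), 0)
  for (i in seq_len(nrow(single))) {
    topo_fold <- mean(recs$foldable[recs$topology == single$topologies[i]])
    expect_equal(single$foldability[i], topo_fold)
  }
  all_fold <- recs
  all_fold$foldable <- TRUE
  expect_true(all(two_loop_combination_table(all_fold)$foldability == 1))
  # a -l before a -p makes the -p long-distance: the pair underperforms
  # the marginal -p at II
  pair <- tab$foldability[tab$position_a == "I" & tab$type_a == "-l" &
                            tab$position_b == "II" & tab$type_b == "-p"]
  marg <- foldability_by_feature(recs, "type")
  marg_iip <- marg$foldability[marg$position == "II" & marg$value == "-p"]
  expect_lt(pair, marg_iip)
})

test_that("classifier recovers separable labels and beats prevalence", {
  recs <- separable_records()
  clf <- fit_foldability_classifier(recs, folds = 5, nrounds = 20)
  expect_equal(clf$precision, 1, tolerance = 1e-9)

  recs2 <- default_records(1:3, seed = 11)
  clf2 <- fit_foldability_classifier(recs2, folds = 5, nrounds = 30)
  expect_gt(clf2$precision, clf2$prevalence + 0.05)
  # deterministic given the seed
  clf3 <- fit_foldability_classifier(recs2, folds = 5, nrounds = 30)
  expect_equal(clf2$precision, clf3$precision)

  # label shuffling drives precision to the class prevalence
  set.seed(99)
  recs2$foldable <- sample(recs2$foldable)
  clf4 <- fit_foldability_classifier(recs2, folds = 5, nrounds = 30)
  prev <- mean(recs2$foldable)
  expect_lt(abs(clf4$precision - prev),
            3 * sqrt(prev * (1 - prev) / (nrow(recs2) / 5)) + 0.05)
  expect_error(fit_foldability_classifier(
    transform(recs2, foldable = TRUE)), "both classes")
})
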