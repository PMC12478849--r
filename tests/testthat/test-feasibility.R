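test_that("per-conformation feasibility applies the type-specific minima", {
  r <- is_feasible("-pd+p", c(1, 3, 1), "RH")
  expect_true(r$feasible)
  expect_equal(nrow(r$violations), 0)

  r <- is_feasible("+p+p+p", c(4, 4, 4), "RH")
  expect_false(r$feasible)
  expect_equal(nrow(r$violations), 3)         # three LD loops below 5 nt
  expect_true(all(r$violations$geometry == "LD"))
  expect_true(all(r$violations$min_required == 5))

  r <- is_feasible("d+pd", c(3, 1, 2), "RH")
  expect_false(r$feasible)
  expect_equal(r$violations$position, "III")  # diagonal at III: 2 < 3 nt
  expect_equal(r$violations$min_required, 3)
})

test_that("feasible sets reproduce the known design cases", {
  expect_setequal(feasible_topologies(c(1, 3, 1), "RH"),
                  c("-pd+p", "-p-p-p"))
  # with 4-nt loops every LD topology fails, every LD-free one passes
  cen <- propeller_census("RH")
  expect_setequal(feasible_topologies(c(4, 4, 4), "RH"),
                  cen$topology[!cen$has_ld])
  expect_equal(feasible_topologies(c(1, 1, 1), "RH"), "-p-p-p")
})

test_that("lengthening a loop never removes a feasible topology", {
  for (h in c("RH")) {
    grid <- expand.grid(i = 1:4, j = 1:4, k = 1:4)
    for (r in seq_len(nrow(grid))) {
      lens <- as.numeric(grid[r, ])
      base <- feasible_topologies(lens, h)
      for (pos in 1:3) {
        longer <- lens
        longer[pos] <- longer[pos] + 1
        expect_true(all(base %in% feasible_topologies(longer, h)))
      }
    }
  }
})

test_that("RH feasibility maps to LH feasibility of mirror topologies", {
  for (lens in list(c(1, 3, 1), c(2, 2, 2), c(1, 1, 5), c(4, 1, 3))) {
    rh <- feasible_topologies(lens, "RH")
    lh <- feasible_topologies(lens, "LH")
    expect_setequal(vapply(rh, mirror_topology, character(1)), lh)
  }
})

test_that("rule-set extremes bound the feasible sets", {
  no_ld <- g4_rules(min_ld_propeller_nt = Inf)
  cen <- propeller_census("RH")
  for (lens in list(c(4, 4, 4), c(8, 8, 8))) {
    expect_true(all(!cen$has_ld[match(feasible_topologies(lens, "RH", no_ld),
                                      cen$topology)]))
  }
  lax <- g4_rules(min_lateral_nt = 1, min_diagonal_nt = 1,
                  min_sd_propeller_nt = 1, min_ld_propeller_nt = 1,
                  strict_lateral = FALSE)
  expect_length(feasible_topologies(c(1, 1, 1), "RH", lax), 26)
  expect_error(g4_rules(min_ld_propeller_nt = 0), ">= 1")
  expect_error(g4_rules(min_ld_propeller_nt = 2, min_sd_propeller_nt = 3))
})

test_that("relaxing strict laterals admits 1-nt lateral loops", {
  relaxed <- g4_rules(strict_lateral = FALSE)
  expect_false(is_feasible("-l-p-p", c(1, 5, 5), "RH")$feasible)
  expect_true(is_feasible("-l-p-p", c(1, 5, 5), "RH", relaxed)$feasible)
})

test_that("design search ranks loop-length triples by competitor count", {
  ds <- design_search("-pd+p", "RH", max_len = 4)
  expect_true(nrow(ds) > 0)
  top <- ds[ds$n_competitors == min(ds$n_competitors), ]
  expect_true(all(top$n_competitors == 1))
  expect_true(all(top$competitors == "-p-p-p"))
  key <- paste(ds$len_I, ds$len_II, ds$len_III)
  expect_true(all(c("1 3 1", "1 4 1") %in%
                    paste(top$len_I, top$len_II, top$len_III)))
  expect_equal(key[1], "1 3 1")   # smallest total length ranks first

  expect_equal(nrow(design_search("+p+p+p", "RH", max_len = 4)), 0)

  ds1 <- design_search("-p-p-p", "RH", max_len = 1)
  expect_equal(nrow(ds1), 1)
  expect_equal(unlist(ds1[1, c("len_I", "len_II", "len_III")],
                      use.names = FALSE), c(1L, 1L, 1L))
  expect_equal(ds1$n_competitors, 0)
})

test_that("rule sets serialise to JSON and back", {
  rules <- g4_rules(min_lateral_nt = 3, strict_lateral = FALSE)
  expect_equal(rules_from_json(rules_to_json(rules)), rules)
  f <- tempfile(fileext = ".json")
  rules_to_json(rules, f)
  expect_equal(rules_from_json(f), rules)
  unlink(f)
})
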