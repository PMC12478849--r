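test_that("the closed-form rule labels propellers by preceding loop count", {
  expect_equal(classify_propellers_rule("+p+p+p", "RH"),
               c("LD", "LD", "LD"))
  expect_equal(classify_propellers_rule("-p-p-p", "LH"),
               c("LD", "LD", "LD"))
  expect_equal(classify_propellers_rule("-pd+p", "RH"),
               c("SD", NA, "SD"))
  expect_equal(classify_propellers_rule("-ld+l", "RH"),
               c(NA_character_, NA, NA))
})

test_that("long-distance counts match known topologies", {
  expect_equal(count_long_distance("-l-p-p", "RH"), 2)
  expect_equal(count_long_distance("d-pd", "RH"), 1)
  expect_equal(count_long_distance("-p-p-p", "RH"), 0)
  # left-handed foldability comparison set carries 3/2/1/0 LD loops
  expect_equal(count_long_distance("-p-p-p", "LH"), 3)
  expect_equal(count_long_distance("-p-p-l", "LH"), 2)
  expect_equal(count_long_distance("-p-l-l", "LH"), 1)
  expect_equal(count_long_distance("+p+p+p", "LH"), 0)
})

test_that("census: 12 topologies carry LD propellers, 14 do not", {
  for (h in c("RH", "LH")) {
    cen <- propeller_census(h)
    expect_equal(nrow(cen), 26)
    expect_equal(sum(cen$has_ld), 12)
    expect_equal(sum(!cen$has_ld), 14)
  }
  cen <- propeller_census("RH")
  expect_true("-pd+p" %in% cen$topology[!cen$has_ld])
  # histogram of LD counts: 14 at zero, exactly one topology with three,
  # and that topology is all-(+p)
  expect_equal(sum(cen$ld_count == 0), 14)
  expect_equal(cen$topology[cen$ld_count == 3], "+p+p+p")
  expect_equal(sum(cen$ld_count), sum(propeller_census("LH")$ld_count))
})

test_that("helicity reversal flips every propeller label", {
  for (topo in enumerate_topologies()) {
    rh <- classify_propellers_rule(topo, "RH")
    lh <- classify_propellers_rule(topo, "LH")
    expect_identical(is.na(rh), is.na(lh))
    flips <- xor(rh[!is.na(rh)] == "LD", lh[!is.na(lh)] == "LD")
    expect_true(all(flips))
  }
})

test_that("unwrap projection lays tracts out in strand order", {
  pr <- unwrap_projection("-ld+l", "RH")
  expect_equal(pr$unwrap, "counterclockwise")
  # 5'-end on the left edge for '-' first loops
  expect_equal(pr$tracts$x_plot[1], min(pr$tracts$x_plot))
  pr <- unwrap_projection("+ld-l", "RH")
  expect_equal(pr$unwrap, "clockwise")
  expect_equal(pr$tracts$x_plot[1], max(pr$tracts$x_plot))
  # strand order, no overlap
  for (topo in enumerate_topologies()) {
    u <- unwrap_projection(topo, "RH")$tracts$x
    expect_true(all(diff(u) > 0))
  }
})

test_that("helicity mirrors the projection without changing distances", {
  for (topo in c("-p-p-p", "+p+p+p", "-pd+p", "d-pd", "+l+p+l")) {
    rh <- unwrap_projection(topo, "RH")
    lh <- unwrap_projection(topo, "LH")
    # a left-handed topology projects like its sign-swapped mirror image
    # under right-handed helicity
    mirror_rh <- unwrap_projection(mirror_topology(topo), "RH")
    expect_equal(sort(lh$loops$distance), sort(mirror_rh$loops$distance),
                 tolerance = 1e-12)
    # labels swap between helicities
    expect_identical(
      classify_propellers_geometric(rh),
      classify_propellers_rule(topo, "RH"))
    expect_identical(
      classify_propellers_geometric(lh),
      classify_propellers_rule(topo, "LH"))
  }
})

test_that("geometric classifier equals the rule on all 52 cases", {
  thr <- ld_distance_threshold()
  band <- attr(thr, "band")
  expect_true(band["low"] < thr, )
  expect_true(band["high"] > thr)
  # equivalence holds at the midpoint and across the admissible band
  for (t in c(thr, band[["low"]] + 1e-6, band[["high"]] - 1e-6)) {
    for (topo in enumerate_topologies()) {
      for (h in c("RH", "LH")) {
        expect_identical(
          classify_propellers_geometric(unwrap_projection(topo, h), t),
          classify_propellers_rule(topo, h))
      }
    }
  }
})

test_that("a zero threshold marks every propeller long-distance", {
  pr <- unwrap_projection("-p-p-p", "RH")
  expect_equal(classify_propellers_geometric(pr, 0), rep("LD", 3))
})
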