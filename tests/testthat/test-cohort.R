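# Cohort generation, routing through graded arrays and design outputs.

test_that("the normal cohort generator is reproducible and truncatable", {
  c1 <- generate_cohort(1000, seed = 7)
  c2 <- generate_cohort(1000, seed = 7)
  expect_identical(c1$diameter_um, c2$diameter_um)
  ct <- generate_cohort(2000, seed = 8, truncation = c(12, 28))
  expect_true(all(ct$diameter_um >= 12 & ct$diameter_um <= 28))
  expect_error(generate_cohort(10, mean_um = 100, truncation = c(12, 28)),
               class = "pillartrap_error_degenerate_generator")
})

test_that("large cohorts concentrate around the configured mean", {
  co <- generate_cohort(1e5, seed = 33)
  expect_lt(abs(mean(co$diameter_um) - 17.27), 0.05)
  expect_lt(abs(sd(co$diameter_um) - 2.91), 0.05)
})

test_that("binned generation respects bins and renormalises proportions", {
  one <- generate_cohort_binned(
    500, tibble::tibble(lower_um = 12, upper_um = 17, proportion = 1),
    seed = 1)
  expect_true(all(one$diameter_um >= 12 & one$diameter_um <= 17))
  expect_warning(
    co <- generate_cohort_binned(1e5, a549_size_bins(), seed = 2),
    class = "pillartrap_warning_renormalised_bins")
  bins <- a549_size_bins()
  props <- bins$proportion / sum(bins$proportion)
  for (i in seq_len(nrow(bins))) {
    frac <- mean(co$diameter_um >= bins$lower_um[i] &
                   co$diameter_um <= bins$upper_um[i])
    expect_lt(abs(frac - props[i]), 0.01)
  }
  overlap <- tibble::tibble(lower_um = c(10, 12), upper_um = c(14, 16),
                            proportion = c(0.5, 0.5))
  expect_error(generate_cohort_binned(10, overlap, seed = 1),
               class = "pillartrap_error_invalid_bins")
})

test_that("routing follows the size-fraction rule through the arrays", {
  arrays <- c(14, 10, 8, 4)
  big <- tibble::tibble(diameter_um = 60, modulus_pa = 430)
  r <- route_cohort(big, arrays)
  expect_equal(which(r$per_array$captured == 1), 1L)   # 0.25*60 >= 14
  mid <- tibble::tibble(diameter_um = 24, modulus_pa = 430)
  r2 <- route_cohort(mid, arrays)
  expect_equal(which(r2$per_array$captured == 1), 4L)  # first gap <= 6 is 4
  small <- tibble::tibble(diameter_um = 10, modulus_pa = 430)
  r3 <- route_cohort(small, arrays)
  expect_equal(r3$escaped, 1L)
  empty <- tibble::tibble(diameter_um = numeric(), modulus_pa = numeric())
  r0 <- route_cohort(empty, arrays)
  expect_equal(sum(r0$per_array$captured) + r0$escaped, 0L)
})

test_that("routing conserves cells and is monotone in size", {
  co <- generate_cohort(5000, seed = 11)
  r <- route_cohort(co)
  expect_equal(sum(r$per_array$captured) + r$escaped, nrow(co))
  expect_equal(sum(r$per_array$fraction) + r$escaped_fraction, 1)
  # larger cells are captured at equal or larger gaps
  gap_of <- ifelse(is.na(r$assignment), 0, r$gaps_um[r$assignment])
  ord <- order(co$diameter_um)
  d_sorted <- co$diameter_um[ord]
  g_sorted <- gap_of[ord]
  # escaped (0) cells are all smaller than any captured cell's threshold
  expect_true(all(diff(g_sorted) >= 0 | diff(d_sorted) == 0))
  expect_s3_class(autoplot(r), "ggplot")
  expect_equal(nrow(tidy(r)), length(r$gaps_um) + 1L)
})

test_that("the critical-pressure rule captures where Pc exceeds the drive", {
  co <- tibble::tibble(diameter_um = c(10, 17), modulus_pa = 430)
  rule <- capture_rule("critical_pressure", operating_pressure_pa = 40)
  r <- route_cohort(co, c(14, 10, 8, 4), rule)
  # 17 um cell: Pc at 8 um gap is 52 Pa > 40 -> captured at the 8 um array
  expect_equal(r$assignment[2], 3L)
  # 10 um cell: Pc at 8 is 18 Pa, at 4 is 73 Pa -> captured at 4
  expect_equal(r$assignment[1], 4L)
})

test_that("gap recommendations follow the 25% rule", {
  expect_equal(recommend_gap(12), 3)
  expect_equal(recommend_gap(28), 7)
  expect_equal(recommend_gap(c(12, 28), 0.3), c(3.6, 8.4))
  expect_warning(g0 <- recommend_gap(20, 0),
                 class = "pillartrap_warning_zero_fraction")
  expect_equal(g0, 0)
  expect_error(recommend_gap(-5), class = "pillartrap_error_invalid_input")
})

test_that("operating-pressure curves decrease in gap with fixed type ratios", {
  curves <- operating_pressure_curves(gaps_um = seq(4, 10, by = 1))
  expect_equal(nrow(curves), 6 * 7)
  by_type <- split(curves, curves$cell_type)
  for (ct in by_type) {
    expect_true(all(diff(ct$pc_pa[order(ct$gap_um)]) < 0))
  }
  a549 <- dplyr::filter(curves, cell_type == "A549")
  mda <- dplyr::filter(curves, cell_type == "MDA-MB-231")
  ratio <- a549$pc_pa / mda$pc_pa
  expect_equal(ratio, rep((430 * 17^2) / (206 * 15.5^2), length(ratio)))
  expect_equal(dplyr::filter(a549, gap_um == 8)$pc_pa, 52.42641,
               tolerance = 1e-6)
  expect_s3_class(plot_operating_curves(curves), "ggplot")
})

test_that("the packaged panel and fixture tables carry the published values", {
  panel <- cell_panel()
  expect_equal(nrow(panel), 6)
  expect_equal(panel$diameter_um[panel$cell_type == "A549"], 17)
  expect_equal(panel$stiffness_pa[panel$cell_type == "SW480"], 580)
  tab <- a549_capture_table()
  expect_equal(sum(tab$captured_fraction), 1)
  expect_equal(tab$gap_um, c(4, 8, 10, 14))
})
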