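test_that("the default configuration reproduces the study design exactly", {
  cf <- default_study_config()
  expect_equal(cf$n_populations, 54L)
  expect_equal(cf$n_males + cf$n_females, 794L)
  expect_equal(unname(cf$region_sites), c(30L, 14L, 10L))
  expect_true(all(vapply(cf$capture_windows,
                         function(w) w$mean_day, 1) %in% 148:153))
  sim <- simulate_cohort(seed = 5)
  expect_equal(nrow(sim$cohort), 794)
  expect_equal(sum(sim$cohort$sex == "male"), 498)
  expect_equal(length(unique(sim$cohort$population_id)), 54)
})

test_that("identical seeds give bit-identical cohorts, different seeds do not", {
  s1 <- simulate_cohort(small_config(), seed = 8)
  s2 <- simulate_cohort(small_config(), seed = 8)
  s3 <- simulate_cohort(small_config(), seed = 9)
  expect_identical(s1$cohort, s2$cohort)
  expect_false(identical(s1$cohort, s3$cohort))
})

test_that("generated covariates respect their stated supports", {
  sim <- simulate_cohort(seed = 6)
  co <- sim$cohort
  cf <- sim$config
  for (s in c("male", "female")) {
    r <- cf$svl[[s]]$range
    expect_true(all(co$svl_mm[co$sex == s] >= r[1] &
                    co$svl_mm[co$sex == s] <= r[2]))
  }
  for (rg in names(cf$capture_windows)) {
    w <- cf$capture_windows[[rg]]
    dd <- co$capture_day[co$region == rg]
    expect_true(all(dd >= w$start & dd <= w$end))
    lat <- co$latitude_utm[co$region == rg]
    b <- cf$latitude_bands[[rg]]
    expect_true(all(lat >= b[1] & lat <= b[2]))
  }
  # every population holds at least 2 of each sex
  tab <- table(co$population_id, co$sex)
  expect_true(all(tab >= 2))
  # differentials are valid strictly positive compositions
  parts <- as.matrix(co[leukocyte_classes])
  expect_true(all(parts > 0))
  expect_equal(rowSums(parts), rep(1, nrow(co)), tolerance = 1e-9)
  expect_true(all(co$wbc_cells_per_ul > 0))
})

test_that("a degenerate flat generating process centres responses on the MESOR", {
  truth <- default_true_params()
  t0 <- truth$log_wbc
  for (nm in grep("^beta|amplitude", names(t0), value = TRUE)) t0[[nm]] <- 0
  t0$sigma_pop <- 0
  truth$log_wbc <- t0
  sim <- simulate_cohort(small_config(), truth, seed = 21)
  lw <- log(sim$cohort$wbc_cells_per_ul)
  se <- t0$sigma / sqrt(length(lw))
  expect_lt(abs(mean(lw) - t0$mesor), 3 * se)
})

test_that("doubling sigma_pop doubles the spread of population means", {
  truth <- default_true_params()
  t0 <- truth$log_wbc
  for (nm in grep("^beta|amplitude", names(t0), value = TRUE)) t0[[nm]] <- 0
  t0$sigma <- 0.01
  t0$sigma_pop <- 0.3
  truth$log_wbc <- t0
  s1 <- simulate_cohort(truth = truth, seed = 30)
  truth$log_wbc$sigma_pop <- 0.6
  s2 <- simulate_cohort(truth = truth, seed = 30)
  sd_pop <- function(s) sd(tapply(log(s$cohort$wbc_cells_per_ul),
                                  s$cohort$population_id, mean))
  ratio <- sd_pop(s2) / sd_pop(s1)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})

test_that("infeasible allocations are refused", {
  cf <- small_config()
  cf$n_males <- 10L  # 12 populations x 2 males minimum needs 24
  expect_error(simulate_cohort(cf, seed = 1), "infeasible allocation")
})

test_that("simulated smears obey the counting rule and the multinomial law", {
  sim <- simulate_cohort(small_config(), seed = 31)
  sm <- simulate_smears(sim$cohort, seed = 32)
  expect_true(all(counting_rule_satisfied(sm$n_fields, sm$total_leukocytes)))
  probs <- close_composition(as.matrix(sim$cohort[leukocyte_classes]))
  within3 <- vapply(seq_len(nrow(sm)), function(i) {
    n <- sm$total_leukocytes[i]
    expected <- n * probs[i, ]
    sds <- sqrt(n * probs[i, ] * (1 - probs[i, ]))
    all(abs(as.numeric(sm[i, leukocyte_classes]) - expected) <=
          3 * pmax(sds, 1))
  }, logical(1))
  expect_gt(mean(within3), 0.95)
  # counted frequencies carry the 1/total granularity of the tally
  fr <- as.matrix(sm[leukocyte_classes]) / sm$total_leukocytes
  expect_equal(fr * sm$total_leukocytes,
               round(fr * sm$total_leukocytes), tolerance = 1e-9)
  # a class with zero true frequency never shows up
  co0 <- sim$cohort[1:10, ]
  co0$basophils <- 0
  co0[leukocyte_classes] <- close_composition(as.matrix(co0[leukocyte_classes]))
  sm0 <- simulate_smears(co0, seed = 33)
  expect_true(all(sm0$basophils == 0))
})

test_that("smear counting approximately recovers the generating WBC and differential", {
  sim <- simulate_cohort(small_config(), seed = 34)
  sm <- simulate_smears(sim$cohort, mean_cells_per_field = 4, seed = 35)
  i <- 1
  rec <- smear_record(sm$individual_id[i], sm$n_fields[i],
                      as.numeric(sm[i, leukocyte_classes]))
  # mean cells/field near 4 -> WBC near 4 * 60^2
  expect_equal(estimate_wbc(rec) / 3600, 4, tolerance = 0.5)
  d <- differential_from_counts(rec)
  truth_i <- as.numeric(sim$cohort[i, leukocyte_classes])
  expect_true(all(abs(d - truth_i) < 0.1))
})

test_that("study configurations round-trip through YAML", {
  cf <- default_study_config(seed = 4)
  f <- tempfile(fileext = ".yaml")
  write_study_config(cf, f)
  cf2 <- read_study_config(f)
  expect_equal(cf2$n_populations, cf$n_populations)
  expect_equal(cf2$region_sites, cf$region_sites)
  expect_equal(cf2$svl$male$mean, cf$svl$male$mean)
  expect_equal(cf2$capture_windows, cf$capture_windows)
  expect_equal(cf2$latitude_bands, cf$latitude_bands)
  # and the round-tripped config drives an identical simulation
  expect_identical(simulate_cohort(cf, seed = 4)$cohort,
                   simulate_cohort(cf2, seed = 4)$cohort)
})
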