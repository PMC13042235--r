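# The cohort generator: determinism, label allocation, planted-shift
# calibration, the default region map's partition structure, and the effect
# of measurement noise on downstream recovery.

test_that("a fixed seed reproduces the cohort bit-identically", {
  a <- generate_cohort(mini_config(seed = 42))
  b <- generate_cohort(mini_config(seed = 42))
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$table$metadata, b$table$metadata)
  expect_identical(a$true_labels, b$true_labels)
  c <- generate_cohort(mini_config(seed = 43))
  expect_false(identical(a$table$values, c$table$values))
})

test_that("prevalences allocate patients by largest remainder (27/21/14 at n = 62)", {
  co <- generate_cohort(mini_config(endophenotypes = mini_endophenotypes()))
  tab <- table(co$true_labels)
  expect_identical(as.integer(tab[c("subcortical_reduction",
                                    "increased_cortical_thickness",
                                    "decreased_cortical_thickness")]),
                   c(27L, 21L, 14L))
  expect_identical(as.integer(sum(tab)), 62L)
  # every patient exactly one label; controls none
  expect_setequal(names(co$true_labels),
                  co$table$metadata$subject_id[co$table$metadata$group == "patient"])
})

test_that("invalid configurations are rejected", {
  eps <- mini_endophenotypes()
  eps[[1]]$prevalence <- 0.6
  expect_error(mini_config(endophenotypes = eps), "sum to 1")
  expect_error(generate_cohort(mini_config(n_patients = 2,
                                           endophenotypes = mini_endophenotypes())),
               "at least the number of endophenotypes")
})

test_that("default region map partitions the atlas", {
  map <- default_region_map()
  df <- as.data.frame(map)
  # every DK label in exactly one cortical composite, per hemisphere
  for (h in c("L", "R")) {
    ct <- unlist(lapply(map[df$measure_class == "cortical_thickness" &
                              df$hemisphere == h], `[[`, "members"))
    pre <- if (h == "L") "lh." else "rh."
    expect_setequal(ct, paste0(pre, unlist(dk_lobe_assignment())))
    expect_identical(anyDuplicated(ct), 0L)
    # motor + non-motor thalamus = full nucleus list, disjoint
    thal <- unlist(lapply(map[paste0(c("motor_thalamus_", "nonmotor_thalamus_"), h)],
                          `[[`, "members"))
    expect_setequal(thal, paste0(pre, "thal.", thalamic_nuclei()))
    expect_identical(anyDuplicated(thal), 0L)
  }
  # aggregation rule tied to measure class
  expect_true(all(df$aggregation[df$measure_class == "cortical_thickness"] == "mean"))
  expect_true(all(df$aggregation[df$measure_class != "cortical_thickness"] == "sum"))
  # generator baselines cover every mapped region
  expect_true(all(unlist(lapply(map, `[[`, "members")) %in%
                    default_region_baselines()$region))
})

test_that("planted composite shift is recovered at Monte-Carlo precision", {
  # covariate effects off so the raw composite isolates the planting mechanism
  cfg <- mini_config(
    n_controls = 300, n_patients = 300, seed = 1,
    endophenotypes = list(list(
      name = "sr", prevalence = 1,
      effect_map = c(motor_thalamus_L = -1.5))),
    thickness_age_slope = 0, thickness_age_quad = 0, volume_age_rate = 0,
    sex_effect_thickness = 0, sex_effect_volume_frac = 0, tiv_r2 = 1e-4)
  co <- generate_cohort(cfg)
  comp <- rowSums(co$table$values[, c("lh.thal.VA", "lh.thal.VLp")])
  grp <- co$table$metadata$group
  sd_c <- sqrt(40^2 + 95^2)  # baseline composite SD from mini_baselines()
  shift <- (mean(comp[grp == "patient"]) - mean(comp[grp == "control"])) / sd_c
  expect_lt(abs(shift - (-1.5)), 0.15)
})

test_that("more measurement noise monotonically degrades label recovery", {
  ari_at <- function(noise) {
    mean(vapply(1:6, function(s) {
      co <- generate_cohort(mini_config(seed = 100 + s,
                                        endophenotypes = mini_endophenotypes(),
                                        measurement_noise_sd = noise))
      res <- zmap_from_cohort(co, screen = FALSE)
      km <- kmeans_cluster(patient_z(res$zmap), 3, seed = s)
      adjusted_rand(km$labels, res$truth)
    }, 0))
  }
  ari <- vapply(c(0.7, 1.0, 1.6), ari_at, 0)
  expect_true(ari[1] > ari[2] && ari[2] > ari[3])
})
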