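# Candidate-space enumeration, ppm matching, cap typing and the reports.

catalog <- enumerate_caps()
t1 <- cap_detection_matrix()
assigned <- t1[!grepl("Y[0-9]+", t1$structure), ]

test_that("zero-methyl alphabet enumerates the 10 unordered base pairs", {
  bare <- enumerate_caps(default_alphabet(
    base_methyl_max = c(A = 0L, C = 0L, G = 0L, U = 0L),
    ribose_methyl = FALSE))
  expect_equal(nrow(bare), 10L)
  expect_true(all(c("GpppG", "GpppA", "UpppU") %in% bare$label))
  expect_setequal(bare$base_pair,
                  c("AA", "AC", "AG", "AU", "CC", "CG", "CU", "GG", "GU", "UU"))
})

test_that("default enumeration is deterministic and covers every assigned label", {
  expect_equal(catalog$anion_mass, sort(catalog$anion_mass))
  expect_false(any(duplicated(catalog$label)))
  expect_true(all(canonical_label(assigned$structure) %in% catalog$label))
  # rerun gives the identical catalog
  expect_identical(as.data.frame(enumerate_caps()), as.data.frame(catalog))
})

test_that("every assigned observed mass matches its printed label at 5 ppm", {
  for (i in seq_len(nrow(assigned))) {
    m <- match_observation(assigned$observed_mass[i], catalog, 5)
    expect_equal(m$status, "matched")
    expect_true(canonical_label(assigned$structure[i]) %in%
                  m$candidates$label)
  }
})

test_that("isobar groups share one formula; the 813 group holds the 4 published labels", {
  m <- match_observation(813.1157, catalog, 5)
  expect_equal(length(m$isobar_groups), 1L)
  expect_length(unique(m$candidates$formula), 1L)
  expect_true(all(c("2mGpppAm", "mGpppmAm", "3mGpppA") %in%
                    m$candidates$label))
  # 2mGpppAm stands for both published retention-time isomers
  expect_setequal(
    intersect(canonical_label(assigned$structure[assigned$calculated_mass == 813.1138]),
              m$candidates$label),
    c("2mGpppAm", "mGpppmAm", "3mGpppA"))
  # candidates at base pair {G,A} with 3 methyls are all isobaric
  ga3 <- catalog[catalog$base_pair == "AG" & catalog$total_methyls == 3L, ]
  expect_gte(nrow(ga3), 4L)
  expect_length(unique(ga3$formula), 1L)
})

test_that("unmatched observations are unknown but keep nearest candidates", {
  m <- match_observation(841.1104, catalog, 5)
  expect_equal(m$status, "unknown")
  expect_equal(nrow(m$candidates), 0L)
  expect_gt(nrow(m$nearest), 0L)
  expect_true(all(abs(m$nearest$ppm) > 5))
})

test_that("widening the tolerance never shrinks a candidate set", {
  masses <- t1$observed_mass
  for (obs in masses) {
    prev <- character()
    for (tol in c(1, 3, 5, 20)) {
      cand <- match_observation(obs, catalog, tol)$candidates$label
      expect_true(all(prev %in% cand))
      prev <- cand
    }
  }
})

test_that("matching validates its inputs", {
  expect_error(match_observation(800, catalog, 0), "positive")
  expect_error(match_observation(800, catalog, -1), "positive")
  expect_error(match_observation(800, catalog, 5, fraction = "10-20"),
               "fraction")
})

test_that("cap types split on inner 2'-O-methylation", {
  expect_equal(classify_cap_type(cap_structure(nucleoside("G"),
                                               nucleoside("G"))), "type0")
  expect_equal(classify_cap_type(cap_structure(nucleoside("G", 1),
                                               nucleoside("A"))), "type0")
  expect_equal(classify_cap_type(
    cap_structure(nucleoside("G", 3), nucleoside("A", ribose_methyl = TRUE))),
    "type1_or_higher")
  # the published type-0 list all classify as type0 in the catalog
  t0 <- c("mGpppC", "mGpppG", "GpppG", "GpppA", "mGpppA")
  expect_true(all(catalog$cap_type[match(t0, catalog$label)] == "type0"))
})

test_that("fraction-specific scan reproduces the five short-fraction caps", {
  expect_setequal(fraction_specific_structures(t1, "20-50"),
                  c("mGpppUm", "mGpppG", "mGpppA", "GpppCm", "GpppGm"))
  expect_length(fraction_specific_structures(t1, "50-100"), 0L)
  expect_length(fraction_specific_structures(t1[0, ], "20-50"), 0L)
  expect_error(fraction_specific_structures(t1, "0-20"), "unknown fraction")
})

test_that("cross-validation joins on the cap-nucleoside key", {
  tlc <- data.frame(spot_label = c("2,2,7mGp", "X1"),
                    fraction = c("<50", "<50"), stringsAsFactors = FALSE)
  ms <- data.frame(structure = "3mGpppAm/Amppp3mG", fraction = "20-50",
                   stringsAsFactors = FALSE)
  cv <- cross_validate(tlc, ms)
  expect_equal(nrow(cv$cross_validated), 1L)
  expect_equal(cv$cross_validated$spot_labels, "2,2,7mGp")
  expect_equal(cv$cross_validated$structures, "3mGpppAm")
  # the unassignable TLC spot lands in the residual section, never dropped
  expect_equal(cv$tlc_only$spot_label, "X1")
  # disjoint methylation states do not join
  cv2 <- cross_validate(data.frame(spot_label = "7mGp", fraction = "<50"),
                        data.frame(structure = "3mGpppAm", fraction = ">100"))
  expect_equal(nrow(cv2$cross_validated), 0L)
  expect_equal(nrow(cv2$tlc_only), 1L)
  expect_equal(nrow(cv2$ms_only), 1L)
})

test_that("position-style and count-style methyl labels map to one key", {
  # TLC lists positions (2,2,7mGp = three methyls); MS lists counts (3mG)
  cv <- cross_validate(
    data.frame(spot_label = c("Gp", "7mGp", "2,2mGp", "Cmp"),
               fraction = "<50"),
    data.frame(structure = c("GpppA", "mGpppUm", "2mGpppAm", "CmpppG"),
               fraction = "20-50"))
  expect_setequal(cv$cross_validated$spot_labels,
                  c("Gp", "7mGp", "2,2mGp", "Cmp"))
})

test_that("seeded noisy observations recover their isobar group", {
  cfg <- sim_config(seed = 42)
  ms <- gen_mass_observations(cfg, catalog, n = 60, sd_ppm = 1.5)
  ok <- vapply(seq_len(nrow(ms$truth)), function(i) {
    m <- match_observation(ms$truth$observed_mass[i], catalog, 5)
    ms$truth$true_formula[i] %in% m$candidates$formula
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})
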