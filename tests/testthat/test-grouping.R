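random_profile <- function(K) {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V")
  sample(codes, K, replace = TRUE)
}

test_that("state distance is Jaccard on base sets", {
  expect_equal(state_distance("A", "A"), 0)
  expect_equal(state_distance("A", "G"), 1)
  expect_equal(state_distance("A", "R"), 0.5)
  expect_equal(state_distance("R", "R"), 0)
  expect_equal(state_distance("R", "Y"), 1)        # {A,G} vs {C,T}
  expect_equal(state_distance("R", "D"), 1 - 2 / 3) # {A,G} vs {A,G,T}
  expect_error(state_distance("N", "A"), "missing")
  expect_error(state_distance("-", "A"), "missing")
})

test_that("profile distance averages shared non-missing columns", {
  expect_equal(profile_distance(c("A", "C"), c("A", "C")), 0)
  expect_equal(profile_distance(c("A", "C", "."), c("G", "C", "T")), 0.5)
  expect_error(profile_distance(c(".", "N"), c("A", "-")), "no shared")
})

test_that("profile distance satisfies the metric axioms on random triples", {
  set.seed(31)
  for (k in 1:200) {
    K <- sample(3:10, 1)
    x <- random_profile(K); y <- random_profile(K); z <- random_profile(K)
    dxy <- profile_distance(x, y)
    expect_equal(dxy, profile_distance(y, x))
    expect_equal(profile_distance(x, x), 0)
    if (!identical(x, y)) expect_gt(dxy, 0)
    expect_lte(dxy, profile_distance(x, z) + profile_distance(z, y) + 1e-12)
    expect_gte(dxy, 0); expect_lte(dxy, 1)
  }
})

test_that("fixture profile distances to the reference match the documented counts", {
  fx <- con2_fixture()
  pm <- fixture_profile_matrix(fx$zygosity, family = "CON2")
  diffs_vs_ref <- function(sample) {
    sum(pm$states[sample, ] != pm$ref_states)
  }
  expect_equal(diffs_vs_ref("Da_KEW-0522816"), 1)  # group 1: one alteration
  expect_equal(diffs_vs_ref("Ds_78"), 7)           # group 2: one match
  expect_equal(diffs_vs_ref("Hp_KEW-065160"), 5)   # group 3: three matches
  expect_equal(diffs_vs_ref("Dd_W6-39054"), 6)     # group 4: six alterations
})

test_that("partition groups samples by exact profile equality", {
  prof <- matrix("hom_ref", 4, 2,
                 dimnames = list(c("reference", "a", "b", "c"), NULL))
  prof[c("a", "b", "c"), 1] <- "het"
  cfg <- family_config("TOY", length = 40, profiles = prof,
                       flank5 = "", flank3 = "")
  pm <- pipeline_from_dataset(generate_dataset(cfg))$pm
  g <- partition_profiles(pm)
  expect_length(g$groups, 1)
  expect_setequal(g$groups[[1]]$members, c("a", "b", "c"))

  # all pairwise distinct -> n groups
  prof2 <- matrix("hom_ref", 4, 3,
                  dimnames = list(c("reference", "a", "b", "c"), NULL))
  prof2["a", 1] <- "hom_alt"; prof2["b", 2] <- "het"; prof2["c", 3] <- "het3"
  cfg2 <- family_config("TOY", length = 40, profiles = prof2,
                        flank5 = "", flank3 = "")
  pm2 <- pipeline_from_dataset(generate_dataset(cfg2))$pm
  expect_length(partition_profiles(pm2)$groups, 3)
})

test_that("partition membership is invariant under sample reordering", {
  fx <- con2_fixture()
  pm <- fixture_profile_matrix(fx$zygosity)
  ref_groups <- lapply(partition_profiles(pm)$groups,
                       function(g) sort(g$members))
  set.seed(17)
  for (k in 1:20) {
    zy <- fx$zygosity[c("reference",
                        sample(setdiff(rownames(fx$zygosity), "reference"))), ]
    g2 <- lapply(partition_profiles(fixture_profile_matrix(zy))$groups,
                 function(g) sort(g$members))
    # same classes, order of groups may differ
    expect_setequal(vapply(g2, paste, "", collapse = ","),
                    vapply(ref_groups, paste, "", collapse = ","))
  }
})

test_that("missing states compare equal for profile-equality grouping", {
  pm <- build_profile_matrix(list(), c("a", "b"))
  pm$states <- matrix(c("A", ".", "A", "-"), nrow = 2, byrow = TRUE,
                      dimnames = list(c("a", "b"), NULL))
  pm$zygosity <- matrix("HOM_REF", 2, 2, dimnames = dimnames(pm$states))
  pm$ref_positions <- c(0L, 5L); pm$ref_states <- c("C", "C")
  g <- partition_profiles(pm)
  expect_length(g$groups, 1)
})
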